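#' Inputs for the steady-state theory
#'
#' Collects the handful of quantities the closed-form theory needs: the
#' activator and inhibitor transcription MM constants, the common bulk MM
#' constant, the steady total RNAP concentration `c_n`, the genome capacity
#' `n_c`, and the cell-to-nuclear volume ratio `a`. Built either explicitly
#' or from a calibrated genome (activator/inhibitor constants are averaged if
#' heterogeneous; the bulk constant is the capacity-weighted mean).
#'
#' @param genome,params A calibrated [genome()] and [global_params()]; or
#'   leave `genome` `NULL` and give the fields directly.
#' @param K_act,K_inh,K_n,c_n,n_c,a Direct field values (um^-3 for the K's
#'   and `c_n`).
#' @return An object of class `theory_inputs`.
#' @export
theory_inputs <- function(genome = NULL, params = NULL, K_act = NULL,
                          K_inh = NULL, K_n = NULL, c_n = NULL, n_c = NULL,
                          a = NULL) {
  if (!is.null(genome)) {
    mod <- .compile_model(genome, params)
    .check_calibrated(mod)
    other <- setdiff(seq_along(mod$K_n), c(mod$i_act, mod$i_inh))
    K_act <- mean(mod$K_n[mod$i_act])
    K_inh <- mean(mod$K_n[mod$i_inh])
    K_n <- sum(mod$K_n[other] * mod$cap_n[other]) / sum(mod$cap_n[other])
    c_n <- mod$c_n
    n_c <- mod$nc
    a <- mod$a
  }
  stopifnot(K_act > 0, K_inh > 0, K_n > 0, c_n > 0, n_c > 0, a > 0)
  if (K_act <= K_inh) {
    stop("the activator must have the weaker promoter (K_act > K_inh)")
  }
  structure(list(K_act = K_act, K_inh = K_inh, K_n = K_n, c_n = c_n,
                 n_c = n_c, a = a),
            class = "theory_inputs")
}

#' @export
print.theory_inputs <- function(x, ...) {
  cat(sprintf(
    "<theory_inputs> K_act=%g, K_inh=%g, K_n=%g, c_n=%g um^-3; n_c=%g; a=%g\n",
    x$K_act, x$K_inh, x$K_n, x$c_n, x$n_c, x$a))
  invisible(x)
}

#' Effective promoter-strength combination
#'
#' `Ktilde = theta * K_act - K_inh`: the single linear combination of the two
#' regulator MM constants that the birth volume depends on.
#'
#' @param theta Division threshold.
#' @param K_act,K_inh Activator and inhibitor MM constants, um^-3.
#' @return `Ktilde`, um^-3.
#' @export
ktilde <- function(theta, K_act, K_inh) theta * K_act - K_inh

#' Critical division thresholds
#'
#' The stable cell cycle exists for `theta1 < theta < theta2` with
#' `theta1 = K_inh / K_act` (free-RNAP fraction at division reaching 0) and
#' `theta2 = (c_n + K_inh) / (c_n + K_act)` (reaching 1). Outside this window
#' the activator and scaled inhibitor concentration curves never intersect
#' and the cell cannot divide.
#'
#' @param inputs A [theory_inputs()] (or supply `K_act`, `K_inh`, `c_n`).
#' @param K_act,K_inh,c_n Direct values, used when `inputs` is missing.
#' @return Named numeric vector `c(theta1, theta2)`.
#' @export
critical_thresholds <- function(inputs = NULL, K_act = NULL, K_inh = NULL,
                                c_n = NULL) {
  if (!is.null(inputs)) {
    K_act <- inputs$K_act; K_inh <- inputs$K_inh; c_n <- inputs$c_n
  }
  c(theta1 = K_inh / K_act, theta2 = (c_n + K_inh) / (c_n + K_act))
}

.check_window <- function(theta, inputs, closed = FALSE) {
  th <- critical_thresholds(inputs)
  ok <- if (closed) theta >= th[1] && theta <= th[2] else
    theta > th[1] && theta < th[2]
  if (!ok) {
    stop(sprintf("theta = %g outside the stable-cycle window (%g, %g)",
                 theta, th[1], th[2]), call. = FALSE)
  }
  th
}

#' Free RNAP fraction at division
#'
#' `F_n_d = Ktilde / ((1 - theta) c_n)`; it sweeps from 0 at `theta1` to 1 at
#' `theta2`.
#'
#' @param theta Division threshold in the stable window.
#' @param inputs A [theory_inputs()].
#' @return `F_n_d` in `[0, 1]`.
#' @export
free_fraction_at_division <- function(theta, inputs) {
  .check_window(theta, inputs, closed = TRUE)
  kt <- ktilde(theta, inputs$K_act, inputs$K_inh)
  min(1, max(0, kt / ((1 - theta) * inputs$c_n)))
}

#' Theoretical birth volume
#'
#' The deterministic steady-state cell volume at birth,
#' `V_b = gamma * a * n_c * (1 - theta) * Ktilde /
#'  (((1 - theta) c_n - Ktilde) ((1 - theta) K_n + Ktilde))`,
#' strictly increasing across the stable window, vanishing at `theta1` and
#' diverging at `theta2`, and proportional to the genome capacity `n_c`
#' (hence to ploidy).
#'
#' @inheritParams free_fraction_at_division
#' @param gamma Daughter volume fraction (0.5 = symmetric division).
#' @return `V_b` in um^3.
#' @export
birth_volume <- function(theta, inputs, gamma = 0.5) {
  th <- .check_window(theta, inputs, closed = TRUE)
  if (theta == th[1]) return(0)
  if (theta == th[2]) return(Inf)
  gamma * inputs$a * division_count_at_division(theta, inputs) / inputs$c_n
}

#' RNAP count and mRNA vector at division
#'
#' `division_count_at_division()` gives the closed-form total RNAP number at
#' division,
#' `n_d = n_c c_n (1 - theta) Ktilde /
#'  (((1 - theta) c_n - Ktilde) ((1 - theta) K_n + Ktilde))`;
#' `division_state()` additionally evaluates the quasi-steady mRNA copy
#' numbers of every gene class at division,
#' `m_i_d = Gamma_n_i g_i tau_m_i Ktilde / (Ktilde + (1 - theta) K_n_i)`.
#'
#' @inheritParams birth_volume
#' @return `division_count_at_division()`: the count `n_d`;
#'   `division_state()`: list with `n_d`, `n_b = gamma * n_d`, and (when a
#'   genome is supplied) the vector `m_d`.
#' @export
division_count_at_division <- function(theta, inputs) {
  th <- .check_window(theta, inputs, closed = TRUE)
  if (theta == th[2]) return(Inf)
  kt <- max(0, ktilde(theta, inputs$K_act, inputs$K_inh))
  s <- 1 - theta
  inputs$n_c * inputs$c_n * s * kt / ((s * inputs$c_n - kt) *
                                        (s * inputs$K_n + kt))
}

#' @rdname division_count_at_division
#' @param genome,params Optional calibrated genome for the per-class mRNA
#'   vector.
#' @export
division_state <- function(theta, inputs, gamma = 0.5, genome = NULL,
                           params = NULL) {
  n_d <- division_count_at_division(theta, inputs)
  out <- list(n_d = n_d, n_b = gamma * n_d)
  if (!is.null(genome)) {
    mod <- .compile_model(genome, params)
    .check_calibrated(mod)
    kt <- max(0, ktilde(theta, inputs$K_act, inputs$K_inh))
    tau_m <- 1 / mod$inv_tau_m
    out$m_d <- mod$Gamma_n * mod$w * tau_m * kt /
      (kt + (1 - theta) * mod$K_n)
  }
  out
}

#' Free RNAP fraction at birth
#'
#' Solves `n_b (1 - F_n_b) = n_c F_n_b c_n / (F_n_b c_n + K_n)`: the birth
#' analogue of the division free fraction, with the genome represented by its
#' total capacity and common MM constant. Increasing in `n_b`, 0 at
#' `n_b = 0`, 1 as `n_b` grows without bound.
#'
#' @param n_b RNAP count at birth (>= 0, may be `Inf`).
#' @param inputs A [theory_inputs()].
#' @return `F_n_b` in `[0, 1]`.
#' @export
free_fraction_at_birth <- function(n_b, inputs) {
  if (!is.finite(n_b)) return(1)
  if (n_b <= 0) return(0)
  .solve_fraction(n_b, inputs$n_c, inputs$K_n, inputs$c_n)
}

#' Regulator concentration ratio at a given free RNAP fraction
#'
#' The quasi-steady activator-to-inhibitor concentration ratio,
#' `(F_n c_n + K_inh) / (F_n c_n + K_act)`: strictly increasing in `F_n`,
#' bounded between the two critical thresholds.
#'
#' @param F_n Free RNAP fraction in `[0, 1]`.
#' @param inputs A [theory_inputs()].
#' @return The ratio `c_act / c_inh`.
#' @export
ratio_of_concentrations <- function(F_n, inputs) {
  x <- F_n * inputs$c_n
  (x + inputs$K_inh) / (x + inputs$K_act)
}

#' Oscillation amplitude of the regulator ratio
#'
#' The within-cycle drop of `c_act / c_inh` below the division threshold:
#' `A = theta - (F_n_b c_n + K_inh) / (F_n_b c_n + K_act)` with `F_n_b` the
#' free RNAP fraction at birth ([free_fraction_at_birth()] at
#' `n_b = gamma * n_d`). `A` is positive strictly inside the stable window,
#' exactly 0 at both critical thresholds, and has a single interior maximum.
#' Its size against the threshold noise decides robust division.
#'
#' @inheritParams birth_volume
#' @return The amplitude `A`.
#' @export
amplitude <- function(theta, inputs, gamma = 0.5) {
  th <- .check_window(theta, inputs, closed = TRUE)
  F_nb <- if (theta == th[1]) 0 else if (theta == th[2]) 1 else {
    free_fraction_at_birth(gamma * division_count_at_division(theta, inputs),
                           inputs)
  }
  theta - ratio_of_concentrations(F_nb, inputs)
}

#' Moments of the stochastic birth size
#'
#' Linearizing the birth volume in the threshold noise gives
#' `<V_b> = V_b(theta_bar)` and
#' `CV = (K_act - K_inh) ((1-theta_bar)^2 c_n K_n + Ktilde^2) sigma /
#'  ((1-theta_bar) Ktilde ((1-theta_bar) c_n - Ktilde)
#'   ((1-theta_bar) K_n + Ktilde))`
#' with `sigma = delta_theta / 3`. The CV vanishes with the noise, falls as
#' the activator promoter weakens (larger `K_act`) and rises as the inhibitor
#' promoter weakens (larger `K_inh`): more differential size-scaling of the
#' two regulators narrows the size distribution.
#'
#' @param theta_bar Mean threshold, inside the stable window.
#' @param delta_theta Threshold half-width; the threshold SD is
#'   `delta_theta / 3`.
#' @inheritParams birth_volume
#' @return List with `mean_V_b` and `cv_V_b`.
#' @export
stochastic_birth_moments <- function(theta_bar, delta_theta, inputs,
                                     gamma = 0.5) {
  .check_window(theta_bar, inputs)
  sigma <- delta_theta / 3
  kt <- ktilde(theta_bar, inputs$K_act, inputs$K_inh)
  s <- 1 - theta_bar
  cv <- (inputs$K_act - inputs$K_inh) * (s^2 * inputs$c_n * inputs$K_n +
                                           kt^2) * sigma /
    (s * kt * (s * inputs$c_n - kt) * (s * inputs$K_n + kt))
  list(mean_V_b = birth_volume(theta_bar, inputs, gamma), cv_V_b = cv)
}

#' Robust-division condition under threshold noise
#'
#' With i.i.d. thresholds on `(theta_bar - delta_theta, theta_bar +
#' delta_theta)`, every cycle's ratio minimum must fall below the next
#' threshold. Since `theta - A(theta)` increases with `theta`, the worst case
#' is a division at `theta_bar + delta_theta` followed by a threshold
#' `theta_bar - delta_theta`, giving the condition
#' `A(theta_bar + delta_theta) > 2 delta_theta`. With `delta_theta = 0` it
#' reduces to `A(theta_bar) > 0`, the deterministic viability condition.
#'
#' @inheritParams stochastic_birth_moments
#' @return `TRUE` if robust division is predicted.
#' @export
robust_division_condition <- function(theta_bar, delta_theta, inputs,
                                      gamma = 0.5) {
  stopifnot(theta_bar - delta_theta > 0)
  th <- critical_thresholds(inputs)
  hi <- theta_bar + delta_theta
  if (hi >= th[2] || hi <= th[1]) return(FALSE)
  amplitude(hi, inputs, gamma) > 2 * delta_theta
}

#' Viable mean-threshold band under noise
#'
#' The interval of `theta_bar` satisfying [robust_division_condition()] for a
#' given `delta_theta`, located numerically from the unimodal amplitude
#' curve.
#'
#' @inheritParams stochastic_birth_moments
#' @return `c(lower, upper)` band edges (NA if the condition holds nowhere).
#' @export
robust_theta_band <- function(delta_theta, inputs, gamma = 0.5) {
  th <- critical_thresholds(inputs)
  h <- function(tb) amplitude(tb + delta_theta, inputs, gamma) -
    2 * delta_theta
  grid <- seq(th[1] + 1e-6, th[2] - delta_theta - 1e-6, length.out = 400)
  grid <- grid[grid - delta_theta > 0]
  vals <- vapply(grid, h, numeric(1))
  pos <- which(vals > 0)
  if (length(pos) == 0L) return(c(NA_real_, NA_real_))
  lo_i <- pos[1L]; hi_i <- pos[length(pos)]
  lo <- if (lo_i == 1L) grid[1L] else
    stats::uniroot(h, c(grid[lo_i - 1L], grid[lo_i]), tol = 1e-10)$root
  hi <- if (hi_i == length(grid)) grid[length(grid)] else
    stats::uniroot(h, c(grid[hi_i], grid[hi_i + 1L]), tol = 1e-10)$root
  c(lower = lo, upper = hi)
}

#' Full theory prediction at one operating point
#'
#' Convenience wrapper bundling the closed-form quantities: the critical
#' thresholds, birth volume, free fractions at division and birth, RNAP
#' counts, amplitude, stochastic moments, and the robustness verdict.
#'
#' @inheritParams stochastic_birth_moments
#' @param theta Deterministic threshold (or give `theta_bar`/`delta_theta`).
#' @return An object of class `theory_prediction`.
#' @export
theory_predict <- function(inputs, theta = NULL, theta_bar = NULL,
                           delta_theta = 0, gamma = 0.5) {
  if (is.null(theta_bar)) theta_bar <- theta
  stopifnot(!is.null(theta_bar))
  th <- .check_window(theta_bar, inputs)
  n_d <- division_count_at_division(theta_bar, inputs)
  n_b <- gamma * n_d
  mom <- stochastic_birth_moments(theta_bar, delta_theta, inputs, gamma)
  structure(list(
    theta_bar = theta_bar, delta_theta = delta_theta,
    theta1 = unname(th[1]), theta2 = unname(th[2]),
    V_b = birth_volume(theta_bar, inputs, gamma),
    F_n_d = free_fraction_at_division(theta_bar, inputs),
    F_n_b = free_fraction_at_birth(n_b, inputs),
    n_d = n_d, n_b = n_b,
    A = amplitude(theta_bar, inputs, gamma),
    mean_V_b = mom$mean_V_b, cv_V_b = mom$cv_V_b,
    robust = robust_division_condition(theta_bar, max(delta_theta, 0),
                                       inputs, gamma)),
    class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf("<theory_prediction> theta_bar = %g (window %.4g - %.4g)\n",
              x$theta_bar, x$theta1, x$theta2))
  cat(sprintf("  V_b = %.5g um^3, F_n_d = %.4g, F_n_b = %.4g, A = %.4g\n",
              x$V_b, x$F_n_d, x$F_n_b, x$A))
  cat(sprintf("  <V_b> = %.5g, CV = %.4g, robust: %s\n",
              x$mean_V_b, x$cv_V_b, x$robust))
  invisible(x)
}
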