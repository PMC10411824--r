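#' Specify a division rule
#'
#' The division rule monitors a scalar readout of the cell state and triggers
#' division at its first upward zero-crossing after a minimal cycle time.
#' Kinds:
#' \describe{
#'   \item{`ratio`}{divide when the weighted activator-to-inhibitor
#'     concentration ratio `sum(chi_act c_act) / sum(chi_inh c_inh)` rises to
#'     `theta` (the default, and the rule the closed-form theory describes).}
#'   \item{`activator_only`}{divide when the activator concentration rises to
#'     `theta` (um^-3).}
#'   \item{`inhibitor_only`}{divide when the inhibitor concentration falls to
#'     `theta` (um^-3).}
#'   \item{`and_logic`}{divide when both the activator has risen to
#'     `theta_act` and the inhibitor has fallen to `theta_inh`.}
#'   \item{`hazard`}{probabilistic entry: each cycle draws the division ratio
#'     from the hazard `k(theta)` by inverse-transform sampling
#'     ([hazard_sample_division()]), then divides when the ratio rises to the
#'     drawn value.}
#' }
#'
#' With `delta_theta > 0` the threshold of each generation is an independent
#' draw from `Normal(theta_bar, (delta_theta/3)^2)`, reset to `theta_bar`
#' whenever it falls outside `(theta_bar - delta_theta, theta_bar +
#' delta_theta)` ([draw_threshold()]). A `theta_sequence` overrides the draws
#' with a fixed recycled sequence (useful for worst-case robustness probes).
#'
#' @param kind Rule type, see Details.
#' @param theta Deterministic threshold (alias for `theta_bar` with
#'   `delta_theta = 0`).
#' @param theta_bar,delta_theta Mean and half-width of the stochastic
#'   threshold.
#' @param theta_act,theta_inh Concentration thresholds for `and_logic`
#'   (um^-3).
#' @param theta_sequence Optional numeric vector of per-generation thresholds
#'   (recycled), overriding random draws.
#' @param hazard Function `k(theta, theta_b)` giving the division hazard per
#'   unit ratio; see [make_power_hazard()].
#' @param t_min Minimal cycle duration before division is allowed, h
#'   (default 20 min).
#' @param replication_delay If set (`T_M`, h), the threshold crossing triggers
#'   genome replication (all gene copy numbers double) and division follows
#'   `T_M` later, with copy numbers halving back at division.
#' @param gamma Fraction of every species the tracked daughter inherits
#'   (0.5 = symmetric division).
#' @param eta If set, inhibitor proteins are partitioned with fraction `eta`
#'   instead of `gamma` (unequal inhibitor segregation).
#' @param alpha Opaque variant parameter carried through to run manifests
#'   (not used by the dynamics).
#' @return An object of class `division_rule`.
#' @export
division_rule <- function(kind = c("ratio", "activator_only", "inhibitor_only",
                                   "and_logic", "hazard"),
                          theta = NULL, theta_bar = NULL, delta_theta = 0,
                          theta_act = NULL, theta_inh = NULL,
                          theta_sequence = NULL, hazard = NULL,
                          t_min = 1 / 3, replication_delay = NULL,
                          gamma = 0.5, eta = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  if (is.null(theta_bar)) theta_bar <- theta
  if (kind %in% c("ratio", "activator_only", "inhibitor_only")) {
    if (is.null(theta_bar) && is.null(theta_sequence)) {
      stop("rule '", kind, "' needs 'theta' (or 'theta_bar') or a ",
           "'theta_sequence'")
    }
    if (!is.null(theta_bar)) {
      stopifnot(theta_bar > 0, delta_theta >= 0, theta_bar - delta_theta > 0)
    }
  }
  if (kind == "and_logic") {
    stopifnot(!is.null(theta_act), !is.null(theta_inh),
              theta_act > 0, theta_inh > 0)
  }
  if (kind == "hazard") {
    if (is.null(hazard)) hazard <- make_power_hazard()
    stopifnot(is.function(hazard))
  }
  stopifnot(t_min >= 0, gamma > 0, gamma < 1)
  if (!is.null(eta)) stopifnot(eta > 0, eta < 1)
  if (!is.null(replication_delay)) stopifnot(replication_delay >= 0)
  structure(list(kind = kind, theta_bar = theta_bar,
                 delta_theta = delta_theta, theta_act = theta_act,
                 theta_inh = theta_inh, theta_sequence = theta_sequence,
                 hazard = hazard, t_min = t_min,
                 replication_delay = replication_delay,
                 gamma = gamma, eta = eta, alpha = alpha),
            class = "division_rule")
}

#' @export
print.division_rule <- function(x, ...) {
  cat(sprintf("<division_rule '%s'>", x$kind))
  if (!is.null(x$theta_bar)) {
    if (x$delta_theta > 0) {
      cat(sprintf(" theta ~ N(%g, (%g/3)^2) on (%g, %g)", x$theta_bar,
                  x$delta_theta, x$theta_bar - x$delta_theta,
                  x$theta_bar + x$delta_theta))
    } else cat(sprintf(" theta = %g", x$theta_bar))
  }
  if (!is.null(x$theta_sequence)) cat(" [fixed threshold sequence]")
  cat(sprintf(", t_min = %g h, gamma = %g", x$t_min, x$gamma))
  if (!is.null(x$eta)) cat(sprintf(", eta = %g", x$eta))
  if (!is.null(x$replication_delay)) {
    cat(sprintf(", T_M = %g h", x$replication_delay))
  }
  cat("\n")
  invisible(x)
}

#' Draw a division threshold
#'
#' Samples `Normal(theta_bar, (delta_theta/3)^2)` and resets the draw to
#' `theta_bar` when it falls outside `(theta_bar - delta_theta, theta_bar +
#' delta_theta)`, so the support is bounded and about 0.27% of draws are
#' reset. `delta_theta = 0` returns `theta_bar` exactly.
#'
#' @param theta_bar Mean threshold.
#' @param delta_theta Half-width of the admissible interval.
#' @return A single threshold value.
#' @export
draw_threshold <- function(theta_bar, delta_theta) {
  stopifnot(theta_bar > delta_theta, delta_theta >= 0)
  if (delta_theta == 0) return(theta_bar)
  th <- stats::rnorm(1, theta_bar, delta_theta / 3)
  if (th <= theta_bar - delta_theta || th >= theta_bar + delta_theta) {
    th <- theta_bar
  }
  th
}

## Weighted regulator concentration sums (per unit volume cancels in ratios,
## so sums of protein numbers are used where only the ratio matters).
.regulator_sums <- function(p, mod) {
  list(act = sum(mod$chi[mod$i_act] * p[mod$i_act]),
       inh = sum(mod$chi[mod$i_inh] * p[mod$i_inh]))
}

#' Division signal
#'
#' Returns the monitored scalar minus its threshold, oriented so that an
#' upward zero-crossing always signals division: for the `ratio` kind
#' `sum(chi_act c_act)/sum(chi_inh c_inh) - theta`; for `activator_only`
#' `c_act - theta`; for `inhibitor_only` `theta - c_inh`; for `and_logic`
#' `min(c_act - theta_act, theta_inh - c_inh)`.
#'
#' @param state A [cell_state()].
#' @param rule A [division_rule()].
#' @inheritParams volume_of
#' @param theta Optional threshold override (the value drawn for the current
#'   generation); defaults to the rule's `theta_bar`.
#' @return The signal value (divide when it crosses zero upward).
#' @export
division_signal <- function(state, rule, genome, params, theta = NULL) {
  mod <- if (inherits(genome, "genome")) .compile_model(genome, params) else
    genome
  .signal_value(state$p, mod, rule,
                if (is.null(theta)) rule$theta_bar else theta)
}

.signal_value <- function(p, mod, rule, theta) {
  V <- sum(p * mod$L) / mod$rho
  switch(rule$kind,
    ratio = , hazard = {
      s <- .regulator_sums(p, mod)
      if (s$inh <= 0) stop("zero inhibitor concentration in ratio rule")
      s$act / s$inh - theta
    },
    activator_only = sum(mod$chi[mod$i_act] * p[mod$i_act]) / V - theta,
    inhibitor_only = theta - sum(mod$chi[mod$i_inh] * p[mod$i_inh]) / V,
    and_logic = {
      min(sum(mod$chi[mod$i_act] * p[mod$i_act]) / V - rule$theta_act,
          rule$theta_inh - sum(mod$chi[mod$i_inh] * p[mod$i_inh]) / V)
    })
}

#' Partition a dividing cell
#'
#' Symmetric division halves every mRNA and protein count; asymmetric
#' division gives the tracked daughter fraction `gamma` of every species,
#' except inhibitor proteins which receive fraction `eta` when set (unequal
#' inhibitor segregation, as for Whi5 in budding yeast).
#'
#' @param state A [cell_state()] at the division event.
#' @param rule A [division_rule()] (uses `gamma` and `eta`).
#' @inheritParams volume_of
#' @return The daughter [cell_state()] at `t = 0`.
#' @export
partition_at_division <- function(state, rule, genome, params) {
  mod <- if (inherits(genome, "genome")) .compile_model(genome, params) else
    genome
  frac_p <- rep(rule$gamma, length(state$p))
  if (!is.null(rule$eta)) frac_p[mod$i_inh] <- rule$eta
  cell_state(0, state$m * rule$gamma, state$p * frac_p)
}

#' Power-law division hazard
#'
#' Builds the default hazard family `k(theta) = C1 * max(0, theta -
#' theta_b)^C2`, where `theta_b` is the activator-to-inhibitor ratio at
#' birth. Any nonnegative function `k(theta, theta_b)` may be supplied to
#' [division_rule()] instead.
#'
#' @param C1 Scale, per unit ratio.
#' @param C2 Exponent.
#' @return A function `k(theta, theta_b)`.
#' @export
make_power_hazard <- function(C1 = 200, C2 = 1) {
  stopifnot(C1 > 0, C2 >= 0)
  function(theta, theta_b) C1 * pmax(0, theta - theta_b)^C2
}

#' Sample a division ratio from a hazard
#'
#' Inverse-transform sampling of the activator-to-inhibitor ratio at which a
#' probabilistic cell-cycle entry fires: with hazard `k(theta)` the cumulative
#' distribution is `F(theta_d) = 1 - exp(-int_{theta_b}^{theta_d} k)`, so a
#' uniform draw `x` is inverted numerically for `theta_d`.
#'
#' @param k Hazard function `k(theta, theta_b)`, nonnegative.
#' @param theta_b Ratio at birth (lower integration limit).
#' @param x Optional uniform variate in `[0, 1)`; drawn internally when
#'   missing.
#' @param max_span Upper search limit for `theta_d - theta_b`.
#' @return The sampled division ratio `theta_d > theta_b`.
#' @export
hazard_sample_division <- function(k, theta_b, x = NULL, max_span = 10) {
  if (is.null(x)) x <- stats::runif(1)
  stopifnot(x >= 0, x < 1)
  if (x == 0) return(theta_b)
  target <- -log1p(-x)
  cum <- function(d) {
    stats::integrate(function(u) k(u, theta_b), theta_b, theta_b + d,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  hi <- max_span
  if (cum(hi) < target) {
    stop("hazard integral never reaches the sampled quantile; ",
         "the hazard is too small or not integrable")
  }
  root <- stats::uniroot(function(d) cum(d) - target, c(0, hi),
                         tol = 1e-10)$root
  theta_b + root
}
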