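## Core self-consistency solver. Finds F in [0, 1] with
##   total * (1 - F) = sum(wts * F * conc / (F * conc + K))
## The left side decreases strictly in F and the right side increases, so the
## root is unique. Safeguarded Newton with a bisection fallback; 'start' may
## carry a warm start from the previous integrator step.
.solve_fraction <- function(total, wts, K, conc, start = NULL,
                            tol = 1e-12, maxit = 200L) {
  if (total <= 0) return(0)        # no resource pool: F = 0 by convention
  keep <- wts > 0 & is.finite(K)
  wts <- wts[keep]; K <- K[keep]
  if (length(wts) == 0L || conc <= 0) return(1)   # no binding sinks
  g <- function(F) {
    x <- F * conc
    total * (1 - F) - sum(wts * x / (x + K))
  }
  gp <- function(F) {
    x <- F * conc
    -total - sum(wts * conc * K / (x + K)^2)
  }
  lo <- 0; hi <- 1
  F <- if (!is.null(start) && is.finite(start) && start > 0 && start < 1) {
    start
  } else 0.5
  for (it in seq_len(maxit)) {
    val <- g(F)
    if (abs(val) <= tol * max(total, 1)) return(F)
    if (val > 0) lo <- F else hi <- F
    step <- val / gp(F)
    Fn <- F - step
    if (!is.finite(Fn) || Fn <= lo || Fn >= hi) Fn <- (lo + hi) / 2
    if (abs(Fn - F) < 1e-15) return(Fn)
    F <- Fn
  }
  if (abs(g(F)) > 1e-6 * max(total, 1)) {
    stop("free-fraction solver failed to converge")
  }
  F
}

#' Free RNAP fraction
#'
#' Solves the RNAP conservation balance
#' `n (1 - F_n) = sum_i g_i (1 + Gamma_n_i L_i / v_n) F_n c_n / (F_n c_n + K_n_i)`
#' with the instantaneous nuclear concentration `c_n = a n / V`. The left side
#' (free RNAPs) decreases and the right side (promoter-bound plus elongating
#' RNAPs) increases with `F_n`, so the root is unique; it is found to
#' absolute tolerance 1e-12. `n = 0` returns 0 by convention so that division
#' events never leave the dynamics undefined.
#'
#' @param n Total RNAP copy number (>= 0).
#' @param V Cell volume, um^3.
#' @inheritParams volume_of
#' @return `F_n` in `[0, 1]`.
#' @export
solve_free_rnap_fraction <- function(n, V, genome, params) {
  stopifnot(n >= 0, V > 0)
  mod <- if (inherits(genome, "genome")) .compile_model(genome, params) else
    genome
  .check_calibrated(mod)
  .solve_fraction(n, mod$cap_n, mod$K_n, mod$a * n / V)
}

#' Free ribosome fraction
#'
#' Solves the ribosome conservation balance
#' `r (1 - F_r) = sum_i m_i (1 + Gamma_r_i L_i / v_r) F_r c_r / (F_r c_r + K_r_i)`
#' with the total cytoplasmic ribosome concentration
#' `c_r = r / (cytoplasm_fraction * V)`. Same contract as
#' [solve_free_rnap_fraction()].
#'
#' @param r Total ribosome copy number (>= 0).
#' @param m mRNA copy-number vector (one entry per gene class).
#' @inheritParams solve_free_rnap_fraction
#' @return `F_r` in `[0, 1]`.
#' @export
solve_free_ribosome_fraction <- function(r, m, V, genome, params) {
  stopifnot(r >= 0, V > 0)
  mod <- if (inherits(genome, "genome")) .compile_model(genome, params) else
    genome
  if (length(m) != length(mod$L)) {
    stop("mRNA vector does not match the number of gene classes")
  }
  .solve_fraction(r, pmax(m, 0) * mod$fac_r, mod$K_r,
                  r / (mod$cyto * V))
}

#' Quasi-steady mRNA copy numbers
#'
#' In the short-mRNA-lifetime limit the mRNA pool tracks the instantaneous
#' free-RNAP concentration:
#' `m_i = Gamma_n_i g_i tau_m_i F_n c_n / (F_n c_n + K_n_i)`,
#' with `c_n` the steady total RNAP concentration ([rnap_concentration()]).
#'
#' @param F_n Free RNAP fraction in `(0, 1]`.
#' @inheritParams volume_of
#' @return Numeric vector of mRNA copy numbers per class.
#' @export
quasi_steady_mrna <- function(F_n, genome, params) {
  stopifnot(F_n > 0, F_n <= 1)
  mod <- if (inherits(genome, "genome")) .compile_model(genome, params) else
    genome
  .check_calibrated(mod)
  tau_m <- 1 / mod$inv_tau_m
  if (any(!is.finite(tau_m))) {
    stop("quasi-steady mRNA requires finite mRNA lifetimes")
  }
  x <- F_n * mod$c_n
  mod$Gamma_n * mod$w * tau_m * x / (x + mod$K_n)
}
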