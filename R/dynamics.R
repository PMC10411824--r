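#' Construct a cell state
#'
#' A cell state holds the time and the per-class mRNA and protein copy
#' numbers (totals over lumped classes). The RNAP and ribosome protein
#' entries are the resource pools `n` and `r`.
#'
#' @param t Time, h.
#' @param m,p Numeric vectors of mRNA and protein copy numbers, one entry per
#'   gene class.
#' @param genome The [genome()] the vectors refer to (used for validation).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(t, m, p, genome = NULL) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (!is.null(genome)) {
    stopifnot(length(m) == length(genome$classes),
              length(p) == length(genome$classes))
  }
  if (any(!is.finite(m)) || any(!is.finite(p)) || any(m < 0) || any(p < 0)) {
    stop("cell state entries must be finite and nonnegative")
  }
  structure(list(t = t, m = as.numeric(m), p = as.numeric(p)),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> t = %g h, %d gene classes\n", x$t, length(x$m)))
  cat("  m:", format(signif(x$m, 4)), "\n")
  cat("  p:", format(signif(x$p, 4)), "\n")
  invisible(x)
}

## Internal RHS shared by state_derivative() and the integrator. 'cache' is an
## environment carrying warm starts for the two free-fraction solves.
.rhs <- function(m, p, mod, cache = NULL) {
  n <- p[mod$i_n]; r <- p[mod$i_r]
  V <- sum(p * mod$L) / mod$rho
  c_loc <- mod$a * n / V
  F_n <- .solve_fraction(n, mod$cap_n, mod$K_n, c_loc,
                         start = if (!is.null(cache)) cache$F_n)
  c_r <- r / (mod$cyto * V)
  F_r <- .solve_fraction(r, pmax(m, 0) * mod$fac_r, mod$K_r, c_r,
                         start = if (!is.null(cache)) cache$F_r)
  if (!is.null(cache)) { cache$F_n <- F_n; cache$F_r <- F_r }
  x_n <- F_n * c_loc
  x_r <- F_r * c_r
  dm <- mod$Gamma_n * mod$w * x_n / (x_n + mod$K_n) - m * mod$inv_tau_m
  dp <- mod$Gamma_r * pmax(m, 0) * x_r / (x_r + mod$K_r) - p * mod$inv_tau_p
  list(dm = dm, dp = dp, F_n = F_n, F_r = F_r, V = V)
}

#' Time derivative of the cell state
#'
#' Evaluates the gene-expression dynamics with the free RNAP and ribosome
#' fractions solved quasi-statically from the current state:
#' `dm_i/dt = Gamma_n_i g_i F_n c_n / (F_n c_n + K_n_i) - m_i / tau_m_i` and
#' `dp_i/dt = Gamma_r_i m_i F_r c_r / (F_r c_r + K_r_i) - p_i / tau_p_i`.
#' Infinite lifetimes contribute no degradation.
#'
#' @param state A [cell_state()].
#' @inheritParams volume_of
#' @return List with elements `dm`, `dp`, and the solved `F_n`, `F_r`, `V`.
#' @export
state_derivative <- function(state, genome, params) {
  mod <- if (inherits(genome, "genome")) .compile_model(genome, params) else
    genome
  .check_calibrated(mod)
  .rhs(state$m, state$p, mod)
}

#' Initialize a cell state at a target volume
#'
#' Builds a near-steady state at volume `V0`: the RNAP count from the steady
#' concentration (`n0 = c_n V0 / a`), other proteins from the steady
#' nondegradable copy-number ratios, and mRNAs at their quasi-steady values
#' for the implied free-RNAP fraction. A short burn-in is still required
#' before the periodic steady state is reached, but this start avoids long
#' transients.
#'
#' @param V0 Target volume, um^3.
#' @inheritParams volume_of
#' @return A [cell_state()] at `t = 0` with `volume_of(p) == V0` up to the
#'   neglected regulator mass.
#' @export
initialize_state <- function(V0, genome, params) {
  stopifnot(V0 > 0)
  mod <- .compile_model(genome, params)
  .check_calibrated(mod)
  n0 <- mod$c_n * V0 / mod$a
  if (n0 < 1) {
    warning("initial volume implies fewer than one RNAP (n(0) = ",
            signif(n0, 3), ")")
  }
  p <- mod$Gamma_n * mod$w / (mod$Gamma_n[mod$i_n] * mod$w[mod$i_n]) * n0
  p[mod$i_n] <- n0
  F_n <- .solve_fraction(n0, mod$cap_n, mod$K_n, mod$a * n0 / (sum(p * mod$L) / mod$rho))
  x <- F_n * mod$c_n
  tau_m <- 1 / mod$inv_tau_m
  m <- mod$Gamma_n * mod$w * tau_m * x / (x + mod$K_n)
  m[!is.finite(m)] <- 0
  cell_state(0, m, p)
}
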