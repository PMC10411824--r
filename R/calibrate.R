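#' Calibrate transcription initiation rates
#'
#' Fills in the per-class transcription initiation rates `Gamma_n_i` of a
#' skeleton genome so that three conditions hold simultaneously:
#'
#' 1. the ribosome-gene rate `Gamma_n_r` reproduces the attempted growth rate
#'    `mu` (setting the free-ribosome fraction to zero in the growth-rate
#'    balance, a numerical convenience that makes the calibration closed-form);
#' 2. the RNAP-gene rate satisfies `Gamma_n_n g_n = 0.1 * Gamma_n_r g_r`, so
#'    that the steady RNAP:ribosome copy-number ratio is 1:10;
#' 3. all remaining genes (bulk and regulators) share a common rate `Gamma_n`
#'    chosen so that the genome capacity [total_capacity()] equals
#'    `params$nc_target`.
#'
#' With every non-RNAP, non-ribosome gene of common length `L` the ribosome
#' rate takes the closed form
#' `Gamma_n_r = mu v_n (n_c - G) (1 + Gamma_r L / v_r) /
#'   (g_r (Gamma_r L - mu (1.1 L - 0.1 L_n - L_r)))`
#' where `G` is the total gene count; the implementation generalizes this to
#' heterogeneous lengths through the inverse mean length of those genes and
#' reduces to the closed form when lengths are equal.
#'
#' @inheritParams volume_of
#' @return The genome with all `Gamma_n` fields set.
#' @examples
#' gp <- default_genome()
#' total_capacity(gp$genome, gp$params)        # equals nc_target
#' steady_protein_ratio(gp$genome, "ribosome", gp$params)  # 10
#' @export
calibrate_rates <- function(genome, params) {
  mod <- .compile_model(genome, params)
  i_n <- mod$i_n; i_r <- mod$i_r
  other <- setdiff(seq_along(mod$w), c(i_n, i_r))
  if (length(other) == 0L) stop("genome has no genes besides RNAP and ribosome")
  Gamma_r <- mod$Gamma_r
  if (diff(range(Gamma_r)) > 1e-9 * Gamma_r[1]) {
    stop("calibration assumes a single shared translation initiation rate")
  }
  Gamma_r <- Gamma_r[1]
  G <- sum(mod$w)
  nc <- params$nc_target
  if (nc <= G) stop("nc_target must exceed the total gene count")
  v_n <- params$v_n; v_r <- params$v_r; mu <- params$mu
  L_n <- mod$L[i_n]; L_r <- mod$L[i_r]
  g_n <- mod$w[i_n]; g_r <- mod$w[i_r]
  ## lambda = inverse mean length of the shared-rate genes; equals 1/L when
  ## they share a common length
  lam <- sum(mod$w[other]) / sum(mod$w[other] * mod$L[other])
  den <- Gamma_r - mu * (1.1 - (0.1 * L_n + L_r) * lam)
  if (den <= 0) {
    stop("attempted growth rate too large: requires ",
         "Gamma_r > mu * (1.1 - (0.1 L_n + L_r) / L); reduce mu or ",
         "increase Gamma_r", call. = FALSE)
  }
  Gamma_nr <- unname(mu * v_n * (nc - G) * (lam + Gamma_r / v_r) /
                       (g_r * den))
  Gamma_nn <- unname(0.1 * Gamma_nr * g_r / g_n)
  ## shared rate for all other genes fixes the capacity at nc
  num <- (nc - G) * v_n - Gamma_nn * g_n * L_n - Gamma_nr * g_r * L_r
  if (num <= 0) {
    stop("capacity target infeasible: RNAP and ribosome genes alone ",
         "exceed nc_target", call. = FALSE)
  }
  Gamma_bulk <- unname(num / sum(mod$w[other] * mod$L[other]))
  out <- genome
  for (j in seq_along(out$classes)) {
    out$classes[[j]]$Gamma_n <-
      if (j == i_n) Gamma_nn else if (j == i_r) Gamma_nr else Gamma_bulk
  }
  out
}
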