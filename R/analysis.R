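#' Pearson correlation with a 95% confidence interval
#'
#' Pearson `R` with the Fisher-z 95% confidence interval, as used to test
#' whether division size is uncorrelated with birth size (sizer behavior).
#'
#' @param x,y Paired numeric vectors (>= 4 finite pairs).
#' @return List with `r`, `ci` (length-2), `n`.
#' @export
pearson_with_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, conf.level = 0.95)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), n = length(x))
}

#' Equal-count binned linear regression
#'
#' Sorts by `x`, splits the data into `n_bins` bins of (near-)equal counts,
#' and fits ordinary least squares to the bin means; the slope summarizes the
#' trend robustly against the marginal distribution of `x`. Ties are kept in
#' input order (stable sort).
#'
#' @param x,y Paired numeric vectors.
#' @param n_bins Number of equal-count bins (default 10).
#' @return An object of class `binned_fit`: bin centers/means/SEMs, `slope`,
#'   `intercept`, `n_bins`.
#' @export
binned_regression <- function(x, y, n_bins = 10) {
  stopifnot(n_bins >= 2, length(x) == length(y), length(x) >= n_bins)
  ord <- order(x)            # stable: ties stay in input order
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep.int(seq_len(n_bins), sizes)
  bc <- tapply(x, grp, mean)
  bm <- tapply(y, grp, mean)
  bs <- tapply(y, grp, function(v) stats::sd(v) / sqrt(length(v)))
  fit <- stats::lm(bm ~ bc)
  structure(list(bin_centers = as.numeric(bc), bin_means = as.numeric(bm),
                 bin_sems = as.numeric(bs),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_bins = as.integer(n_bins)),
            class = "binned_fit")
}

#' @export
print.binned_fit <- function(x, ...) {
  cat(sprintf("<binned_fit> %d equal-count bins: slope %.4g, intercept %.4g\n",
              x$n_bins, x$slope, x$intercept))
  invisible(x)
}

#' Lineage size summary
#'
#' Mean, sample SD and CV of the birth volume, division volume and cycle
#' duration of a lineage (sample, n-1, standard deviations).
#'
#' @param records A [simulate_lineage()] result or its `records` data.frame
#'   (columns `V_b`, `V_d`, `T_D`).
#' @return A data.frame with one row per quantity.
#' @export
size_summary <- function(records) {
  if (inherits(records, "cell_lineage")) records <- records$records
  if (is.null(records) || nrow(records) < 2L) {
    stop("need at least two recorded generations")
  }
  one <- function(v) c(mean = mean(v), sd = stats::sd(v),
                       cv = stats::sd(v) / mean(v))
  out <- rbind(V_b = one(records$V_b), V_d = one(records$V_d),
               T_D = one(records$T_D))
  as.data.frame(out)
}

#' Compare a mutant lineage with wild type
#'
#' Relative changes of the mean and CV of the birth size:
#' `delta_mean = (<V_b,mut> - <V_b,wt>) / <V_b,wt>` and
#' `delta_cv = (CV_mut - CV_wt) / CV_wt`. With several redundant regulators
#' a single deletion shifts the mean appreciably while leaving the CV almost
#' unchanged.
#'
#' @param wt,mutant Lineages (or record data.frames) for the two genotypes.
#' @return An object of class `mutant_comparison` with `delta_mean` and
#'   `delta_cv`.
#' @export
mutant_comparison <- function(wt, mutant) {
  sw <- size_summary(wt); sm <- size_summary(mutant)
  if (sw["V_b", "mean"] == 0 || sw["V_b", "cv"] == 0) {
    stop("wild-type mean or CV is zero")
  }
  structure(list(
    delta_mean = (sm["V_b", "mean"] - sw["V_b", "mean"]) / sw["V_b", "mean"],
    delta_cv = (sm["V_b", "cv"] - sw["V_b", "cv"]) / sw["V_b", "cv"]),
    class = "mutant_comparison")
}

#' @export
print.mutant_comparison <- function(x, ...) {
  cat(sprintf("<mutant_comparison> delta<V_b> = %+.3g, delta_CV = %+.3g\n",
              x$delta_mean, x$delta_cv))
  invisible(x)
}
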