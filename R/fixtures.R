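#' Default calibrated model
#'
#' Builds the reference parameterization: one RNAP gene, one ribosome gene,
#' cell-cycle regulators with `K_act = 12000` and (single-pair) `K_inh =
#' 4000` um^-3, and 5000 bulk genes of 400 codons lumped into one class with
#' `K_n = 6000` um^-3, all calibrated with [calibrate_rates()] so that the
#' genome capacity is `n_c = 1e4` and the attempted growth rate is
#' `ln(2)/2` per hour (with the RNAP:ribosome ratio 1:10). Options select the
#' multi-regulator panel (`g_act = g_inh = 10` with `K_inh = 1000` um^-3),
#' a lognormal spread of bulk promoter strengths, and a nondegradable
#' inhibitor.
#'
#' @param regulators `"single"` (one activator, one inhibitor) or `"panel"`
#'   (10 of each, with the stronger default inhibitor promoter of the
#'   multi-regulator experiments).
#' @param K_act,K_inh Regulator MM constants, um^-3 (`K_inh` defaults to
#'   4000 for `"single"`, 1000 for `"panel"`).
#' @param chi_act,chi_inh Optional per-regulator weight vectors for the panel
#'   (recycled to 10).
#' @param heterogeneous_bulk If `TRUE`, replace the single bulk class by
#'   `n_bulk_classes` classes whose `K_n` are lognormal with mean 6000 and
#'   the given CV ([sample_heterogeneous_affinities()]).
#' @param n_bulk_classes,bulk_cv,bulk_seed Heterogeneous-bulk options.
#' @param nondegradable_inhibitor If `TRUE`, the inhibitor protein lifetime
#'   is infinite.
#' @param tau_p Regulator protein lifetime, h.
#' @param ploidy Genome ploidy (applied after calibration, so the haploid
#'   capacity is `nc_target`).
#' @param params A [global_params()] (defaults documented there).
#' @return `list(genome, params)` with the genome calibrated.
#' @export
default_genome <- function(regulators = c("single", "panel"),
                           K_act = 12000, K_inh = NULL,
                           chi_act = 1, chi_inh = 1,
                           heterogeneous_bulk = FALSE, n_bulk_classes = 50,
                           bulk_cv = 0.5, bulk_seed = 1,
                           nondegradable_inhibitor = FALSE,
                           tau_p = 1 / 120, ploidy = 1,
                           params = global_params()) {
  regulators <- match.arg(regulators)
  n_reg <- if (regulators == "panel") 10L else 1L
  if (is.null(K_inh)) K_inh <- if (regulators == "panel") 1000 else 4000
  chi_act <- rep_len(chi_act, n_reg)
  chi_inh <- rep_len(chi_inh, n_reg)
  cls <- list(
    gene_class("rnap", "rnap", length = 4000, K_n = 6000),
    gene_class("ribosome", "ribosome", length = 7000, K_n = 6000))
  for (j in seq_len(n_reg)) {
    suffix <- if (n_reg > 1L) as.character(j) else ""
    cls <- c(cls, list(
      gene_class(paste0("act", suffix), "activator", K_n = K_act,
                 tau_p = tau_p, chi = chi_act[j]),
      gene_class(paste0("inh", suffix), "inhibitor", K_n = K_inh,
                 tau_p = if (nondegradable_inhibitor) Inf else tau_p,
                 chi = chi_inh[j])))
  }
  if (heterogeneous_bulk) {
    Ks <- sample_heterogeneous_affinities(n_bulk_classes, mean = 6000,
                                          cv = bulk_cv, seed = bulk_seed)
    per <- 5000 / n_bulk_classes
    for (j in seq_len(n_bulk_classes)) {
      cls <- c(cls, list(gene_class(paste0("bulk", j), "bulk",
                                    multiplicity = per, K_n = Ks[j])))
    }
  } else {
    cls <- c(cls, list(gene_class("bulk", "bulk", multiplicity = 5000)))
  }
  g <- calibrate_rates(genome(cls, ploidy = 1L), params)
  g$ploidy <- as.numeric(ploidy)
  list(genome = g, params = params)
}

#' Lognormal promoter-affinity sample
#'
#' Draws `n` transcription MM constants from a lognormal distribution with
#' the requested arithmetic mean and coefficient of variation (the
#' heterogeneous-promoter genome variant).
#'
#' @param n Number of classes.
#' @param mean Arithmetic mean, um^-3.
#' @param cv Coefficient of variation (0 gives constant values).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_heterogeneous_affinities <- function(n, mean = 6000, cv = 0.5,
                                            seed = NULL) {
  stopifnot(mean > 0, cv >= 0)
  if (cv == 0) return(rep(mean, n))
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Run a canned experiment
#'
#' Drives the simulator over a parameter sweep and writes per-point CSV
#' results plus a JSON manifest (inputs, seeds, package version) into
#' `out_dir`. Experiments:
#' \describe{
#'   \item{`theta_sweep`}{deterministic lineages over a threshold grid,
#'     recording simulated and theoretical `V_b` and amplitude.}
#'   \item{`ploidy`}{haploid vs diploid deterministic lineages over a
#'     threshold grid, recording the birth-volume ratio.}
#'   \item{`mutant_panel`}{stochastic lineages for the multi-regulator wild
#'     type, one-activator deletion and one-inhibitor deletion, recording
#'     size summaries and relative changes.}
#' }
#' Points at which the cell cannot divide are recorded as
#' `failed_no_division` rows rather than errors.
#'
#' @param name Experiment name (see Details).
#' @param out_dir Output directory (created if needed).
#' @param theta_grid Threshold grid (defaults per experiment).
#' @param theta_bar,delta_theta Stochastic threshold parameters
#'   (`mutant_panel`).
#' @param n_generations Recorded generations per lineage.
#' @param seed Integer seed.
#' @param model `list(genome, params)` as from [default_genome()]; defaults
#'   to the experiment's standard parameterization.
#' @return Invisibly, the list of result data.frames (also written to disk).
#' @export
run_experiment <- function(name = c("theta_sweep", "ploidy", "mutant_panel"),
                           out_dir, theta_grid = NULL, theta_bar = 0.45,
                           delta_theta = 0.1, n_generations = 50,
                           seed = 1, model = NULL) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- switch(name,
    theta_sweep = .exp_theta_sweep(model, theta_grid, n_generations, seed),
    ploidy = .exp_ploidy(model, theta_grid, n_generations, seed),
    mutant_panel = .exp_mutants(model, theta_bar, delta_theta,
                                n_generations, seed))
  for (nm in names(results)) {
    utils::write.csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(experiment = name, seed = seed,
                   theta_grid = theta_grid, theta_bar = theta_bar,
                   delta_theta = delta_theta, n_generations = n_generations,
                   package_version = as.character(utils::packageVersion("cellsizer")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

.exp_theta_sweep <- function(model, theta_grid, n_generations, seed) {
  if (is.null(model)) model <- default_genome()
  ti <- theory_inputs(model$genome, model$params)
  th <- critical_thresholds(ti)
  if (is.null(theta_grid)) {
    w <- th[2] - th[1]
    theta_grid <- seq(th[1] + 0.1 * w, th[2] - 0.1 * w, length.out = 8)
  }
  rows <- lapply(theta_grid, function(theta) {
    rule <- division_rule("ratio", theta = theta)
    lin <- simulate_lineage(model$genome, model$params, rule,
                            n_generations = max(3, min(n_generations, 5)),
                            seed = seed, burn_in = 8)
    inside <- theta > th[1] && theta < th[2]
    data.frame(theta = theta, status = lin$status,
               V_b_sim = if (lin$status == "steady")
                 mean(lin$records$V_b) else NA_real_,
               A_sim = if (lin$status == "steady")
                 mean(lin$records$theta_k - lin$records$ratio_min) else
                   NA_real_,
               V_b_theory = if (inside) birth_volume(theta, ti) else NA_real_,
               A_theory = if (inside) amplitude(theta, ti) else NA_real_)
  })
  list(theta_sweep = do.call(rbind, rows))
}

.exp_ploidy <- function(model, theta_grid, n_generations, seed) {
  if (is.null(model)) model <- default_genome()
  ti <- theory_inputs(model$genome, model$params)
  th <- critical_thresholds(ti)
  if (is.null(theta_grid)) theta_grid <- seq(0.6, 0.8, by = 0.1)
  rows <- lapply(theta_grid, function(theta) {
    rule <- division_rule("ratio", theta = theta)
    sim1 <- simulate_lineage(model$genome, model$params, rule, 3,
                             seed = seed, burn_in = 8)
    g2 <- model$genome; g2$ploidy <- g2$ploidy * 2
    sim2 <- simulate_lineage(g2, model$params, rule, 3, seed = seed,
                             burn_in = 8)
    ok <- sim1$status == "steady" && sim2$status == "steady"
    data.frame(theta = theta,
               status = if (ok) "steady" else "failed_no_division",
               V_b_haploid = if (ok) mean(sim1$records$V_b) else NA_real_,
               V_b_diploid = if (ok) mean(sim2$records$V_b) else NA_real_,
               ratio = if (ok) mean(sim2$records$V_b) /
                 mean(sim1$records$V_b) else NA_real_)
  })
  list(ploidy = do.call(rbind, rows))
}

.exp_mutants <- function(model, theta_bar, delta_theta, n_generations,
                         seed) {
  if (is.null(model)) model <- default_genome("panel")
  rule <- division_rule("ratio", theta_bar = theta_bar,
                        delta_theta = delta_theta)
  genomes <- list(WT = model$genome,
                  actD = delete_regulators(model$genome, "act1"),
                  inhD = delete_regulators(model$genome, "inh1"))
  lins <- lapply(seq_along(genomes), function(i) {
    simulate_lineage(genomes[[i]], model$params, rule, n_generations,
                     seed = seed + i - 1L, burn_in = 10)
  })
  names(lins) <- names(genomes)
  summ <- do.call(rbind, lapply(names(lins), function(nm) {
    s <- size_summary(lins[[nm]])
    data.frame(genotype = nm, mean_V_b = s["V_b", "mean"],
               cv_V_b = s["V_b", "cv"], status = lins[[nm]]$status)
  }))
  cmp <- do.call(rbind, lapply(c("actD", "inhD"), function(nm) {
    mc <- mutant_comparison(lins$WT, lins[[nm]])
    data.frame(genotype = nm, delta_mean = mc$delta_mean,
               delta_cv = mc$delta_cv)
  }))
  list(mutant_summary = summ, mutant_comparison = cmp)
}
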