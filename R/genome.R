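#' Define a gene class
#'
#' A gene class describes one gene, or a lump of identical genes, in the
#' whole-cell gene-expression model. Transcription of each gene is initiated by
#' free RNA polymerase (RNAP) through a Michaelis-Menten (MM) step with
#' constant `K_n` (small `K_n` = strong promoter), and translation of each
#' mRNA by free ribosomes with MM constant `K_r`. Cell-cycle regulators are
#' distinguished by their `role`: the division rule monitors the concentration
#' ratio of activators (weak promoters, superlinear size scaling) to
#' inhibitors (strong promoters, sublinear scaling).
#'
#' @param label Short unique name.
#' @param role One of `"rnap"`, `"ribosome"`, `"activator"`, `"inhibitor"`,
#'   `"bulk"`.
#' @param copy_number Gene copy number `g` (per haploid genome), positive
#'   integer.
#' @param multiplicity Number of identical genes this class lumps together
#'   (the model treats `copy_number * multiplicity` gene copies with shared
#'   parameters; `m` and `p` entries for the class are totals over the lump).
#' @param length Gene length `L` in codons.
#' @param K_n Transcription-initiation MM constant, um^-3.
#' @param Gamma_n Transcription initiation rate per promoter-bound RNAP, h^-1.
#'   May be `NA` before [calibrate_rates()] is applied.
#' @param K_r Translation-initiation MM constant, um^-3.
#' @param Gamma_r Translation initiation rate, h^-1.
#' @param tau_m mRNA lifetime, h (`Inf` = nondegradable).
#' @param tau_p Protein lifetime, h (`Inf` = nondegradable).
#' @param chi Division-rule weight for regulator classes (default 1).
#'
#' @return An object of class `gene_class` (a named list).
#' @seealso [genome()], [calibrate_rates()], [default_genome()]
#' @export
gene_class <- function(label, role = c("bulk", "rnap", "ribosome", "activator",
                                       "inhibitor"),
                       copy_number = 1L, multiplicity = 1L, length = 400,
                       K_n = 6000, Gamma_n = NA_real_, K_r = 1e4,
                       Gamma_r = 3600, tau_m = 1 / 120, tau_p = Inf, chi = 1) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  num_pos <- function(x, name, allow_inf = FALSE, allow_na = FALSE) {
    if (allow_na && is.na(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!allow_inf && !is.finite(x)) || x <= 0) {
      stop(sprintf("'%s' must be a positive %s number", name,
                   if (allow_inf) "(possibly infinite)" else "finite"),
           call. = FALSE)
    }
    invisible(NULL)
  }
  num_pos(copy_number, "copy_number")
  num_pos(multiplicity, "multiplicity")
  num_pos(length, "length")
  num_pos(K_n, "K_n")
  num_pos(Gamma_n, "Gamma_n", allow_na = TRUE)
  num_pos(K_r, "K_r")
  num_pos(Gamma_r, "Gamma_r")
  num_pos(tau_m, "tau_m", allow_inf = TRUE)
  num_pos(tau_p, "tau_p", allow_inf = TRUE)
  stopifnot(is.numeric(chi), length(chi) == 1L, chi >= 0)
  structure(list(label = label, role = role,
                 copy_number = as.numeric(copy_number),
                 multiplicity = as.numeric(multiplicity),
                 length = as.numeric(length),
                 K_n = K_n, Gamma_n = Gamma_n, K_r = K_r, Gamma_r = Gamma_r,
                 tau_m = tau_m, tau_p = tau_p, chi = chi),
            class = "gene_class")
}

#' Assemble a genome from gene classes
#'
#' A genome is an ordered list of [gene_class()] objects plus a ploidy
#' multiplier applied to every copy number. Exactly one RNAP class and one
#' ribosome class are required; these two proteins are the limiting shared
#' resources of transcription and translation.
#'
#' @param classes List of [gene_class()] objects with unique labels.
#' @param ploidy Positive integer multiplier on all gene copy numbers.
#' @return An object of class `genome`.
#' @export
genome <- function(classes, ploidy = 1L) {
  stopifnot(is.list(classes), length(classes) >= 1L)
  ok <- vapply(classes, inherits, logical(1), "gene_class")
  if (!all(ok)) stop("all elements of 'classes' must be gene_class objects")
  labels <- vapply(classes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("gene class labels must be unique")
  roles <- vapply(classes, `[[`, character(1), "role")
  if (sum(roles == "rnap") != 1L) stop("genome needs exactly one 'rnap' class")
  if (sum(roles == "ribosome") != 1L) {
    stop("genome needs exactly one 'ribosome' class")
  }
  stopifnot(is.numeric(ploidy), length(ploidy) == 1L, ploidy >= 1,
            ploidy == round(ploidy))
  names(classes) <- labels
  structure(list(classes = classes, ploidy = as.numeric(ploidy)),
            class = "genome")
}

#' Global parameters of the whole-cell model
#'
#' @param a Ratio of cell volume to nuclear volume (dimensionless); total
#'   nuclear RNAP concentration is `a * n / V`.
#' @param rho Protein mass per cell volume, amino acids per um^3; the cell
#'   volume is the total protein mass divided by `rho`.
#' @param v_n RNAP elongation speed, codons h^-1.
#' @param v_r Ribosome elongation speed, codons h^-1.
#' @param mu Attempted exponential growth rate, h^-1 (used by
#'   [calibrate_rates()]).
#' @param nc_target Target genome capacity `n_c`: the maximum number of RNAPs
#'   the whole genome can hold (promoter-bound plus elongating).
#' @param cytoplasm_fraction Fraction of the cell volume in which ribosomes
#'   and mRNAs mix; the total ribosome concentration is
#'   `r / (cytoplasm_fraction * V)`.
#' @return An object of class `global_params`.
#' @export
global_params <- function(a = 7, rho = 3.5e9, v_n = 7200, v_r = 7200,
                          mu = log(2) / 2, nc_target = 1e4,
                          cytoplasm_fraction = 1) {
  vals <- c(a = a, rho = rho, v_n = v_n, v_r = v_r, mu = mu,
            nc_target = nc_target, cytoplasm_fraction = cytoplasm_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all global parameters must be positive finite numbers")
  }
  if (cytoplasm_fraction > 1) stop("cytoplasm_fraction must be <= 1")
  structure(as.list(vals), class = "global_params")
}

## Internal: flatten a genome + params into the numeric vectors used by every
## solver. Copy numbers are expanded by multiplicity and ploidy (w). Returned
## once and reused throughout a simulation.
.compile_model <- function(genome, params) {
  cl <- genome$classes
  role <- vapply(cl, `[[`, character(1), "role")
  get <- function(f) vapply(cl, `[[`, numeric(1), f)
  w <- get("copy_number") * get("multiplicity") * genome$ploidy
  L <- get("length")
  K_n <- get("K_n"); Gamma_n <- get("Gamma_n")
  K_r <- get("K_r"); Gamma_r <- get("Gamma_r")
  cap_n <- w * (1 + ifelse(is.na(Gamma_n), 0, Gamma_n) * L / params$v_n)
  fac_r <- 1 + Gamma_r * L / params$v_r
  i_n <- which(role == "rnap"); i_r <- which(role == "ribosome")
  i_act <- which(role == "activator"); i_inh <- which(role == "inhibitor")
  denom <- sum(Gamma_n * w * L)
  c_n <- if (is.na(denom) || denom <= 0) NA_real_ else {
    unname(params$a * params$rho * Gamma_n[i_n] * w[i_n] / denom)
  }
  list(labels = names(cl), role = role, w = w, L = L,
       K_n = K_n, Gamma_n = Gamma_n, K_r = K_r, Gamma_r = Gamma_r,
       inv_tau_m = 1 / get("tau_m"), inv_tau_p = 1 / get("tau_p"),
       chi = get("chi"), cap_n = cap_n, fac_r = fac_r,
       i_n = i_n, i_r = i_r, i_act = i_act, i_inh = i_inh,
       nc = sum(cap_n), c_n = c_n,
       a = params$a, rho = params$rho, v_n = params$v_n, v_r = params$v_r,
       cyto = params$cytoplasm_fraction)
}

.check_calibrated <- function(mod) {
  if (anyNA(mod$Gamma_n)) {
    stop("genome has unset transcription initiation rates; ",
         "run calibrate_rates() first", call. = FALSE)
  }
}

#' Cell volume implied by a protein vector
#'
#' The cell volume is proportional to the total protein mass,
#' `V = sum(p_i * L_i) / rho`, with `p_i` the total protein copy number of
#' class `i` and `L_i` its length in codons.
#'
#' @param p Numeric vector of protein copy numbers, one entry per gene class
#'   (totals over lumped classes).
#' @param genome,params A [genome()] and [global_params()].
#' @return Volume in um^3.
#' @export
volume_of <- function(p, genome, params) {
  mod <- if (is.list(genome) && !inherits(genome, "genome")) genome else
    .compile_model(genome, params)
  if (length(p) != length(mod$L)) {
    stop("protein vector does not match the number of gene classes")
  }
  if (all(p == 0)) stop("all-zero protein vector has no defined volume")
  sum(p * mod$L) / mod$rho
}

#' Genome capacity for RNAPs
#'
#' The maximum number of RNAPs the genome can hold at once:
#' `n_c = sum_i g_i (1 + Gamma_n_i L_i / v_n)` over the expanded gene set
#' (one promoter-bound RNAP per gene copy plus the elongating RNAPs it can
#' carry). Scales linearly with ploidy.
#'
#' @inheritParams volume_of
#' @return The capacity `n_c` (a count).
#' @export
total_capacity <- function(genome, params) {
  mod <- .compile_model(genome, params)
  .check_calibrated(mod)
  mod$nc
}

#' Steady-state total RNAP concentration
#'
#' In the growing cell the nuclear concentration of total RNAPs is
#' approximately constant:
#' `c_n = a * rho * Gamma_n_n g_n / sum_i Gamma_n_i g_i L_i`.
#' It is invariant under ploidy doubling (all copy numbers scale together).
#'
#' @inheritParams volume_of
#' @return `c_n` in um^-3.
#' @export
rnap_concentration <- function(genome, params) {
  mod <- .compile_model(genome, params)
  .check_calibrated(mod)
  if (!is.finite(mod$c_n)) stop("zero denominator in RNAP concentration")
  mod$c_n
}

#' Steady copy-number ratio of a nondegradable protein to RNAP
#'
#' For nondegradable proteins the copy-number ratio to RNAP converges to
#' `Gamma_n_i g_i / (Gamma_n_n g_n)`: gene dosage times initiation rate is all
#' that distinguishes stable proteins, because the shared free-RNAP and
#' free-ribosome factors cancel.
#'
#' @inheritParams volume_of
#' @param class Label (or index) of the gene class.
#' @return The ratio `p_i / n`.
#' @export
steady_protein_ratio <- function(genome, class, params) {
  mod <- .compile_model(genome, params)
  .check_calibrated(mod)
  i <- if (is.character(class)) match(class, mod$labels) else as.integer(class)
  if (is.na(i) || i < 1L || i > length(mod$w)) stop("unknown gene class")
  if (is.finite(1 / mod$inv_tau_p[i]) && mod$inv_tau_p[i] > 0) {
    stop("steady_protein_ratio applies only to nondegradable proteins; class '",
         mod$labels[i], "' has a finite protein lifetime", call. = FALSE)
  }
  unname(mod$Gamma_n[i] * mod$w[i] /
           (mod$Gamma_n[mod$i_n] * mod$w[mod$i_n]))
}

#' @export
print.gene_class <- function(x, ...) {
  cat(sprintf("<gene_class '%s' (%s)> g=%g x%g, L=%g codons, K_n=%g um^-3\n",
              x$label, x$role, x$copy_number, x$multiplicity, x$length, x$K_n))
  cat(sprintf("  Gamma_n=%s /h, Gamma_r=%g /h, K_r=%g um^-3, tau_m=%g h, tau_p=%g h, chi=%g\n",
              format(x$Gamma_n), x$Gamma_r, x$K_r, x$tau_m, x$tau_p, x$chi))
  invisible(x)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d gene classes, ploidy %g\n",
              length(x$classes), x$ploidy))
  for (cl in x$classes) {
    cat(sprintf("  %-10s %-9s g=%-5g x%-6g L=%-5g K_n=%-7g Gamma_n=%s\n",
                cl$label, cl$role, cl$copy_number, cl$multiplicity, cl$length,
                cl$K_n, format(cl$Gamma_n, digits = 5)))
  }
  invisible(x)
}

#' @export
print.global_params <- function(x, ...) {
  cat("<global_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}
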