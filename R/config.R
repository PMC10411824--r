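#' Read and write model configurations
#'
#' A configuration file stores one [global_params()] set plus a [genome()]
#' (ploidy and gene classes) in YAML (`.yml`/`.yaml`) or JSON (`.json`).
#' All fields use the SI-style units documented in [gene_class()] and
#' [global_params()]; infinite lifetimes are serialized as the string
#' `"Inf"` in JSON and `.inf` in YAML.
#'
#' @param genome,params Objects to serialize.
#' @param path File path; the extension selects the dialect.
#' @return `read_model_config()` returns `list(genome, params)`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
write_model_config <- function(genome, params, path) {
  stopifnot(inherits(genome, "genome"), inherits(params, "global_params"))
  cls <- lapply(genome$classes, function(cl) {
    cl <- unclass(cl)
    cl$tau_m <- if (is.finite(cl$tau_m)) cl$tau_m else "Inf"
    cl$tau_p <- if (is.finite(cl$tau_p)) cl$tau_p else "Inf"
    cl
  })
  obj <- list(params = unclass(params),
              ploidy = genome$ploidy,
              classes = unname(cls))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(obj, precision = 15L), path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_num <- function(x) if (identical(x, "Inf")) Inf else as.numeric(x)
  params <- do.call(global_params, lapply(obj$params, as.numeric))
  classes <- lapply(obj$classes, function(cl) {
    gene_class(label = cl$label, role = cl$role,
               copy_number = as.numeric(cl$copy_number),
               multiplicity = as.numeric(cl$multiplicity),
               length = as.numeric(cl$length),
               K_n = as.numeric(cl$K_n),
               Gamma_n = if (is.null(cl$Gamma_n)) NA_real_ else
                 as.numeric(cl$Gamma_n),
               K_r = as.numeric(cl$K_r), Gamma_r = as.numeric(cl$Gamma_r),
               tau_m = as_num(cl$tau_m), tau_p = as_num(cl$tau_p),
               chi = as.numeric(cl$chi))
  })
  list(genome = genome(classes, ploidy = as.numeric(obj$ploidy)),
       params = params)
}
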