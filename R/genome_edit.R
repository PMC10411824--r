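#' Delete regulator genes
#'
#' Removes the named regulator classes (or decrements their multiplicity when
#' they lump several identical genes). At least one activator and one
#' inhibitor must remain for the ratio division rule to stay defined.
#'
#' @inheritParams volume_of
#' @param labels Character vector of gene class labels to delete (one gene
#'   each).
#' @return The edited genome.
#' @export
delete_regulators <- function(genome, labels) {
  out <- genome
  for (lab in labels) {
    i <- match(lab, names(out$classes))
    if (is.na(i)) stop("no gene class labelled '", lab, "'")
    role <- out$classes[[i]]$role
    if (!role %in% c("activator", "inhibitor")) {
      stop("'", lab, "' is not a regulator class")
    }
    if (out$classes[[i]]$multiplicity > 1) {
      out$classes[[i]]$multiplicity <- out$classes[[i]]$multiplicity - 1
    } else {
      out$classes[[i]] <- NULL
    }
  }
  roles <- vapply(out$classes, `[[`, character(1), "role")
  if (!any(roles == "activator") || !any(roles == "inhibitor")) {
    stop("deletion would remove the last activator or inhibitor")
  }
  out
}

#' Swap the promoters of an activator and an inhibitor
#'
#' Exchanges the transcription MM constants `K_n` of the two named classes,
#' leaving every other field untouched (the in-silico analogue of a promoter
#' exchange experiment).
#'
#' @inheritParams volume_of
#' @param act_label,inh_label Labels of the two classes.
#' @return The edited genome.
#' @export
swap_promoters <- function(genome, act_label, inh_label) {
  ia <- match(act_label, names(genome$classes))
  ii <- match(inh_label, names(genome$classes))
  if (is.na(ia) || is.na(ii)) stop("unknown gene class label")
  out <- genome
  ka <- out$classes[[ia]]$K_n
  out$classes[[ia]]$K_n <- out$classes[[ii]]$K_n
  out$classes[[ii]]$K_n <- ka
  out
}

#' Equivalent single-pair threshold of a multi-regulator rule
#'
#' With `g_act` activators and `g_inh` inhibitors sharing promoter strengths,
#' the multi-regulator division condition maps onto the single-pair model at
#' the equivalent threshold `theta_tilde = (g_inh / g_act) * theta`
#' (weighted: `sum(chi_inh) / sum(chi_act) * theta`). Deleting one activator
#' therefore raises the equivalent threshold to `g_inh / (g_act - 1) * theta`
#' and enlarges the cell.
#'
#' @param g_act,g_inh Numbers of activator and inhibitor genes.
#' @param theta Threshold of the multi-regulator rule.
#' @param chi_act,chi_inh Optional per-regulator weights.
#' @return The equivalent threshold `theta_tilde`.
#' @export
equivalent_threshold <- function(g_act, g_inh, theta,
                                 chi_act = NULL, chi_inh = NULL) {
  if (is.null(chi_act)) chi_act <- rep(1, g_act)
  if (is.null(chi_inh)) chi_inh <- rep(1, g_inh)
  if (sum(chi_act) <= 0) stop("zero total activator weight")
  sum(chi_inh) / sum(chi_act) * theta
}
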