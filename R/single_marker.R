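#' Bonferroni selection over a family of P-values
#'
#' Selects tests with `P < level / m`, where `m` counts the converged
#' tests only (`NA` P-values, e.g. from non-converged fits, are excluded
#' from both the family size and the selection).
#'
#' @param pvals P-value vector (may contain `NA`).
#' @param level family-wise error rate.
#' @return A list with `method`, `level`, `m`, `cutoff` and `selected`
#'   (indices into `pvals`).
#' @export
bonferroni_select <- function(pvals, level = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- sum(!is.na(pvals))
  cutoff <- if (m > 0) level / m else 0
  list(method = "BON", level = level, m = m, cutoff = cutoff,
       selected = which(!is.na(pvals) & pvals < cutoff))
}

#' Benjamini-Hochberg selection over a family of P-values
#'
#' The step-up rule at FDR level `q`: with the `m` non-missing P-values
#' sorted ascending, `k* = max{i : P_(i) <= i q / m}` and the `k*`
#' smallest are selected. Implemented through [stats::p.adjust()], whose
#' BH-adjusted values are at most `q` exactly for the step-up set.
#'
#' @param pvals P-value vector (may contain `NA`).
#' @param q FDR level.
#' @return A list with `method`, `level`, `m`, `cutoff` (the largest
#'   selected raw P, or 0) and `selected` (indices into `pvals`).
#' @export
bh_select <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- sum(!is.na(pvals))
  adj <- p.adjust(pvals, method = "BH")
  selected <- which(!is.na(adj) & adj <= q)
  cutoff <- if (length(selected)) max(pvals[selected]) else 0
  list(method = "BH", level = q, m = m, cutoff = cutoff,
       selected = selected)
}
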