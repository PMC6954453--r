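#' Assemble a sample table
#'
#' Bundles the trait, the environmental exposure and an optional covariate
#' block for `n` subjects. Use [prepare_samples()] before passing the table
#' to any scan or test.
#'
#' @param y per-subject trait: continuous for `family = "gaussian"`, 0/1
#'   for `family = "binomial"`.
#' @param e per-subject exposure: 0/1 binary, or continuous (rescaled to
#'   `[0, 1]` during preparation).
#' @param x optional n x p covariate matrix or data frame.
#' @param family trait family.
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(y, e, x = NULL,
                         family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y <- as.numeric(y)
  e <- as.numeric(e)
  stopifnot(length(y) == length(e))
  if (!is.null(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    stopifnot(nrow(x) == length(y))
  }
  if (family == "binomial" && !all(y[!is.na(y)] %in% c(0, 1))) {
    stop("binomial trait must take values in {0, 1}")
  }
  obj <- list(y = y, e = e, x = x, family = family, prepared = FALSE,
              n_dropped = 0L, keep = seq_along(y))
  class(obj) <- "sample_table"
  obj
}

#' Rescale an environmental exposure to the unit interval
#'
#' Binary 0/1 exposures pass through unchanged. Continuous exposures are
#' affinely mapped so the sample minimum becomes 0 and the maximum 1;
#' missing entries stay missing.
#'
#' @param e exposure vector.
#' @return The rescaled exposure.
#' @export
scale_environment <- function(e) {
  obs <- e[!is.na(e)]
  if (all(obs %in% c(0, 1))) return(e)
  rng <- range(obs)
  if (diff(rng) == 0) {
    stop("constant continuous exposure: interaction is inestimable")
  }
  (e - rng[1]) / diff(rng)
}

#' Standardize a continuous trait
#'
#' Centers and scales to sample mean 0 and sample SD 1 (n - 1 denominator).
#' Applied on the ADABF path only, so that the default prior variance for
#' interaction coefficients refers to a unit-variance trait; risk-score
#' models stay on the raw trait scale.
#'
#' @param y continuous trait vector (may contain `NA`).
#' @return The standardized trait.
#' @export
standardize_trait <- function(y) {
  s <- sd(y, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("trait has zero variance: cannot standardize")
  (y - mean(y, na.rm = TRUE)) / s
}

#' Prepare a sample table for analysis
#'
#' Drops subjects missing the trait, the exposure or any covariate
#' (listwise), then rescales a continuous exposure to `[0, 1]` using the
#' post-deletion sample. When `standardize = TRUE` (the ADABF path for
#' continuous traits) the trait is additionally standardized to mean 0,
#' SD 1.
#'
#' @param s a [sample_table()].
#' @param standardize standardize a gaussian trait?
#' @return The prepared `sample_table`; `n_dropped` records the listwise
#'   deletions and `keep` the retained row indices of the original table.
#' @export
prepare_samples <- function(s, standardize = FALSE) {
  stopifnot(inherits(s, "sample_table"))
  ok <- !is.na(s$y) & !is.na(s$e)
  if (!is.null(s$x)) ok <- ok & complete.cases(s$x)
  out <- s
  out$n_dropped <- sum(!ok)
  out$keep <- which(ok)
  out$y <- s$y[ok]
  out$e <- scale_environment(s$e[ok])
  out$x <- if (is.null(s$x)) NULL else s$x[ok, , drop = FALSE]
  if (standardize && s$family == "gaussian") {
    out$y <- standardize_trait(out$y)
  }
  out$prepared <- TRUE
  out
}

#' Read a sample table from tab-separated text
#'
#' Expects a header line with columns `FID`, `IID`, `Y`, `E` and any
#' further columns treated as covariates. Rows are reordered to match
#' `iid_order` when given (e.g. the fam file order of a genotype fileset).
#'
#' @param path file path.
#' @param family trait family.
#' @param iid_order optional IID vector defining the output row order;
#'   IIDs absent from the file yield all-missing rows.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, family = c("gaussian", "binomial"),
                              iid_order = NULL) {
  family <- match.arg(family)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("FID", "IID", "Y", "E")
  if (!all(need %in% colnames(df))) {
    stop("sample table must have columns FID, IID, Y, E")
  }
  if (!is.null(iid_order)) {
    df <- df[match(iid_order, df$IID), , drop = FALSE]
  }
  covars <- setdiff(colnames(df), need)
  x <- if (length(covars)) as.matrix(df[, covars, drop = FALSE]) else NULL
  sample_table(df$Y, df$E, x, family)
}
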