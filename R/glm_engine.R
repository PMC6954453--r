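.check_prepared <- function(s) {
  if (!inherits(s, "sample_table") || !isTRUE(s$prepared)) {
    stop("sample table must be passed through prepare_samples() first")
  }
}

.scan_pvalue <- function(beta, se, df, family) {
  z <- beta / se
  if (family == "gaussian") {
    # t reference with residual degrees of freedom; indistinguishable from
    # the normal at GWAS sample sizes
    2 * pt(-abs(z), df = df)
  } else {
    2 * pnorm(-abs(z))
  }
}

#' Marginal association scan
#'
#' Fits, for every SNP, `trait ~ intercept + SNP + covariates` (identity
#' link for gaussian traits, logit link for binomial) and returns the SNP
#' coefficient, its standard error and the two-sided Wald P-value. SNPs
#' whose fit does not converge (monomorphic in the analysis sample,
#' separated logistic fit, rank deficiency) are flagged and carry missing
#' estimates. Subjects missing a SNP's genotype are dropped from that
#' SNP's fit only.
#'
#' @param g a [genotype_matrix()].
#' @param s a prepared [sample_table()].
#' @return A data frame of class `marginal_scan` with columns `snp_id`,
#'   `beta`, `se`, `p`, `converged`.
#' @export
fit_marginal_scan <- function(g, s) {
  .check_prepared(s)
  n <- length(s$y)
  stopifnot(nrow(g$dosages) == n)
  xbase <- cbind(rep(1, n), s$x)
  if (n <= ncol(xbase) + 2) stop("too few subjects for the marginal scan")
  fit <- glm_scan_cpp(s$y, xbase, g$dosages, numeric(0),
                      interaction = FALSE,
                      binomial = s$family == "binomial")
  p <- .scan_pvalue(fit$beta, fit$se, fit$df, s$family)
  p[!fit$converged] <- NA_real_
  out <- data.frame(snp_id = g$snp_ids, beta = fit$beta, se = fit$se,
                    p = p, converged = fit$converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("marginal_scan", "data.frame")
  out
}

#' SNP-by-environment interaction scan
#'
#' Fits, for every selected SNP, `trait ~ intercept + SNP + E + SNP:E +
#' covariates` and returns the interaction coefficient, its estimated
#' variance and the two-sided Wald P-value.
#'
#' @param g a [genotype_matrix()].
#' @param s a prepared [sample_table()] (exposure already scaled; trait
#'   standardized on the ADABF path for gaussian families).
#' @param subset SNP indices to scan; defaults to all SNPs.
#' @return A data frame of class `interaction_scan` with columns `snp_id`,
#'   `index` (original SNP index), `beta_ge`, `se`, `var_ge`, `p`,
#'   `converged`.
#' @export
fit_interaction_scan <- function(g, s, subset = NULL) {
  .check_prepared(s)
  n <- length(s$y)
  stopifnot(nrow(g$dosages) == n)
  if (is.null(subset)) subset <- seq_len(ncol(g$dosages))
  xbase <- cbind(rep(1, n), s$e, s$x)
  if (n <= ncol(xbase) + 3) stop("too few subjects for the interaction scan")
  fit <- glm_scan_cpp(s$y, xbase, g$dosages[, subset, drop = FALSE], s$e,
                      interaction = TRUE,
                      binomial = s$family == "binomial")
  p <- .scan_pvalue(fit$beta, fit$se, fit$df, s$family)
  p[!fit$converged] <- NA_real_
  out <- data.frame(snp_id = g$snp_ids[subset], index = subset,
                    beta_ge = fit$beta, se = fit$se,
                    var_ge = fit$se^2, p = p, converged = fit$converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_scan", "data.frame")
  out
}

#' Select SNPs passing the marginal screening
#'
#' Returns the indices of SNPs with a converged marginal fit and a
#' marginal P-value strictly below `alpha`, in original order. Screening
#' on marginal association before interaction testing boosts power without
#' inflating the interaction test's type I error.
#'
#' @param m a [fit_marginal_scan()] result.
#' @param alpha screening significance level.
#' @return Integer index vector (possibly empty).
#' @export
screen_snps <- function(m, alpha = 0.05) {
  which(m$converged & !is.na(m$p) & m$p < alpha)
}

#' Wald test
#'
#' @param beta coefficient estimate.
#' @param se standard error (positive).
#' @return A list with `z = beta / se` and the two-sided normal P-value.
#' @export
wald_test <- function(beta, se) {
  if (any(se <= 0)) stop("standard error must be positive")
  z <- beta / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}
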