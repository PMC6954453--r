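#' Wakefield log Bayes factor for an interaction coefficient
#'
#' Computes, in log space, the approximate Bayes factor comparing a normal
#' prior `N(0, w)` on the interaction coefficient against the point null,
#' given the coefficient estimate and its estimated sampling variance:
#' `log BF = 0.5 * log(v / (v + w)) + beta^2 * w / (2 * v * (v + w))`.
#' Working on the log scale avoids overflow for Wald ratios up to and
#' beyond 40.
#'
#' @param beta_ge interaction coefficient estimate(s).
#' @param v estimated sampling variance(s), positive.
#' @param w prior variance; the default 0.04 (= 0.2^2) matches the WTCCC
#'   prior for modest effect sizes on a unit-variance trait or log-odds
#'   scale.
#' @return The natural-log Bayes factor (vectorized).
#' @export
log_bayes_factor <- function(beta_ge, v, w = 0.04) {
  if (any(v <= 0)) stop("sampling variance must be positive")
  if (any(w < 0)) stop("prior variance must be nonnegative")
  0.5 * log(v / (v + w)) + beta_ge^2 * w / (2 * v * (v + w))
}

#' Cumulative ordered-score statistics
#'
#' Sorts the per-SNP log Bayes factors in descending order (stable: ties
#' keep the lower SNP index first) and returns the cumulative sums
#' `S_k = sum of the k largest log-BFs`, for `k = 1, ..., L`.
#'
#' @param log_bf per-SNP log Bayes factors.
#' @return A list with `s` (the score profile) and `order` (the descending
#'   permutation of SNP indices).
#' @export
summary_scores <- function(log_bf) {
  stopifnot(length(log_bf) >= 1)
  ord <- order(-log_bf) # radix sort: stable, ties by index
  list(s = cumsum(log_bf[ord]), order = ord)
}

#' Null covariance of interaction estimates
#'
#' Builds the covariance `V[i, j] = R[i, j] * sqrt(v_i * v_j)` of the
#' interaction estimates under the global null, where `R` is the genotype
#' correlation matrix (the correlation of association statistics is well
#' approximated by the correlation of genotypes). The matrix is repaired
#' to be positive semidefinite by clipping eigenvalues at 1e-8 and
#' rescaling back to the original diagonal; an eigenvalue below -1e-6
#' (relative to the largest) indicates a structurally invalid input and is
#' an error.
#'
#' @param r genotype correlation matrix (L x L).
#' @param v per-SNP estimated variances of the interaction coefficients.
#' @return The repaired covariance matrix.
#' @export
build_null_covariance <- function(r, v) {
  stopifnot(nrow(r) == length(v), all(v > 0))
  covm <- r * tcrossprod(sqrt(v))
  covm <- (covm + t(covm)) / 2
  ee <- eigen(covm, symmetric = TRUE)
  lam <- ee$values
  if (min(lam) < -1e-6 * max(abs(lam))) {
    stop("null covariance has a substantially negative eigenvalue")
  }
  if (min(lam) < 1e-8) {
    lam <- pmax(lam, 1e-8)
    covm2 <- ee$vectors %*% (lam * t(ee$vectors))
    d <- sqrt(diag(covm) / diag(covm2))
    covm <- covm2 * tcrossprod(d)
    covm <- (covm + t(covm)) / 2
  }
  covm
}

#' Draw the resampling null ensemble
#'
#' Draws `b` vectors of interaction estimates from `N(0, cov)`, converts
#' each entry to a Wakefield log Bayes factor using the corresponding
#' diagonal variance, and computes each draw's cumulative ordered-score
#' profile.
#'
#' @param covm null covariance from [build_null_covariance()].
#' @param b number of resampling replicates (at least 100 for usable
#'   resolution).
#' @param w prior variance.
#' @param seed optional RNG seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `null_ensemble` with elements `b`,
#'   `null_log_bf` (b x L), `null_scores` (b x L), `v` (diagonal
#'   variances), `w`.
#' @export
draw_null <- function(covm, b, w = 0.04, seed = NULL) {
  if (b < 100) warning("fewer than 100 resamples: P-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(covm)
  ee <- eigen(covm, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  if (min(ee$values) < -1e-6 * max(abs(ee$values))) {
    stop("covariance has a substantially negative eigenvalue")
  }
  M <- ee$vectors %*% diag(sqrt(lam), L)
  z <- matrix(rnorm(b * L), b, L)
  betas <- z %*% t(M)
  v <- diag(covm)
  nb <- log_bayes_factor(betas, rep(v, each = b), w)
  ns <- t(apply(nb, 1L, function(r) cumsum(sort(r, decreasing = TRUE))))
  if (L == 1L) ns <- matrix(ns, ncol = 1L)
  structure(list(b = b, null_log_bf = nb, null_scores = ns, v = v, w = w),
            class = "null_ensemble")
}

#' Overall adaptive min-P test
#'
#' For each truncation point `k`, the P-value of the observed score `S_k`
#' is the fraction of resamples whose score at `k` is at least `S_k`; each
#' resample's own per-`k` P-values are computed against the other `b - 1`
#' resamples. The overall P-value is the fraction of resamples whose
#' minimum P (over `k`) is at most the observed minimum P. When no
#' resample is as extreme the numeric value is 0 and the display label is
#' `"< 1/B"`.
#'
#' @param s_obs observed score profile from [summary_scores()].
#' @param ensemble a [draw_null()] ensemble with matching `L`.
#' @return A list with `p_k`, `min_p`, `p_overall`, `p_label`, `count`.
#' @export
overall_p <- function(s_obs, ensemble) {
  ns <- ensemble$null_scores
  B <- ensemble$b
  L <- length(s_obs)
  stopifnot(ncol(ns) == L)
  p_k <- vapply(seq_len(L), function(k) mean(ns[, k] >= s_obs[k]),
                numeric(1))
  # per-resample leave-one-out P at each k via ranking: the count of other
  # resamples with a score >= the b-th equals B - rank_min(b)
  p_b <- matrix(0, B, L)
  for (k in seq_len(L)) {
    ge_count <- B - rank(ns[, k], ties.method = "min") # excludes self
    p_b[, k] <- ge_count / (B - 1)
  }
  min_p <- min(p_k)
  min_p_b <- apply(p_b, 1L, min)
  # when the observed statistic beats every resample at some k, its min-P
  # hits the floor of the resampling resolution; a resample tying at that
  # floor only beat its peers, not the observed profile, so the count is 0
  # and the result is reported as the interval "< 1/B"
  count <- if (min_p == 0) 0L else sum(min_p_b <= min_p)
  p_overall <- count / B
  list(p_k = p_k, min_p = min_p, p_overall = p_overall,
       p_label = if (count == 0) sprintf("< %g", 1 / B)
                 else format(p_overall),
       count = count)
}

#' Resampling false discovery rate over the ordered Bayes factors
#'
#' Estimates, for each `k`, the expected number of null Bayes factors per
#' resample at or above the k-th largest observed Bayes factor
#' (`FP_(k)`), and the FDR as `FP_(k) / k`. The selected set is the
#' leading `k*` SNPs in descending-BF order, where `k*` is the largest `k`
#' with `FDR_(k) < q` (possibly 0).
#'
#' @param log_bf observed per-SNP log Bayes factors.
#' @param ensemble a [draw_null()] ensemble with matching `L`.
#' @param q FDR selection level.
#' @return A list with `fdr_curve`, `fp_curve`, `k_star`, `selected`
#'   (SNP positions within `log_bf`, in descending-BF order) and `order`.
#' @export
resampling_fdr <- function(log_bf, ensemble, q = 0.05) {
  L <- length(log_bf)
  stopifnot(ncol(ensemble$null_log_bf) == L)
  B <- ensemble$b
  sc <- summary_scores(log_bf)
  bf_desc <- log_bf[sc$order]
  null_sorted <- sort(as.vector(ensemble$null_log_bf))
  n_null <- length(null_sorted)
  # count of null log-BFs >= threshold, via binary search on the sorted pool
  fp <- vapply(bf_desc, function(thr) {
    (n_null - findInterval(thr, null_sorted, left.open = TRUE)) / B
  }, numeric(1))
  fdr <- fp / seq_len(L)
  k_star <- if (any(fdr < q)) max(which(fdr < q)) else 0L
  list(fdr_curve = fdr, fp_curve = fp, k_star = k_star,
       selected = if (k_star > 0) sc$order[seq_len(k_star)] else integer(0),
       order = sc$order)
}

#' Run the full adaptive combination-of-Bayes-factors pipeline
#'
#' Screens SNPs by marginal association (`P < screen_alpha`), scans the
#' screened SNPs for SNP-by-environment interaction, converts the
#' interaction estimates to Wakefield log Bayes factors, calibrates the
#' cumulative ordered scores against a multivariate normal resampling null
#' whose covariance combines the genotype correlations with the estimated
#' coefficient variances, and reports the overall min-P test together with
#' the resampling-FDR-selected SNP set. Gaussian traits are standardized
#' internally so that the default prior variance applies.
#'
#' @param g a [genotype_matrix()].
#' @param s a prepared [sample_table()].
#' @param w prior variance of the interaction coefficients.
#' @param b number of resampling replicates (1000 is ample for comparing
#'   against nominal levels of 0.05 or 0.01; use 1e5 when small P-values
#'   must be resolved).
#' @param screen_alpha marginal screening level.
#' @param seed optional RNG seed for the resampling null.
#' @param fdr_q FDR level for pinpointing individual SNPs.
#' @param marginal optional precomputed [fit_marginal_scan()] on the same
#'   data (screening uses only its P-values, which are invariant to trait
#'   standardization for gaussian families).
#' @return An object of class `adabf_result`: `p_overall`, `p_label`,
#'   `p_k`, `min_p`, `screened` (SNP indices), `scan` (interaction scan on
#'   the screened set), `log_bf`, `s_obs`, `fdr` (see [resampling_fdr()]),
#'   `selected_snps` (ids with resampling FDR below `fdr_q`), `w`, `b`.
#'   With an empty screened set, `p_overall` is 1 and the selection empty.
#' @export
run_adabf <- function(g, s, w = 0.04, b = 1000, screen_alpha = 0.05,
                      seed = NULL, fdr_q = 0.05, marginal = NULL) {
  .check_prepared(s)
  if (s$family == "gaussian") s$y <- standardize_trait(s$y)
  if (is.null(marginal)) marginal <- fit_marginal_scan(g, s)
  screened <- screen_snps(marginal, screen_alpha)
  empty <- list(p_overall = 1, p_label = "1", p_k = numeric(0),
                min_p = NA_real_, screened = integer(0), scan = NULL,
                log_bf = numeric(0), s_obs = numeric(0), fdr = NULL,
                selected_snps = character(0), w = w, b = b)
  class(empty) <- "adabf_result"
  if (length(screened) == 0) return(empty)

  scan <- fit_interaction_scan(g, s, screened)
  ok <- scan$converged
  if (!any(ok)) return(empty)
  scan <- scan[ok, , drop = FALSE]

  lbf <- log_bayes_factor(scan$beta_ge, scan$var_ge, w)
  sc <- summary_scores(lbf)
  r <- genotype_correlation(g, scan$index)
  covm <- build_null_covariance(r, scan$var_ge)
  ens <- draw_null(covm, b, w, seed)
  op <- overall_p(sc$s, ens)
  fdr <- resampling_fdr(lbf, ens, fdr_q)

  out <- list(p_overall = op$p_overall, p_label = op$p_label,
              p_k = op$p_k, min_p = op$min_p,
              screened = scan$index, scan = scan,
              log_bf = lbf, s_obs = sc$s, fdr = fdr,
              selected_snps = scan$snp_id[fdr$selected],
              selected_index = scan$index[fdr$selected],
              w = w, b = b)
  class(out) <- "adabf_result"
  out
}

#' @export
print.adabf_result <- function(x, ...) {
  cat("Adaptive combination of Bayes factors (G x E)\n")
  cat(sprintf("  screened SNPs: %d;  resamples: %d;  prior variance W = %g\n",
              length(x$screened), x$b, x$w))
  cat(sprintf("  overall P = %s\n", x$p_label))
  if (length(x$selected_snps)) {
    cat("  SNPs with resampling FDR < 5%:",
        paste(x$selected_snps, collapse = ", "), "\n")
  } else {
    cat("  no individual SNP passes the resampling FDR selection\n")
  }
  invisible(x)
}
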