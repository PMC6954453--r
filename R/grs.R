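#' Default P-value thresholds for internally weighted risk scores
#'
#' The ten selection thresholds routinely used to explore the strength of
#' a genetic risk score.
#'
#' @return Numeric vector of length 10, strictly increasing.
#' @export
grs_thresholds <- function() {
  c(0.0001, 0.00025, 0.0005, 0.001, 0.0025, 0.005, 0.01, 0.025, 0.05, 0.1)
}

#' Build a rescaled genetic risk score
#'
#' The pre-score of subject `i` is `sum_l w_l * g_il` over the SNPs whose
#' selection P-value is strictly below the threshold. It is then rescaled
#' to the scale of a count of phenotype-increasing alleles: multiplied by
#' the number of available SNPs and divided by the sum of `|w_l|` over the
#' available SNPs, where "available" means selected and nonmissing for
#' that subject. The rescaled score is invariant to multiplying all
#' weights by a positive constant, and equals the plain allele count when
#' all weights are 1.
#'
#' @param g a [genotype_matrix()].
#' @param weights per-SNP weights (marginal or interaction coefficients);
#'   `NA` for SNPs without a converged fit.
#' @param select_p per-SNP selection P-values.
#' @param threshold selection P-value threshold.
#' @return Per-subject scores, or `NULL` when no SNP passes the threshold
#'   (the caller logs and skips the threshold). Subjects with no available
#'   SNP get `NA`.
#' @export
build_grs <- function(g, weights, select_p, threshold) {
  sel <- which(!is.na(weights) & !is.na(select_p) & select_p < threshold)
  if (length(sel) == 0) return(NULL)
  gs <- g$dosages[, sel, drop = FALSE]
  w <- weights[sel]
  obs <- !is.na(gs)
  gs0 <- gs
  gs0[!obs] <- 0
  pre <- as.vector(gs0 %*% w)
  n_avail <- rowSums(obs)
  denom <- as.vector(obs %*% abs(w))
  score <- pre * n_avail / denom
  score[n_avail == 0] <- NA_real_
  score
}

#' Test the risk-score-by-environment interaction
#'
#' Fits `trait ~ intercept + score + E + score:E + covariates` and returns
#' the Wald test of the interaction coefficient. Gaussian fits stay on the
#' raw trait scale, so the coefficient reads as the trait change per
#' phenotype-increasing allele attributable to exposure.
#'
#' @param score per-subject risk score.
#' @param s a prepared [sample_table()].
#' @return A list with `coef`, `se`, `p`, `n`; or `NULL` when the score is
#'   constant or the exposure is constant in the complete cases (the
#'   caller logs and skips).
#' @export
grs_interaction_test <- function(score, s) {
  .check_prepared(s)
  df <- data.frame(y = s$y, score = score, e = s$e)
  if (!is.null(s$x)) df <- cbind(df, as.data.frame(s$x))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 3) return(NULL)
  if (sd(df$score) == 0 || sd(df$e) == 0) return(NULL)
  fml <- stats::as.formula(paste(
    "y ~ score + e + score:e",
    if (ncol(df) > 3) paste("+", paste(colnames(df)[-(1:3)], collapse = " + "))
    else ""))
  fit <- if (s$family == "gaussian") {
    stats::lm(fml, data = df)
  } else {
    suppressWarnings(stats::glm(fml, data = df, family = binomial()))
  }
  cf <- summary(fit)$coefficients
  row <- match("score:e", rownames(cf))
  if (is.na(row) || !is.finite(cf[row, 2])) return(NULL)
  list(coef = cf[row, 1], se = cf[row, 2], p = cf[row, 4], n = nrow(df))
}

#' Bonferroni combination over evaluated thresholds
#'
#' The combined P-value is the minimum per-threshold P-value multiplied by
#' the total number of thresholds `t_total` (thresholds skipped because
#' they selected no SNP still count, a deliberately conservative
#' convention), capped at 1.
#'
#' @param pvals per-threshold P-values (skipped thresholds as `NA`).
#' @param t_total total number of thresholds in the family.
#' @return The combined P-value, or `NA` when no threshold was evaluated.
#' @export
bonferroni_combine <- function(pvals, t_total = length(pvals)) {
  stopifnot(length(pvals) >= 1)
  if (all(is.na(pvals))) return(NA_real_)
  min(1, t_total * min(pvals, na.rm = TRUE))
}

#' Split a sample into random halves
#'
#' Disjoint training and testing halves covering all subjects; an odd
#' subject count puts the extra subject in training.
#'
#' @param n sample count (at least 4).
#' @param seed optional RNG seed.
#' @return A list with `train` and `test` index vectors.
#' @export
split_sample <- function(n, seed = NULL) {
  stopifnot(n >= 4)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  n_train <- ceiling(n / 2)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1):n]))
}

.grs_result <- function(method, rows, thresholds) {
  per <- do.call(rbind, rows)
  combined <- bonferroni_combine(per$p, length(thresholds))
  out <- list(method = method, per_threshold = per, combined_p = combined)
  class(out) <- "grs_result"
  out
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf("%s interaction test\n", x$method))
  print(x$per_threshold, row.names = FALSE)
  cat(sprintf("combined (Bonferroni over %d thresholds): P = %s\n",
              nrow(x$per_threshold),
              format(x$combined_p)))
  invisible(x)
}

#' Marginal-weighted genetic risk score interaction test (GRS-M)
#'
#' Weights come from the marginal association scan on the full sample;
#' screening on marginal association keeps the subsequent interaction test
#' valid without sample splitting. For each threshold a risk score is
#' built from the SNPs whose marginal P-value passes, and its interaction
#' with the exposure is tested; the ten per-threshold tests are combined
#' by Bonferroni.
#'
#' @param g a [genotype_matrix()].
#' @param s a prepared [sample_table()] (raw trait scale).
#' @param thresholds selection thresholds.
#' @param marginal optional precomputed [fit_marginal_scan()].
#' @return A `grs_result` with a per-threshold table (`threshold`,
#'   `n_snps`, `coef`, `se`, `p`; skipped thresholds carry `NA`) and the
#'   Bonferroni-combined P.
#' @export
run_grs_m <- function(g, s, thresholds = grs_thresholds(),
                      marginal = NULL) {
  .check_prepared(s)
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1))
  if (is.null(marginal)) marginal <- fit_marginal_scan(g, s)
  rows <- lapply(thresholds, function(t) {
    score <- build_grs(g, marginal$beta, marginal$p, t)
    res <- if (is.null(score)) NULL else grs_interaction_test(score, s)
    n_snps <- sum(!is.na(marginal$beta) & !is.na(marginal$p) &
                    marginal$p < t)
    if (is.null(res)) {
      data.frame(threshold = t, n_snps = n_snps, coef = NA_real_,
                 se = NA_real_, p = NA_real_)
    } else {
      data.frame(threshold = t, n_snps = n_snps, coef = res$coef,
                 se = res$se, p = res$p)
    }
  })
  .grs_result("GRS-M", rows, thresholds)
}

#' Interaction-weighted genetic risk score interaction test (GRS-I)
#'
#' The sample is split into random halves. Interaction coefficients
#' estimated on the training half provide the weights and selection
#' P-values; scores are built and the score-by-exposure interaction tested
#' on the testing half only, which preserves the type I error rate at the
#' cost of power.
#'
#' @param g a [genotype_matrix()].
#' @param s a prepared [sample_table()] (raw trait scale).
#' @param thresholds selection thresholds.
#' @param seed seed for the random split.
#' @return A `grs_result`, as for [run_grs_m()].
#' @export
run_grs_i <- function(g, s, thresholds = grs_thresholds(), seed = NULL) {
  .check_prepared(s)
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1))
  n <- length(s$y)
  sp <- split_sample(n, seed)

  subset_samples <- function(s, idx) {
    out <- s
    out$y <- s$y[idx]
    out$e <- s$e[idx]
    out$x <- if (is.null(s$x)) NULL else s$x[idx, , drop = FALSE]
    out
  }
  g_train <- g
  g_train$dosages <- g$dosages[sp$train, , drop = FALSE]
  g_test <- g
  g_test$dosages <- g$dosages[sp$test, , drop = FALSE]
  s_train <- subset_samples(s, sp$train)
  s_test <- subset_samples(s, sp$test)

  train_scan <- fit_interaction_scan(g_train, s_train)
  rows <- lapply(thresholds, function(t) {
    score <- build_grs(g_test, train_scan$beta_ge, train_scan$p, t)
    res <- if (is.null(score)) NULL else grs_interaction_test(score, s_test)
    n_snps <- sum(!is.na(train_scan$beta_ge) & !is.na(train_scan$p) &
                    train_scan$p < t)
    if (is.null(res)) {
      data.frame(threshold = t, n_snps = n_snps, coef = NA_real_,
                 se = NA_real_, p = NA_real_)
    } else {
      data.frame(threshold = t, n_snps = n_snps, coef = res$coef,
                 se = res$se, p = res$p)
    }
  })
  out <- .grs_result("GRS-I", rows, thresholds)
  out$split <- sp
  out
}
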