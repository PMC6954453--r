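# Small fixtures built in code.

# A deterministic genotype matrix from explicit dosage columns.
toy_genotypes <- function(cols, chrom = NULL, pos = NULL) {
  m <- do.call(cbind, cols)
  L <- ncol(m)
  genotype_matrix(m,
                  snp_ids = paste0("snp", seq_len(L)),
                  chrom = if (is.null(chrom)) rep(1L, L) else chrom,
                  pos = if (is.null(pos)) seq_len(L) else pos)
}

# A prepared gaussian sample table with no covariates.
toy_samples <- function(y, e, family = "gaussian", x = NULL) {
  prepare_samples(sample_table(y, e, x, family = family))
}

# Random Hardy-Weinberg panel for property-style tests.
random_panel <- function(n, L, maf_range = c(0.1, 0.5)) {
  maf <- runif(L, maf_range[1], maf_range[2])
  genotype_matrix(matrix(rbinom(n * L, 2, rep(maf, each = n)), n, L),
                  paste0("snp", seq_len(L)), rep(1L, L), seq_len(L))
}

# Quadrature oracle for the Wakefield Bayes factor:
# BF = [integral of N(bhat; b, v) N(b; 0, w) db] / N(bhat; 0, v).
quadrature_log_bf <- function(beta_hat, v, w) {
  num <- integrate(function(b) {
    dnorm(beta_hat, mean = b, sd = sqrt(v)) * dnorm(b, 0, sqrt(w))
  }, lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  log(num) - dnorm(beta_hat, 0, sqrt(v), log = TRUE)
}
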