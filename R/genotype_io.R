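#' Construct a genotype matrix
#'
#' Container for a panel of biallelic autosomal SNPs with dosages coded as
#' minor-allele counts.  The constructor enforces the minor-allele
#' convention: for any SNP whose stated "minor" allele has sample frequency
#' above 0.5 the dosages are flipped (`2 - g`) and the allele labels are
#' swapped, so that `maf <= 0.5` always holds.  A frequency of exactly 0.5
#' keeps the supplied orientation.
#'
#' @param dosages n x L numeric matrix with entries in `{0, 1, 2}` or `NA`
#'   for missing genotypes; rows are samples, columns are SNPs.
#' @param snp_ids character vector of SNP identifiers (length L).
#' @param chrom chromosome per SNP (length L).
#' @param pos 1-based base-pair position per SNP (length L).
#' @param minor,major allele labels per SNP (length L); `minor` is the
#'   allele counted by `dosages` as supplied.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snp_ids`, `chrom`, `pos`, `minor`, `major`, `maf`
#'   (recomputed from the dosages) and `call_rate` (fraction of nonmissing
#'   genotypes per SNP).
#' @export
genotype_matrix <- function(dosages, snp_ids, chrom, pos,
                            minor = NULL, major = NULL) {
  dosages <- as.matrix(dosages)
  L <- ncol(dosages)
  if (is.null(minor)) minor <- rep("A", L)
  if (is.null(major)) major <- rep("B", L)
  stopifnot(length(snp_ids) == L, length(chrom) == L, length(pos) == L,
            length(minor) == L, length(major) == L)
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  storage.mode(dosages) <- "double"

  freq <- colMeans(dosages, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  flip <- freq > 0.5
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    tmp <- minor[flip]
    minor[flip] <- major[flip]
    major[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }

  obj <- list(
    dosages = dosages,
    snp_ids = as.character(snp_ids),
    chrom = chrom,
    pos = as.integer(pos),
    minor = as.character(minor),
    major = as.character(major),
    maf = unname(freq),
    call_rate = unname(colMeans(!is.na(dosages)))
  )
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range [%.4f, %.4f]; min call rate %.4f\n",
              min(x$maf), max(x$maf), min(x$call_rate)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNP index
#'
#' @param g a [genotype_matrix()].
#' @param idx integer or logical index into the SNP dimension.
#' @return A `genotype_matrix` restricted to the selected SNPs.
#' @export
subset_snps <- function(g, idx) {
  genotype_matrix(g$dosages[, idx, drop = FALSE],
                  g$snp_ids[idx], g$chrom[idx], g$pos[idx],
                  g$minor[idx], g$major[idx])
}

# 256 x 4 lookup table decoding one bed byte into four A1 dosages
.bed_lut <- local({
  codes <- c(2L, NA_integer_, 1L, 0L) # 00=hom A1, 01=missing, 10=het, 11=hom A2
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    for (k in 0:3) {
      lut[b + 1L, k + 1L] <- codes[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
    }
  }
  lut
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam` (SNP-major bed v1) and
#' returns dosages oriented samples x SNPs, coded as minor-allele counts.
#' If the bim A1 allele turns out to be the major allele in the loaded
#' sample, that SNP is recoded (`2 - g`) and the allele labels swapped.
#'
#' @param prefix path stem of the fileset (without extension).
#' @return A [genotype_matrix()] plus attributes `fam` (the six fam
#'   columns) attached as the `fam` element of the attribute list.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  }
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  colnames(fam_df)[1:6] <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENO")
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  colnames(bim_df)[1:6] <- c("CHR", "SNP", "CM", "POS", "A1", "A2")

  n <- nrow(fam_df)
  L <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed v1 files are supported: ", bed)
  }
  bytes_per_snp <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * L) {
    stop("bed payload size does not match bim/fam dimensions (corrupt fileset)")
  }
  # decode all bytes at once, then reshape SNP-major
  dec <- .bed_lut[as.integer(payload) + 1L, , drop = FALSE]   # (bytes) x 4
  dec <- matrix(t(dec), nrow = 4L * bytes_per_snp)            # per-SNP columns
  dosages <- dec[seq_len(n), , drop = FALSE]                  # counts of A1

  g <- genotype_matrix(dosages, bim_df$SNP, bim_df$CHR, bim_df$POS,
                       minor = bim_df$A1, major = bim_df$A2)
  attr(g, "fam") <- fam_df
  g
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: writes SNP-major bed v1 with A1 = the stored
#' minor allele. Used for round-trip testing and for exporting filtered
#' panels.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path stem.
#' @param fam optional data frame with columns FID, IID, PAT, MAT, SEX,
#'   PHENO; defaults to placeholder identifiers.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, fam = NULL) {
  n <- nrow(g$dosages)
  L <- ncol(g$dosages)
  if (is.null(fam)) {
    fam <- data.frame(FID = seq_len(n), IID = seq_len(n), PAT = 0, MAT = 0,
                      SEX = 0, PHENO = -9)
  }
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(CHR = g$chrom, SNP = g$snp_ids, CM = 0, POS = g$pos,
                    A1 = g$minor, A2 = g$major)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  # dosage (A1 count) -> 2-bit code
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2] <- 0L
    out[!is.na(d) & d == 1] <- 2L
    out[!is.na(d) & d == 0] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (l in seq_len(L)) {
    codes <- code_of(g$dosages[, l])
    length(codes) <- 4L * bytes_per_snp   # pad with NA -> treated as 0 below
    codes[is.na(codes)] <- 0L
    m <- matrix(codes, nrow = 4L)
    byte_vals <- m[1, ] + bitwShiftL(m[2, ], 2L) +
      bitwShiftL(m[3, ], 4L) + bitwShiftL(m[4, ], 6L)
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against Hardy-Weinberg expected counts at the estimated allele
#' frequency. Monomorphic SNPs (one allele absent) return P = 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, summing to >= 1).
#' @return The chi-square P-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype count required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

.hwe_p_per_snp <- function(g) {
  vapply(seq_len(ncol(g$dosages)), function(l) {
    d <- g$dosages[, l]
    d <- d[!is.na(d)]
    hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))
  }, numeric(1))
}

#' Quality-control filter for a SNP panel
#'
#' Retains SNPs with call rate at or above `min_call_rate`, Hardy-Weinberg
#' P-value at or above `hwe_p`, and minor allele frequency at or above
#' `min_maf`. Defaults are the standard GWAS settings: genotyping rate
#' below 95%, Hardy-Weinberg P below 5.7e-7 or MAF below 1% removes a SNP.
#'
#' @param g a [genotype_matrix()].
#' @param min_call_rate minimum per-SNP fraction of nonmissing genotypes.
#' @param hwe_p minimum Hardy-Weinberg test P-value.
#' @param min_maf minimum minor allele frequency.
#' @return A list with `genotypes` (the filtered panel) and `removed`, a
#'   data frame logging each dropped SNP and the rule(s) it violated.
#' @export
qc_filter <- function(g, min_call_rate = 0.95, hwe_p = 5.7e-7,
                      min_maf = 0.01) {
  stopifnot(min_call_rate > 0, min_call_rate < 1,
            hwe_p > 0, hwe_p < 1, min_maf > 0, min_maf < 1)
  hwe <- .hwe_p_per_snp(g)
  bad_call <- g$call_rate < min_call_rate
  bad_hwe <- hwe < hwe_p
  bad_maf <- g$maf < min_maf
  drop <- bad_call | bad_hwe | bad_maf
  reason <- vapply(seq_along(drop), function(l) {
    paste(c(if (bad_call[l]) "call_rate",
            if (bad_hwe[l]) "hwe",
            if (bad_maf[l]) "maf"), collapse = ";")
  }, character(1))
  removed <- data.frame(snp_id = g$snp_ids[drop],
                        reason = reason[drop],
                        stringsAsFactors = FALSE)
  if (all(drop)) stop("qc_filter removed every SNP: empty panel")
  list(genotypes = subset_snps(g, !drop), removed = removed)
}

# VIFs for the columns of a dosage block: diagonal of the inverse
# correlation matrix, ridge-stabilised so that collinear or sample-poor
# windows never crash (VIF of an exactly duplicated SNP is then finite but
# enormous, which the pruning loop treats the same as infinite).
.window_vif <- function(x, ridge = 1e-8) {
  R <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  Ri <- tryCatch(solve(R), error = function(e) solve(R + ridge * diag(ncol(R))))
  pmax(diag(Ri), 1)
}

#' Prune SNPs in high linkage disequilibrium by windowed VIF
#'
#' Within a sliding window of `window` SNPs (shifted by `step`), SNPs with
#' variance inflation factor above `vif_max` are removed one at a time
#' (highest VIF first, ties broken by lower MAF then higher column index),
#' recomputing VIFs after each removal, until all remaining VIFs are at or
#' below the bound. The VIF of a SNP is `1 / (1 - R^2)` where `R^2` comes
#' from regressing its dosages on all other remaining SNPs in the window.
#' Pruning is restricted within chromosome; SNPs must be ordered by
#' (chromosome, position).
#'
#' @param g a [genotype_matrix()].
#' @param window window size in SNPs.
#' @param step window shift in SNPs.
#' @param vif_max maximum tolerated VIF.
#' @return Integer indices of the surviving SNPs, in original order.
#' @export
vif_prune <- function(g, window = 50, step = 5, vif_max = 2.0) {
  stopifnot(window >= 2, step >= 1, step <= window)
  ord <- order(match(g$chrom, unique(g$chrom)), g$pos)
  if (!identical(ord, seq_along(ord))) {
    stop("SNPs must be ordered by (chrom, pos) before pruning")
  }
  keep <- rep(TRUE, ncol(g$dosages))
  for (chr in unique(g$chrom)) {
    idx <- which(g$chrom == chr)
    Lc <- length(idx)
    if (Lc < 2) next
    starts <- seq(1, max(1, Lc - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1, Lc)]
      repeat {
        active <- win[keep[win]]
        if (length(active) < 2) break
        vifs <- .window_vif(g$dosages[, active, drop = FALSE])
        if (max(vifs) <= vif_max) break
        cand <- which(vifs == max(vifs))
        if (length(cand) > 1) {
          # ties: remove the lower-MAF SNP; among equal MAFs, the later one
          mafs <- g$maf[active[cand]]
          cand <- cand[mafs == min(mafs)]
        }
        keep[active[max(cand)]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Pearson correlation matrix of genotype dosages
#'
#' @param g a [genotype_matrix()].
#' @param subset nonempty SNP index vector.
#' @return Symmetric correlation matrix over pairwise-complete samples,
#'   with unit diagonal.
#' @export
genotype_correlation <- function(g, subset) {
  stopifnot(length(subset) >= 1)
  x <- g$dosages[, subset, drop = FALSE]
  vars <- apply(x, 2, stats::var, na.rm = TRUE)
  if (any(vars == 0 | is.na(vars))) {
    bad <- g$snp_ids[subset][which(vars == 0 | is.na(vars))]
    stop("zero-variance SNP(s) in correlation subset: ",
         paste(bad, collapse = ", "))
  }
  R <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}
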