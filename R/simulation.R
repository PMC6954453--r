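#' Logit intercept for a given disease prevalence
#'
#' The baseline log-odds used in binary-trait simulation; a prevalence of
#' 5% gives -2.94 (2 d.p.).
#'
#' @param prevalence disease prevalence in (0, 1).
#' @return `log(prevalence / (1 - prevalence))`.
#' @export
prevalence_intercept <- function(prevalence = 0.05) {
  stopifnot(prevalence > 0, prevalence < 1)
  qlogis(prevalence)
}

#' Describe a simulation scenario
#'
#' Bundles the design of one simulated GWAS: the trait family, sample and
#' panel sizes, minor allele frequency range, optional autoregressive LD,
#' binary exposure prevalence, number `d` of interacting SNPs and their
#' effect-size range, and whether SNP main effects are present. Defaults
#' mirror a desk-scale profile of the study conditions: `n = 2000`,
#' `l_snps = 300`, exposure prevalence 0.248 (a population smoking rate),
#' disease prevalence 5%, interaction effect sizes drawn from
#' `[log 1.2, log 1.4]` (binary) or `[0.05, 0.07]` (continuous) for the
#' "smaller" tier and `[log 1.4, log 1.6]` / `[0.07, 0.09]` for "larger".
#'
#' @param family trait family.
#' @param n sample count.
#' @param l_snps panel size.
#' @param maf_range minor-allele-frequency interval for the panel.
#' @param ld_rho autoregressive LD parameter in `[0, 1)`; 0 gives
#'   independent SNPs.
#' @param e_prevalence binary exposure frequency.
#' @param d number of interacting SNPs (0 for the global null; even when
#'   `main_effects = TRUE`).
#' @param effect_size `"smaller"` or `"larger"`, selecting the default
#'   effect range for the family.
#' @param effect_range optional explicit `|beta_GE|` interval overriding
#'   `effect_size` (a warning flags ranges outside the standard tiers).
#' @param main_effects also give SNPs main effects? When `TRUE`, SNPs
#'   `1..d/2` of the special set carry main effects only, `d/2+1..d` carry
#'   both, and `d+1..3d/2` carry interactions only; main-effect sizes are
#'   drawn from the same interval as the interactions.
#' @param prevalence disease prevalence for binary traits.
#' @param reps replicate count for study harnesses.
#' @param seed RNG seed for study harnesses.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(family = c("gaussian", "binomial"),
                          n = 2000, l_snps = 300,
                          maf_range = c(0.05, 0.5), ld_rho = 0,
                          e_prevalence = 0.248, d = 0,
                          effect_size = c("smaller", "larger"),
                          effect_range = NULL,
                          main_effects = FALSE, prevalence = 0.05,
                          reps = 1000, seed = 1) {
  family <- match.arg(family)
  effect_size <- match.arg(effect_size)
  stopifnot(n >= 10, l_snps >= 1, ld_rho >= 0, ld_rho < 1,
            e_prevalence >= 0, e_prevalence <= 1, d >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (main_effects && d > 0 && d %% 2 != 0) {
    stop("d must be even when main effects are present")
  }
  if (main_effects && 1.5 * d > l_snps) {
    stop("panel too small for the main-effect index structure (need 1.5 * d SNPs)")
  }
  if (!main_effects && d > l_snps) stop("d cannot exceed l_snps")
  tiers <- if (family == "binomial") {
    list(smaller = c(log(1.2), log(1.4)), larger = c(log(1.4), log(1.6)))
  } else {
    list(smaller = c(0.05, 0.07), larger = c(0.07, 0.09))
  }
  if (is.null(effect_range)) {
    effect_range <- tiers[[effect_size]]
  } else {
    std <- any(vapply(tiers, function(t) isTRUE(all.equal(t, effect_range)),
                      logical(1)))
    if (!std) warning("effect_range outside the standard tiers")
  }
  structure(list(family = family, n = n, l_snps = l_snps,
                 maf_range = maf_range, ld_rho = ld_rho,
                 e_prevalence = e_prevalence, d = d,
                 effect_range = effect_range, main_effects = main_effects,
                 prevalence = prevalence, reps = reps, seed = seed),
            class = "scenario_spec")
}

#' Simulate a genotype panel
#'
#' MAFs are drawn uniformly from the scenario's range and genotypes from
#' Hardy-Weinberg proportions (two independent allele draws per subject).
#' When `ld_rho > 0`, each of the two allele draws comes from thresholding
#' a latent AR(1) Gaussian chain across SNPs, giving adjacent-SNP
#' correlation while preserving the per-SNP Hardy-Weinberg margins. No
#' missingness is generated.
#'
#' @param spec a [scenario_spec()].
#' @return A [genotype_matrix()] with SNPs `snp1..snpL` on chromosome 1 at
#'   consecutive positions.
#' @export
simulate_genotypes <- function(spec) {
  n <- spec$n
  L <- spec$l_snps
  maf <- runif(L, spec$maf_range[1], spec$maf_range[2])
  if (spec$ld_rho == 0) {
    dos <- matrix(rbinom(n * L, 2L, rep(maf, each = n)), n, L)
  } else {
    rho <- spec$ld_rho
    thr <- qnorm(maf, lower.tail = FALSE) # allele present when Z > thr
    hap <- function() {
      z <- matrix(rnorm(n * L), n, L)
      for (l in 2:L) {
        z[, l] <- rho * z[, l - 1] + sqrt(1 - rho^2) * z[, l]
      }
      sweep(z, 2, thr, ">") + 0
    }
    dos <- hap() + hap()
  }
  genotype_matrix(dos, paste0("snp", seq_len(L)),
                  rep(1L, L), seq_len(L) * 1000L)
}

#' Simulate a binary environmental exposure
#'
#' @param n sample count.
#' @param prevalence exposure frequency.
#' @param seed optional RNG seed.
#' @return Independent Bernoulli draws.
#' @export
simulate_environment <- function(n, prevalence = 0.248, seed = NULL) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 1L, prevalence)
}

.balanced_signs <- function(k) {
  sample(c(rep(1, ceiling(k / 2)), rep(-1, floor(k / 2))))
}

#' Simulate traits from a genotype panel and exposure
#'
#' Under the global null (`d = 0`) binary traits are Bernoulli draws at
#' the scenario prevalence and continuous traits pure standard-normal
#' noise. Under the alternative, `d` randomly placed SNPs interact with
#' the exposure: the linear predictor adds `sum_d beta_GE_d * G_d * E`
#' (plus `sum beta_G_d G_d` main effects when requested, with the special
#' set split into main-only, both, and interaction-only thirds).
#' Interaction magnitudes are uniform on the scenario's effect range with
#' exactly `ceiling(d/2)` positive signs; when a SNP carries both effects,
#' the two signs agree for about half of those SNPs.
#'
#' @param g a [genotype_matrix()].
#' @param e binary exposure vector.
#' @param spec a [scenario_spec()].
#' @return A list with `y`, `truth_idx` (indices of the interacting
#'   SNPs), `beta_ge` and `beta_g` (named by SNP index).
#' @export
simulate_traits <- function(g, e, spec) {
  n <- nrow(g$dosages)
  L <- ncol(g$dosages)
  stopifnot(length(e) == n, L == spec$l_snps)
  d <- spec$d
  intercept <- prevalence_intercept(spec$prevalence)

  if (d == 0) {
    y <- if (spec$family == "binomial") {
      rbinom(n, 1L, plogis(intercept))
    } else {
      rnorm(n)
    }
    return(list(y = y, truth_idx = integer(0),
                beta_ge = numeric(0), beta_g = numeric(0)))
  }

  rng <- spec$effect_range
  if (spec$main_effects) {
    special <- sample.int(L, 3 * d / 2)
    main_only <- special[seq_len(d / 2)]
    both <- special[(d / 2 + 1):d]
    int_only <- special[(d + 1):(3 * d / 2)]
    truth <- c(both, int_only)
    beta_ge <- runif(d, rng[1], rng[2]) * .balanced_signs(d)
    names(beta_ge) <- truth
    # main effects on main_only + both, magnitudes from the same interval;
    # among "both" SNPs the main-effect sign agrees with the interaction
    # sign for about half
    conc <- .balanced_signs(d / 2)
    beta_g_both <- runif(d / 2, rng[1], rng[2]) *
      sign(beta_ge[seq_len(d / 2)]) * conc
    beta_g_main <- runif(d / 2, rng[1], rng[2]) * .balanced_signs(d / 2)
    beta_g <- c(beta_g_main, beta_g_both)
    names(beta_g) <- c(main_only, both)
    eta_main <- g$dosages[, c(main_only, both), drop = FALSE] %*% beta_g
  } else {
    truth <- sample.int(L, d)
    beta_ge <- runif(d, rng[1], rng[2]) * .balanced_signs(d)
    names(beta_ge) <- truth
    beta_g <- numeric(0)
    eta_main <- 0
  }

  eta_int <- (g$dosages[, truth, drop = FALSE] * e) %*% beta_ge
  if (spec$family == "binomial") {
    y <- rbinom(n, 1L, plogis(intercept + eta_main + eta_int))
  } else {
    y <- as.vector(eta_main + eta_int + rnorm(n))
  }
  list(y = y, truth_idx = sort(as.integer(names(beta_ge))),
       beta_ge = beta_ge, beta_g = beta_g)
}

.binom_se <- function(p, n) sqrt(p * (1 - p) / n)

.next_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Empirical type I error study
#'
#' Replicates the global-null scenario, runs the requested methods on each
#' replicate, and reports the rejection rate at each nominal level with
#' its binomial Monte-Carlo standard error. Per-threshold risk-score rates
#' are computed over the replicates where that threshold selected at
#' least one SNP.
#'
#' @param spec a [scenario_spec()] with `d = 0`.
#' @param methods any of `"adabf"`, `"grs_m"`, `"grs_i"`, `"single"`.
#' @param b resampling replicates for the ADABF null ensemble.
#' @param thresholds risk-score selection thresholds.
#' @param nominal nominal significance levels.
#' @return An object of class `type1_study`: `rates` (method, nominal,
#'   rate, mc_se, n_eval), `per_threshold` rates for the risk scores, and
#'   the replicate-level P-values.
#' @export
run_type1_study <- function(spec, methods = c("adabf", "grs_m"),
                            b = 500, thresholds = grs_thresholds(),
                            nominal = c(0.05, 0.01)) {
  stopifnot(spec$d == 0)
  methods <- match.arg(methods, c("adabf", "grs_m", "grs_i", "single"),
                       several.ok = TRUE)
  reps <- spec$reps
  set.seed(spec$seed)

  p_adabf <- rep(NA_real_, reps)
  p_m <- matrix(NA_real_, reps, length(thresholds))
  p_m_comb <- rep(NA_real_, reps)
  p_i <- matrix(NA_real_, reps, length(thresholds))
  p_i_comb <- rep(NA_real_, reps)
  bon_rej <- bh_rej <- matrix(NA, reps, length(nominal))

  for (r in seq_len(reps)) {
    g <- simulate_genotypes(spec)
    e <- simulate_environment(spec$n, spec$e_prevalence)
    tr <- simulate_traits(g, e, spec)
    s <- prepare_samples(sample_table(tr$y, e, family = spec$family))
    marg <- fit_marginal_scan(g, s)

    if ("adabf" %in% methods) {
      res <- run_adabf(g, s, b = b, marginal = marg)
      p_adabf[r] <- res$p_overall
    }
    if ("grs_m" %in% methods) {
      res <- run_grs_m(g, s, thresholds, marginal = marg)
      p_m[r, ] <- res$per_threshold$p
      p_m_comb[r] <- res$combined_p
    }
    if ("grs_i" %in% methods) {
      res <- run_grs_i(g, s, thresholds, seed = .next_seed())
      p_i[r, ] <- res$per_threshold$p
      p_i_comb[r] <- res$combined_p
    }
    if ("single" %in% methods) {
      scan <- fit_interaction_scan(g, s)
      for (j in seq_along(nominal)) {
        bon_rej[r, j] <- length(bonferroni_select(scan$p, nominal[j])$selected) > 0
        bh_rej[r, j] <- length(bh_select(scan$p, nominal[j])$selected) > 0
      }
    }
  }

  rate_row <- function(method, p) {
    do.call(rbind, lapply(nominal, function(a) {
      ok <- !is.na(p)
      rate <- mean(p[ok] < a)
      data.frame(method = method, nominal = a, rate = rate,
                 mc_se = .binom_se(rate, sum(ok)), n_eval = sum(ok))
    }))
  }
  rates <- list()
  per_threshold <- list()
  if ("adabf" %in% methods) rates$adabf <- rate_row("ADABF", p_adabf)
  if ("grs_m" %in% methods) {
    rates$grs_m <- rate_row("GRS-M (M*)", p_m_comb)
    per_threshold$grs_m <- .threshold_rates("GRS-M", p_m, thresholds, nominal)
  }
  if ("grs_i" %in% methods) {
    rates$grs_i <- rate_row("GRS-I (I*)", p_i_comb)
    per_threshold$grs_i <- .threshold_rates("GRS-I", p_i, thresholds, nominal)
  }
  if ("single" %in% methods) {
    for (j in seq_along(nominal)) {
      rates[[paste0("bon", j)]] <-
        data.frame(method = "BON", nominal = nominal[j],
                   rate = mean(bon_rej[, j]),
                   mc_se = .binom_se(mean(bon_rej[, j]), reps),
                   n_eval = reps)
      rates[[paste0("bh", j)]] <-
        data.frame(method = "BH", nominal = nominal[j],
                   rate = mean(bh_rej[, j]),
                   mc_se = .binom_se(mean(bh_rej[, j]), reps),
                   n_eval = reps)
    }
  }
  structure(list(rates = do.call(rbind, c(rates, make.row.names = FALSE)),
                 per_threshold = do.call(rbind, per_threshold),
                 p_adabf = p_adabf, p_grs_m = p_m, p_grs_m_combined = p_m_comb,
                 p_grs_i = p_i, p_grs_i_combined = p_i_comb,
                 spec = spec, b = b),
            class = "type1_study")
}

.threshold_rates <- function(method, pmat, thresholds, nominal) {
  do.call(rbind, lapply(seq_along(thresholds), function(t) {
    do.call(rbind, lapply(nominal, function(a) {
      ok <- !is.na(pmat[, t])
      rate <- if (any(ok)) mean(pmat[ok, t] < a) else NA_real_
      data.frame(method = method, threshold = thresholds[t], nominal = a,
                 rate = rate,
                 mc_se = if (any(ok)) .binom_se(rate, sum(ok)) else NA_real_,
                 n_eval = sum(ok))
    }))
  }))
}

#' Empirical power, sensitivity and positive predictive value study
#'
#' Replicates an alternative scenario (`d > 0`). Polygenic methods score
#' a rejection when their overall or Bonferroni-combined P falls below
#' `alpha`; the single-marker comparators score a rejection when their
#' selected set is nonempty (any declared SNP; the true-only variant is
#' also logged). Pinpointing performance pools the resampling-FDR
#' selections of the ADABF pipeline and the single-marker selections
#' across replicates.
#'
#' @param spec a [scenario_spec()] with `d > 0`.
#' @param methods any of `"adabf"`, `"grs_m"`, `"grs_i"`, `"bon"`, `"bh"`.
#' @param b resampling replicates for the ADABF null ensemble.
#' @param thresholds risk-score selection thresholds.
#' @param alpha nominal significance level for power.
#' @return An object of class `power_study`: `power` (method, power,
#'   mc_se, power_true_only where applicable), `pinpoint` (per-method
#'   sensitivity, PPV and FDP from [sensitivity_ppv()]), and replicate
#'   logs.
#' @export
run_power_study <- function(spec, methods = c("adabf", "grs_m", "grs_i",
                                              "bon", "bh"),
                            b = 500, thresholds = grs_thresholds(),
                            alpha = 0.05) {
  stopifnot(spec$d > 0)
  methods <- match.arg(methods, c("adabf", "grs_m", "grs_i", "bon", "bh"),
                       several.ok = TRUE)
  reps <- spec$reps
  set.seed(spec$seed)

  log_df <- data.frame(adabf_p = rep(NA_real_, reps),
                       grs_m_p = NA_real_, grs_i_p = NA_real_,
                       adabf_found = NA_integer_, adabf_true = NA_integer_,
                       bon_found = NA_integer_, bon_true = NA_integer_,
                       bh_found = NA_integer_, bh_true = NA_integer_)

  for (r in seq_len(reps)) {
    g <- simulate_genotypes(spec)
    e <- simulate_environment(spec$n, spec$e_prevalence)
    tr <- simulate_traits(g, e, spec)
    s <- prepare_samples(sample_table(tr$y, e, family = spec$family))
    marg <- fit_marginal_scan(g, s)

    if ("adabf" %in% methods) {
      res <- run_adabf(g, s, b = b, marginal = marg)
      log_df$adabf_p[r] <- res$p_overall
      sel <- res$selected_index
      log_df$adabf_found[r] <- length(sel)
      log_df$adabf_true[r] <- length(intersect(sel, tr$truth_idx))
    }
    if ("grs_m" %in% methods) {
      log_df$grs_m_p[r] <- run_grs_m(g, s, thresholds,
                                     marginal = marg)$combined_p
    }
    if ("grs_i" %in% methods) {
      log_df$grs_i_p[r] <- run_grs_i(g, s, thresholds,
                                     seed = .next_seed())$combined_p
    }
    if (any(c("bon", "bh") %in% methods)) {
      scan <- fit_interaction_scan(g, s)
      if ("bon" %in% methods) {
        sel <- bonferroni_select(scan$p, alpha)$selected
        log_df$bon_found[r] <- length(sel)
        log_df$bon_true[r] <- length(intersect(sel, tr$truth_idx))
      }
      if ("bh" %in% methods) {
        sel <- bh_select(scan$p, alpha)$selected
        log_df$bh_found[r] <- length(sel)
        log_df$bh_true[r] <- length(intersect(sel, tr$truth_idx))
      }
    }
  }

  pw <- function(method, p) {
    ok <- !is.na(p)
    rate <- mean(p[ok] < alpha)
    data.frame(method = method, power = rate,
               mc_se = .binom_se(rate, sum(ok)), n_eval = sum(ok))
  }
  pw_count <- function(method, found, true_found) {
    rate <- mean(found > 0)
    data.frame(method = method, power = rate,
               mc_se = .binom_se(rate, reps), n_eval = reps,
               power_true_only = mean(true_found > 0))
  }
  power <- list()
  pinpoint <- list()
  if ("adabf" %in% methods) {
    power$adabf <- pw("ADABF", log_df$adabf_p)
    pinpoint$adabf <- cbind(method = "ADABF",
                            as.data.frame(sensitivity_ppv(
                              log_df$adabf_true, log_df$adabf_found,
                              reps, spec$d)))
  }
  if ("grs_m" %in% methods) power$grs_m <- pw("GRS-M (M*)", log_df$grs_m_p)
  if ("grs_i" %in% methods) power$grs_i <- pw("GRS-I (I*)", log_df$grs_i_p)
  if ("bon" %in% methods) {
    power$bon <- pw_count("BON", log_df$bon_found, log_df$bon_true)
    pinpoint$bon <- cbind(method = "BON",
                          as.data.frame(sensitivity_ppv(
                            log_df$bon_true, log_df$bon_found,
                            reps, spec$d)))
  }
  if ("bh" %in% methods) {
    power$bh <- pw_count("BH", log_df$bh_found, log_df$bh_true)
    pinpoint$bh <- cbind(method = "BH",
                         as.data.frame(sensitivity_ppv(
                           log_df$bh_true, log_df$bh_found,
                           reps, spec$d)))
  }
  power_df <- do.call(rbind, lapply(power, function(d) {
    if (!"power_true_only" %in% colnames(d)) d$power_true_only <- NA_real_
    d
  }))
  rownames(power_df) <- NULL
  structure(list(power = power_df,
                 pinpoint = do.call(rbind, c(pinpoint,
                                             make.row.names = FALSE)),
                 log = log_df, spec = spec, b = b, alpha = alpha),
            class = "power_study")
}

#' Pooled sensitivity, positive predictive value and false discovery
#' proportion
#'
#' Pools findings across replicates: sensitivity is the total number of
#' true findings over the total number of simulated interacting SNPs
#' (`reps * d`); PPV is the total number of true findings over the total
#' number of findings (reported missing when nothing was found); FDP is
#' `1 - PPV`.
#'
#' @param true_found per-replicate counts of true findings.
#' @param found per-replicate counts of all findings.
#' @param reps replicate count.
#' @param d number of true interacting SNPs per replicate.
#' @return A list with `sensitivity`, `ppv`, `fdp`.
#' @export
sensitivity_ppv <- function(true_found, found, reps, d) {
  stopifnot(length(true_found) == length(found))
  tot_true <- sum(true_found, na.rm = TRUE)
  tot_found <- sum(found, na.rm = TRUE)
  list(sensitivity = tot_true / (reps * d),
       ppv = if (tot_found > 0) tot_true / tot_found else NA_real_,
       fdp = if (tot_found > 0) 1 - tot_true / tot_found else NA_real_)
}
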