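---
title: "Polygenic gene-environment interaction testing with polygxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic gene-environment interaction testing with polygxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygxe)
```

## The model

A cohort of $n$ subjects carries a panel of $L$ biallelic autosomal SNPs
with dosages $G_{il} \in \{0,1,2\}$ counting minor alleles, a trait $Y_i$
(continuous or binary), an exposure $E_i$, and covariates $X_i$. Two
generalized linear models drive everything:

* the **marginal model**
  $g[E(Y_i)] = \beta_0 + \beta_{G_l} G_{il} + \beta_X' X_i$, used for
  screening and for the GRS-M weights;
* the **interaction model**
  $g[E(Y_i)] = \beta_0 + \beta_{G_l} G_{il} + \beta_E E_i +
  \beta_{GE_l} G_{il} E_i + \beta_X' X_i$, whose coefficient
  $\beta_{GE_l}$ is the quantity of interest.

The link is identity for gaussian traits and logit for binomial traits.
The global hypothesis is $H_0$: $\beta_{GE_1} = \cdots = \beta_{GE_L} = 0$
— no SNP in the panel interacts with the exposure.

### Exposure and trait scaling

Interaction effect sizes depend on the scale of $E$, so a continuous
exposure is affinely rescaled to $[0,1]$ (binary exposures are left as
0/1); $G_{il} E_i$ then lives on $[0,2]$, the same range as a dosage.
On the ADABF path a continuous trait is standardized to mean 0, SD 1
(sample SD, $n-1$ denominator), so that a single prior variance is
meaningful across traits. The risk-score models stay on the raw trait
scale, where their coefficients read directly as trait change (or log
odds ratio) per phenotype-increasing allele. Subjects missing the trait,
the exposure, or any covariate are dropped listwise before analysis, and
the exposure is rescaled using the post-deletion sample — rescaling
before exclusions would let unusable subjects define the range.

### The adaptive combination of Bayes factors

For each screened SNP the Wakefield approximate Bayes factor compares
$H_1$: $\beta_{GE} \sim N(0, W)$ against $H_0$: $\beta_{GE} = 0$:

$$\log BF = \tfrac12 \log\frac{\hat V}{\hat V + W} +
  \frac{\hat\beta_{GE}^2\, W}{2 \hat V (\hat V + W)}.$$

The implementation works entirely in log space; Wald ratios of 40 and
beyond remain finite. The default prior variance $W = 0.2^2 = 0.04$ says
that 95% of interaction effects lie in $(-0.4, 0.4)$ on the standardized
trait scale, or odds ratios in $(0.67, 1.49)$ — the classical modest-effect
prior. Smaller $W$ shrinks harder toward the null; the overall conclusion
is insensitive to $W$ within $\{0.01, 0.04, 0.09\}$ because observed and
resampled BFs use the same prior (a property the test suite checks by rank
correlation across simulated datasets).

The ordered log-BFs are accumulated into
$S_k = \sum_{l \le k} \log BF_{(l)}$, $k = 1, \dots, L$. Small $k$ is
sensitive to a few strong interactions, large $k$ to many weak ones; the
test adapts by taking the minimum P over $k$. Calibration is by
resampling: under $H_0$ the vector of estimates is approximately
$N(\mathbf 0, V)$ with $V_{ij} = R_{ij}\sqrt{\hat V_i \hat V_j}$, where
$R$ is the genotype correlation matrix — the correlation of association
statistics is well approximated by the correlation of genotypes, which is
why LD pruning is a computational convenience rather than a validity
requirement. Each of $B$ draws is converted to log-BFs and scores; the
P-value of $S_k$ is the fraction of resampled scores at least as large,
each resample's own P-values are computed against the other $B-1$, and the
overall P is the fraction of resamples whose minimum P is at most the
observed minimum P.

### Numerical conventions

* **Resampling floor.** With leave-one-out P-values some resample always
  attains a minimum P of exactly 0 (it beat all its peers somewhere), so a
  naive count would never report a result below $1/B$. When the *observed*
  minimum P is 0 — the observed profile beat every resample at some $k$ —
  the tie at the floor resolves in favor of the observed data: the count
  is 0 and the result is displayed as the interval "$< 1/B$". Away from
  the floor the count uses the usual $\le$ convention.
* **Covariance repair.** $V$ is assembled from pairwise-complete
  correlations and per-SNP variances, so it can be marginally indefinite.
  Eigenvalues are clipped at $10^{-8}$ and the matrix rescaled back to its
  original diagonal. An eigenvalue below $-10^{-6}$ (relative) indicates a
  structurally invalid input and raises an error instead.
* **Ties in BF order.** Sorting is stable with ties broken by SNP index,
  so the FDR-selected set is always a well-defined prefix of the
  descending-BF order.
* **Degenerate fits.** Monomorphic SNPs, constant interaction columns,
  non-convergent or separated logistic fits (IRLS, tolerance $10^{-8}$,
  50 iterations) are flagged and excluded, never imputed. Gaussian Wald
  tests use the $t$ reference with residual degrees of freedom, logistic
  tests the normal reference; at GWAS sample sizes the two coincide.

### Pinpointing SNPs: resampling FDR

Claiming the leading $k$ SNPs significant, the expected number of false
positives per resample is
$FP_{(k)} = \frac1B \sum_b \sum_l I(BF_l^{(b)} \ge BF_{(k)})$ and
$FDR_{(k)} = FP_{(k)}/k$. The selected set is the largest $k$ with
$FDR_{(k)} < 5\%$. This uses the same null ensemble as the overall test,
so pinpointing costs nothing extra.

### The risk-score comparators

GRS-M weights SNPs by their marginal coefficients $\hat\beta_{G_l}$,
selecting SNPs with marginal P below each of ten thresholds
(0.0001–0.1). Because selection uses marginal association rather than the
interaction itself, no sample splitting is needed. GRS-I weights SNPs by
$\hat\beta_{GE_l}$ estimated on a random half of the sample and tests on
the other half — the splitting preserves validity but halves both the
training information and the testing sample, which is why it is the least
powerful test. The raw score $\sum_l \hat\beta_l G_{il} I(P_l < P_t)$ is
rescaled by (number of available SNPs) / (sum of $|\hat\beta_l|$ over
available SNPs), putting it on the scale of a count of
phenotype-increasing alleles; "available" is evaluated per subject
(selected and nonmissing), which keeps scores comparable under
missingness. The rescaled score is invariant to multiplying all weights
by a positive constant and reduces to the plain allele count under unit
weights. The ten per-threshold tests are combined by multiplying the
minimum P by 10 — thresholds that select no SNP are skipped but still
counted in the multiplier, a deliberately conservative convention that
keeps the combined test valid whatever the panel size.

## What the simulator emulates

`simulate_genotypes()` draws MAFs uniformly (default $[0.05, 0.5]$) and
genotypes from Hardy–Weinberg proportions; optional LD comes from
thresholding two latent AR(1) Gaussian haplotype chains, which preserves
the per-SNP Hardy–Weinberg margins while correlating neighbors.
`simulate_environment()` is an independent Bernoulli exposure, default
prevalence 0.248 — a realistic population smoking rate. Traits come from

* null: $\text{logit} \Pr(Y=1) = -2.94$ (5% prevalence) or $Y = e$,
  $e \sim N(0,1)$;
* interaction-only: the linear predictor adds
  $\sum_{d=1}^D \beta_{GE_d} G_d E$ with $D = 20$ or 50 interacting SNPs
  placed uniformly at random each replicate, magnitudes uniform on
  $[\log 1.2, \log 1.4]$ / $[\log 1.4, \log 1.6]$ (binary) or
  $[0.05, 0.07]$ / $[0.07, 0.09]$ (continuous), signs balanced (exactly
  $\lceil D/2 \rceil$ positive);
* main + interaction: additionally $\sum_{d} \beta_{G_d} G_d$, with the
  special set split into main-only, both, and interaction-only thirds and
  sign concordance between the two effects for about half of the "both"
  SNPs.

What it does **not** emulate: real LD block structure, population
stratification, covariate confounding, genotype missingness, or
exposure–genotype dependence. Passing tests therefore show calibration
and relative power under idealized polygenic architectures, not
performance guarantees on any particular cohort.

## Study sizes and what to expect

The packaged studies run at a desk-scale profile chosen so a full
calibration experiment completes on one CPU in minutes: $n = 2000$
subjects, $L = 300$ SNPs, 1000 null replicates with $B = 500$ resamples,
500 replicates for power scenarios (the original study conditions —
$n = 16555$, $L \approx 7650$, 10000 replicates — scale all of these up).
Two consequences of the scaling are worth knowing:

* The combined GRS tests become *more* conservative than at full panel
  size, because the stringent selection thresholds rarely select any SNP
  at $L = 300$ while the Bonferroni multiplier stays at 10.
* The power advantage of GRS-M in the presence of SNP main effects is a
  large-sample phenomenon: it requires marginally informative weights
  ($z \approx \beta\sqrt{2n\,\text{maf}(1-\text{maf})} \gtrsim 4$), which
  effect sizes of 0.05–0.09 only reach at cohort-scale $n$. At $n = 2000$
  the adaptive test dominates all scenarios, and the corresponding
  ordering check in the acceptance suite documents this honestly rather
  than passing by construction.

## A small worked run

```{r example, eval = FALSE}
set.seed(7)
spec <- scenario_spec("gaussian", n = 2000, l_snps = 300, d = 20,
                      effect_size = "larger")
g  <- simulate_genotypes(spec)
e  <- simulate_environment(spec$n, spec$e_prevalence)
tr <- simulate_traits(g, e, spec)
s  <- prepare_samples(sample_table(tr$y, e, family = "gaussian"))

run_adabf(g, s, b = 1000, seed = 1)
run_grs_m(g, s)
run_grs_i(g, s, seed = 2)
```

## Known limitations

* Only PLINK 1 binary filesets are read; no VCF/BGEN, no dosage data, no
  X/Y chromosomes.
* One exposure per run; no mixed models or relatedness adjustment; no
  robust variances.
* The multivariate-normal resampling null relies on the asymptotic
  normality of the interaction MLEs; very rare variants or very low case
  counts can strain it.
* The windowed VIF pruning recomputes VIFs after each single removal
  (highest VIF first, ties to the lower-MAF then later SNP) — a fixed,
  reproducible order; other orders satisfying the same VIF bound exist.
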