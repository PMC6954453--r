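# polygxe

Polygenic tests for gene–environment (G×E) interaction in GWAS when no
external weights are available.

## The problem

Complex traits are polygenic, and so are their interactions with
environmental exposures: many SNPs each modify the effect of an exposure
(smoking, alcohol, physical activity, ...) by a small amount. Testing each
SNP×E term genome-wide and correcting for multiplicity is hopelessly
underpowered, and the usual workaround — a genetic risk score (GRS) weighted
by an external GWAS, tested as GRS×E — needs external summary statistics
that often do not exist for the population at hand.

`polygxe` implements the polygenic G×E tests that work with *internal*
weights only:

- **ADABF** — the adaptive combination of Bayes factors. For each SNP *l*
  passing a marginal screen (P < 0.05 in
  g[E(Yᵢ)] = β₀ + β_G Gᵢₗ + β'ₓXᵢ), the interaction model
  g[E(Yᵢ)] = β₀ + β_G Gᵢₗ + β_E Eᵢ + β_GE Gᵢₗ Eᵢ + β'ₓXᵢ
  yields the MLE β̂\_GE with variance V̂. Wakefield's approximate Bayes
  factor against H₀: β_GE = 0 under a N(0, W) prior (default W = 0.2² = 0.04)
  is

      BF = sqrt(V̂ / (V̂ + W)) · exp( β̂²_GE W / (2 V̂ (V̂ + W)) ).

  The ordered log-BFs are aggregated into cumulative scores
  S_k = Σ_{l≤k} log BF₍ₗ₎, the minimum-P over k is calibrated against B
  resamples of β̂\_GE ~ N(0, V) with V_ij = R_ij √(V̂ᵢV̂ⱼ) (R the genotype
  correlation matrix), and the same resamples give a resampling FDR
  FDR₍ₖ₎ = FP₍ₖ₎ / k for pinpointing individual interacting SNPs.
- **GRS-M** — risk score weighted by marginal SNP effects β̂_G, built at ten
  selection P-value thresholds, tested as score×E on the full sample, the
  ten tests Bonferroni-combined (M*).
- **GRS-I** — risk score weighted by interaction effects β̂\_GE estimated on
  a random training half, built and tested on the held-out half (I*).
- **BON / BH** — single-marker interaction scans with family-wise
  (Bonferroni) or FDR (Benjamini–Hochberg) control, as comparators.

Around these sit PLINK 1 bed/bim/fam input, the standard QC filters (call
rate ≥ 95%, Hardy–Weinberg P ≥ 5.7×10⁻⁷, MAF ≥ 1%), windowed
variance-inflation-factor LD pruning (window 50, step 5, VIF ≤ 2), and a
simulation harness that generates Hardy–Weinberg genotype panels, binary
exposures, and null/alternative traits for type I error, power, sensitivity
and PPV studies.

## Worked example

```r
library(polygxe)
set.seed(42)

# a synthetic cohort: 2000 subjects, 300 Hardy-Weinberg SNPs, binary
# exposure at 24.8% prevalence, 50 SNPs truly interacting with E
spec <- scenario_spec("gaussian", n = 2000, l_snps = 300, d = 50,
                      effect_size = "larger")
g  <- simulate_genotypes(spec)
e  <- simulate_environment(spec$n, spec$e_prevalence)
tr <- simulate_traits(g, e, spec)
s  <- prepare_samples(sample_table(tr$y, e, family = "gaussian"))

res <- run_adabf(g, s, b = 1000, seed = 1)
res
#> Adaptive combination of Bayes factors (G x E)
#>   screened SNPs: 16;  resamples: 1000;  prior variance W = 0.04
#>   overall P = 0.038
#>   SNPs with resampling FDR < 5%: snp120

run_grs_m(g, s)$combined_p
#> [1] 0.3748214
```

The overall P of 0.038 rejects H₀: no SNP in the panel interacts with E at
the 0.05 level — a single polygenic test, so no multiplicity correction is
needed. `selected_snps` lists the SNPs whose ordered Bayes factors survive
the resampling FDR at 5%: here `snp120`, which is indeed one of the 50
simulated interactors (pinpointing individual SNP×E is much harder than
detecting the aggregate signal, so recovering one of fifty weak
interactors is typical). The GRS-M combined P (0.37, not significant) is
the Bonferroni-corrected minimum over its ten threshold-specific score×E
tests — without SNP main effects the marginal weights carry little
information, which is exactly the regime where the adaptive test wins.

A thin command-line front end over the same functions ships in
`inst/cli/polygxe.R`:

```sh
Rscript inst/cli/polygxe.R adabf --bfile cohort --pheno pheno.tsv \
    --family gaussian --W 0.04 --B 100000 --seed 1 --out results/
```

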