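---
title: "Unweighted lipid genetic scores for Mendelian randomization: methods and design"
author: "lgsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unweighted lipid genetic scores for Mendelian randomization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Observational associations between blood lipids (triglycerides, HDL, LDL,
total cholesterol) and colorectal cancer (CRC) are vulnerable to confounding
and reverse causation, and statin studies are additionally distorted by
*confounding by indication*: the indication for the drug (high cholesterol)
may itself be associated with the outcome. Mendelian randomization (MR)
side-steps these problems by using genetic variants as instrumental
variables: alleles are assorted at conception, so a genetic score that
raises lifetime lipid exposure is (under the instrumental-variable
assumptions) unconfounded by lifestyle and cannot be caused by the disease.

`lgsmr` implements the complete analysis around *unweighted* allele-count
lipid genetic scores (LGS) in a case-control design, together with a
synthetic cohort generator that reproduces the statistical structure the
analysis assumes, so that every stage can be validated end to end.

# Instrument selection

Candidates arrive as a GWAS-catalog-style table: one row per SNP-trait
association with effect (lipid-raising) allele, GWAS p-value, population and
coordinates. `filter_catalog()` applies, in a fixed precedence order that
gives every row exactly one primary drop reason:

1. **Genome-wide significance** `p <= 5e-8`.
2. **Population restriction** (default "Caucasian").
3. **Reported effect allele** — without it the risk allele cannot be counted.
4. **Region-wise LD pruning**: among same-region candidates with pairwise
   r² > 0.2, only the most significant SNP is kept (`prune_by_region()`,
   greedy in ascending p; ties broken by position, then id, so the result is
   deterministic and invariant to catalog row order).
5. **Pleiotropy**: for the TG/HDL/LDL scores, SNPs associated at genome-wide
   significance with more than one of TG/HDL/LDL are excluded, so each score
   proxies a single exposure. The TC score is exempt: since TC is
   essentially the sum of LDL and HDL, it may share their SNPs.
6. **Excluded traits**: SNPs also tagged to alcohol, BMI, diabetes or
   inflammation (all plausibly CRC-related) are removed from every score.

Two conventions had to be fixed where common practice varies:

* **"Chromosomal region"** is taken as same chromosome within 1 Mb
  (`region_mb`), the usual clumping convention.
* **LD reference**: r² is the squared Pearson correlation of unphased
  dosages (composite LD) computed *among the study controls*
  (`controls_mask`), because phased haplotypes and external panels are not
  part of the data model. Both are configurable.

# Score construction

`align_risk_allele()` orients each catalog effect allele against the
genotype file's counted allele, allowing for the array reporting the
opposite strand (reverse complement). Palindromic A/T and C/G variants are
strand-ambiguous; the default policy excludes them with a warning (the
conservative MR convention), and an allele-frequency policy
(`palindromic = "freq"`, match tolerance 0.2) is available. A frequency near
0.5 is ambiguous under both readings and stays unresolvable.

`build_lgs()` then sums risk-allele dosages with **equal weights** — the
published per-SNP effect sizes are not part of the score. Missing genotypes
are mean-imputed with twice the control risk-allele frequency (default), so
every subject carries all four scores; a complete-case policy is available.
A score over m SNPs is bounded by [0, 2m] and integer-valued in the absence
of imputation.

# Association models

All inference is by maximum-likelihood logistic regression
(`fit_logistic()`, IRLS with convergence tolerance 1e-8 and at most 50
iterations; Wald standard errors from the observed information; Wald 95%
intervals). Rank-deficient designs are an error naming the aliased column;
separation is flagged at |beta| > 15 and the affected estimate withheld.

Every model adjusts for the **study-design covariates**: age, sex,
recruiting center, education, the first three ancestry principal components
(`genotype_pca()`: dosages centered at 2p and scaled by sqrt(2p(1-p)),
unit-norm subject coordinates, sign fixed by the largest-magnitude entry),
and the age-by-sex and region-by-sex interactions (region defaults to the
recruiting center; interactions are encoded contrast-style by hand so any
region grouping stays full rank). The design block is implemented as a
covariate set rather than a fitted composite score: that is the testable
reading, and it is what the adjusted models need. Statin models additionally
adjust for a confounder block (alcohol, waist-hip ratio, physical activity,
red meat, ASA/NSAID use).

The MR estimate itself (`score_crc_association()`) is the coefficient of
score/10: the odds ratio per 10 risk alleles, OR₁₀ = exp(10·β). Scaling is
exact (equivariance of the logistic slope), so per-allele and per-10-allele
reports are interchangeable; reversing every risk allele maps β to −β.
Stratified fits (e.g. by statin use) drop covariates that are constant or
aliased within a stratum, and the score-by-stratum interaction is tested by
Wald on the product term (a likelihood-ratio variant was considered and not
needed for the Wald-based tables produced here).

Supporting analyses: `hwe_scan()` (1-df chi-square against Hardy-Weinberg
proportions among controls, deviation flag at p < 0.001, monomorphic SNPs
reported at p = 1), `per_snp_scan()` (additive per-SNP models with a
Bonferroni threshold of 0.05 divided by the score's SNP count),
`compare_mean_alleles()` (case-control means ± sd; the default
pooled-variance t equals the linear-model comparison, Welch optional),
`or_by_allele_count()` (statin-use odds by 3-allele bins referenced to the
median bin — the bin width mirrors the usual "41–43 alleles" reference
grouping — plus a continuous per-allele OR reported as percent increase),
and the statin subgroup contrasts by lipophilicity, potency, sex and tumour
location with non-users as the common reference.

# Analytic power

`mrnd_binary_power()` implements the binary-outcome power formula of the
mRnd calculator. With case fraction K, total N, score-explained exposure
variance R², and causal odds ratio OR per exposure SD, the attenuated
score-outcome risk difference is

  b = K·(OR / (1 + K·(OR − 1)) − 1),

its sampling variance v = (K(1−K) − b²)/(N·R²), and the 1-df test has
noncentrality b²/v; power is evaluated at the central 0.95 quantile.
`min_detectable_or()` inverts the formula by bisection on (1, 10] to 1e-4,
capping the bracket just below the OR at which the approximation degenerates
(K(1−K) ≤ b²). At the package's reference design (1336 cases, 2744
controls, R² = 0.10, α = 0.05) the formula gives 81.4% power at OR = 1.33
and a minimum detectable OR of 1.32–1.33 at 80% power.

**A caveat the test suite quantifies.** The formula is a linear-probability
approximation. Our Monte-Carlo checks simulate the formula's own model
(risk linear in the exposure, IV Wald-ratio estimator, test at the formula
variance) and agree within 0.02 at five spot-check parameter sets. Under a
*logistic* data-generating process with an estimated variance, however, the
formula is optimistic — by roughly 0.01–0.05 near the reference design and
up to ~0.1 at strong effects (OR 2) — so its power figures should be read
as upper bounds for logistic outcomes.

# The synthetic cohort generator

`simulate_cohort()` produces a complete study whose defaults *are* the
reference design: 1336 cases / 2744 controls sampled from a source
population three times the study size; instrument sets of 22 (TG), 36
(HDL), 39 (LDL) and 49 (TC) SNPs, the TC set sharing 16 SNPs each with LDL
and HDL plus 17 TC-specific ones; allele frequencies uniform on (0.1, 0.9);
and scores explaining R² = 10% of their lipid's variance.

* **Genotypes** are sums of two independent haplotypes, so Hardy-Weinberg
  marginals hold exactly; within an LD block each haplotype is a Markov
  chain with the configured allele correlation ρ, giving dosage r² ≈ ρ²
  (decoy LD pairs use ρ = 0.9). A genotype missingness of 1% is applied by
  default; the rate is a free parameter because array missingness varies by
  platform and no single canonical value exists.
* **Lipids** are per-allele effects times risk dosage plus Gaussian noise
  whose variance is solved so the genetic part explains exactly `target_r2`
  of the total — hence the regression R² of lipid on score converges to the
  target, and rescaling all effects changes nothing. TC is derived
  deterministically as LDL + HDL (optionally + 0.2·TG, Friedewald-style),
  following the reading of TC as essentially the sum of the fractions.
* **Statin use** is Bernoulli with log-odds increasing in standardized LDL
  (the indication); **the outcome** is Bernoulli in the standardized
  lipids, statin use, sex, age and center. With a positive causal LDL
  effect and a zero statin effect this reproduces confounding by
  indication: the crude statin-CRC odds ratio is biased away from 1 and
  attenuates when the indication is adjusted for.
* **The instrument catalog** embeds labeled decoys violating each selection
  rule (sub-threshold p, wrong population, missing effect allele,
  same-region LD duplicates, pleiotropic SNPs including an rs174546-like
  tri-trait variant, excluded-trait tags). The keep/drop ground truth is
  derived from the construction, never from running the filter, so
  selection is tested against an independent label set.
* **Reproducibility**: one master seed; every stage draws its own
  sub-stream (`derive_seeds()`), so outputs are bit-identical given the
  configuration, and the pipeline manifest records stage seeds and MD5
  hashes of every file (floats written at 6 significant digits).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real allele-frequency spectra and long-range LD; the
frequency matching of the original case-control sampling design (covariates
are generated, not matched, which the adjusted analyses tolerate by
construction); genotyping batch effects; population stratification beyond
the optional ancestry-informative-marker block; and lipid measurement error
(lipids are latent in the cohort, as in the study design the package
targets, where blood lipids were not measured). TC-specific decoy SNPs
carry no phenotype effect, so the TC score's realized R² is below target —
acceptable because no analysis conditions on it.

# Problem sizes used by the validation suite

The suite favours a few deep checks at realistic sizes: explained-variance
calibration at n = 20 000 (tolerance ±0.01 absolute); LD and HWE behaviour
at n = 10 000; type-I error of the OR₁₀ test from 1000 full null-pipeline
replicates at the study size n = 4080 with reduced SNP counts (6/6/6/8),
accepted within the binomial 95% band [0.036, 0.064]; parameter recovery of
a per-allele OR of 1.02 (OR₁₀ ≈ 1.219) at n = 50 000; and Monte-Carlo power
at 4000 replicates per parameter set.

# Known limitations

* No Firth or exact logistic fallback: quasi-separated strata are flagged,
  not rescued; no conditional-logistic (matched-set) models.
* Wald intervals throughout; profile-likelihood intervals are not provided.
* The power module covers the binary-outcome formula only, without
  weak-instrument (F-statistic) corrections.
* Palindromic SNPs resolved by frequency remain a heuristic; the default
  exclusion is safer and costs a little power.

# A minimal session

```{r example}
library(lgsmr)

sim <- simulate_cohort(sim_config(seed = 2026L))
controls <- which(sim$cohort$case == 0)
report <- filter_catalog(sim$catalog, sim$genotypes,
                         controls_mask = controls)
sel <- sim$catalog[sim$catalog$trait == "LDL" &
                     sim$catalog$snp_id %in% report$kept$LDL, ]
ldl <- build_lgs(sim$genotypes, sel, trait = "LDL", controls = controls)
pcs <- genotype_pca(sim$genotypes, markers = sim$aim_ids)
X <- build_design_matrix(sim$cohort, design_spec(), pcs = pcs)
score_crc_association(ldl, sim$cohort, design = X, strata = "statin")

mrnd_binary_power(N = 4080, K = 1336 / 4080, R2xz = 0.10, OR = 1.33)
```
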