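---
title: "Estimating mtDNA abundance from array intensities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mtDNA abundance from array intensities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mitoabund)
library(dplyr)
```

## The estimation problem

Genotyping arrays carry a modest number of mitochondrial probes. Each
probe's log R ratio — `l2r = log2(observed / reference)` — reflects the
relative quantity of mtDNA hybridized at that probe, but only weakly:
mitochondrial probes cross-hybridize with nuclear homologs, have
probe-specific gains and offsets, and are noisy relative to the true
copy-number signal. Some probes are outright adversarial, with
intensities that *anticorrelate* with true copy number, so the naive
per-sample median over all MT probes can be a poor or even inverted
estimator.

The package's remedy is calibration against an orthogonal measurement:
off-target mitochondrial coverage from whole-exome sequencing, normalized
to the genomic coverage, is an independent proxy for the same quantity.
On a calibration subset with both measurements:

1. **Stage 1** regresses normalized MT coverage jointly on all MT probe
   L2R values; probes whose coefficient is significant at `alpha`
   (default 0.05) are selected.
2. **Stage 2** refits on the selected probes; the refitted coefficients
   become per-probe weights (`fit_probe_weights()`).
3. Per sample, the abundance estimate **mL2RMT** is the median of
   `weight * l2r` over selected probes (`compute_ml2rmt()`); the median
   (even counts: mean of the middle two) is robust to residual outlier
   probes. Note that regression weights flip the sign of
   anticorrelated probes, turning them back into informative ones.
4. Estimates are rescaled to mean 0, SD 1 within each 96-sample
   genotyping plate (`standardize_by_plate()`), absorbing plate-level
   intensity shifts. A cohort standardized this way has pooled mean 0 and
   pooled SD `sqrt((plate_size - 1) / plate_size)` ≈ 0.995, which prints
   as 0.99 at two decimals.

The weight-fitting regression includes an intercept and no covariates;
probes are not pre-filtered before the joint fit. Coverage may optionally
be z-scored first (`scale_coverage`), but the default leaves it raw since
plate standardization absorbs scale anyway. `compute_ml2rauto()` provides
the autosomal counterpart (median by default for symmetry with mL2RMT,
mean available), a proxy for total hybridized DNA used as an adjustment
covariate downstream.

## Sample quality control

`compute_sdl2r()` computes each sample's SD of autosomal L2R values;
excessive values flag noisy intensity profiles. The default exclusion
threshold is the fixed value 0.36; an adaptive mode (mean + 2 SD of the
cohort) is available because the fixed value is itself approximately two
SDs above the mean in large biobank data — which of the two generated the
printed threshold is not knowable, so both are provided.

`compute_baf_concordance()` is our concrete reading of B-allele-frequency
phase concordance, which detects contamination and mosaicism: at phased
heterozygous sites, the phase-aligned deviation is
`e_i = s_i (BAF_i - 0.5)` with `s_i = +1` when the alternate allele is on
haplotype A; the metric is the fraction of consecutive site pairs whose
deviations share a non-zero sign (zero deviations are skipped). Clean
samples have independent signs (concordance ≈ 0.5); a persistent allelic
imbalance produces runs (concordance → 1). Samples above 0.52 are
excluded. Because the statistic is a sign concordance, its null SD is
`0.5 / sqrt(sites)`: the 0.52 threshold implies thousands of sites per
sample, which is why the generator defaults to 2000 sites and why the
metric should not be computed from a handful of sites in practice.

Call rate below 99%, and upstream flags (sex anomaly, heterozygosity
outlier, ancestry, relatedness) when supplied as columns, complete the
exclusion set; these flags are consumed, not recomputed. A missing value
in a metric that is present excludes the sample (`missing_metric`) rather
than silently passing it.

## Derived phenotypes

The frailty index follows the Rockwood accumulation-of-deficits model:
the fraction of deficits present among items answered, over a 49-item
questionnaire. Under item missingness the denominator is the number of
answered items, with an 80% answered floor (39 of 49) below which the
index is missing — a fraction computed from very few items is more noise
than phenotype.

Tertiles use linear-interpolation quantiles (R type 7) at 1/3 and 2/3,
with boundary values assigned to the lower group; both conventions are
fixed because tertile membership must be deterministic. On a standard
normal distribution the lower cutoff converges to Φ⁻¹(1/3) ≈ −0.431,
which prints as −0.43. Exposures are standardized to z-scores over the
analysis subset (`standardize_exposure()`), so association slopes are
"per SD" effects; the constants are kept as attributes for
back-transformation.

## Associations and the two-lines test

`linear_association()` is ordinary least squares of the outcome on the
standardized exposure plus covariates, optionally within strata (sex, MT
haplogroup), with Wald 95% intervals and Benjamini–Hochberg q-values
across the returned rows (`bh_fdr()` wraps `stats::p.adjust`).

`two_lines_test()` detects slope reversals (the female age–abundance
relationship around menopause): separate covariate-adjusted regressions
below and above each candidate cutoff, with the cutoff chosen to minimize
the total residual sum of squares over a 1-unit grid; the U-shape flag
requires both segment slopes individually significant at 0.05 with
opposite signs. Two numerical choices matter:

* Candidate cutoffs must leave at least 10% of the observations (never
  fewer than 10) on each side. A breakpoint chosen by fit is a
  post-selection quantity; allowing tiny edge segments lets the search
  latch onto unstable slopes and inflates the U-shape false-positive rate
  under weak-slope monotone inputs to ~8%. Interior-only cutoffs bring it
  to ~3% in our null simulations while leaving breakpoint recovery on
  kinked data unaffected.
* RSS minimization is a deliberate simplification of the original
  two-lines procedure (which places the breakpoint by a "Robin Hood"
  reallocation rather than by fit). The simplification keeps the search
  transparent and the grid configurable; its residual type-I inflation in
  the weak-slope regime is the price, and is documented rather than
  hidden.

Ties in the RSS grid resolve to the lowest cutoff. Survival is analysed
as a linear association of follow-up time plus a logistic model for the
death flag; no proportional-hazards model is fitted since the workflow's
claim is directional, not a hazard estimate.

## PheWAS

`build_case_control()` implements incident-disease logic per phecode:
cases have their first matching event strictly after baseline and none on
or before (an event exactly at baseline counts as prevalent — the
conservative choice); prevalent samples are excluded entirely; among
non-cases, any event in the phecode's exclusion range at any time removes
the sample from the controls, preventing contamination by related
diseases. `run_phewas()` fits one logistic regression per qualifying
phecode of case status on tertile exposure plus covariates: the primary
contrast is ordinal (OR per tertile step), the secondary contrasts
compare the lowest or highest tertile against the middle one (the U-shape
check). Phecodes qualify with strictly more than 250 modeled cases
(counted after covariate-completeness filtering — the stricter and more
reproducible of the two possible orderings); separation or
non-convergence skips the phecode with a recorded reason. Q-values are BH
within contrast.

## Variant-level scan

`hwe_test()` defaults to the exact conditional Hardy–Weinberg test: given
the allele counts, the heterozygote-count distribution under equilibrium
is computed in closed form and the two-sided p-value sums all outcomes no
more probable than the observed one. A 1-df chi-square goodness-of-fit
variant is provided, but it is anti-conservative by orders of magnitude
on extreme small-count tables (e.g. 1/0/49), so the exact test — also the
default in standard GWAS toolchains — is the default here.
`filter_variants()` applies MAF > 5%, missingness < 2%, imputation
R² > 0.6 and HWE p ≥ 1e−5, reporting per-filter exclusion counts.

`gwas_scan()` regresses the standardized abundance on each variant's
additive dosage plus covariates (missing dosages dropped per variant) and
reports the genomic inflation factor λ = median(χ²)/0.45494, the null
median of χ²₁. `clump_signals()` groups genome-wide-significant variants
(p < 5e−8) greedily: the best remaining variant leads a locus, absorbing
significant variants within 1 Mb (a conventional window, since no single
locus width is canonical; the window is configurable); absorbed variants with dosage r² < 0.1 to the lead count
as additional independent signals.

## What the generator emulates

`simulate_cohort()` draws, per sample, a true log copy number composed of
a female age kink (slopes +0.12/−0.12 abundance-SD per year around age
55), a male decline (−0.06 per SD of age) and male offset (−0.05), BMI
and smoking effects (−0.05 per SD each), additive causal-variant effects
(default: one variant, MAF 0.3, effect 0.15 per allele), and unit
Gaussian residual. Around it:

* **Probes**: MT probes have gains U(0.5, 1.5) (adversarial fraction:
  U(−1, 0]), offsets N(0, 0.1), and noise SDs drawn from U(0.1, 0.4)
  times an MT-specific multiplier of 12. The multiplier encodes the
  cross-hybridization reality that the copy-number signal is small
  relative to MT-probe noise; it was calibrated once so that the weighted
  estimator's advantage over the unweighted median is manifest and the
  weighted-estimate-vs-coverage correlation is moderate rather than
  near-perfect, and then frozen. All noise is Gaussian: L2R is a log
  scale quantity with approximately symmetric error.
* **Kink magnitude**: ±0.12 SD/year is deliberately pronounced. A
  pre-registered power check showed that recovering the change point to
  ±1 year at n = 10,000 with unit residual SD on a 1-year grid requires
  a slope magnitude of at least ~0.12; weaker kinks yield the same
  qualitative reversal but a wider sampling distribution of the cutoff.
* **Coverage** is true copy number plus N(0, 0.5) noise, shifted (+5) to
  stay positive.
* **DNA-quality confounding**: a latent per-sample factor scales
  intensity noise log-normally (SD 0.2) and, when
  `missingness_confounding > 0`, multiplies genotype missingness and
  depresses overall hybridized DNA quantity — tying call rate, SDL2R and
  mL2Rauto together the way real DNA quality does. Setting the
  confounding to 0 decouples call rate from intensity noise exactly.
* **Genotypes** are drawn under Hardy–Weinberg equilibrium at the
  requested MAFs; missingness is per-sample Bernoulli.
* **Deficits** are Bernoulli with an age-increasing logit plus a latent
  frailty factor; ~2% of items are missing.
* **Disease**: one incident disease with odds ratio `disease_tertile_or`
  (default 1.5) per true-copy-number tertile step over a 10-year
  follow-up, a single Bernoulli draw rather than a survival process —
  matching the logistic analysis that consumes it. Small fractions of
  prevalent, related-code and unrelated-code events exercise the
  case/control exclusion logic. Mosaic samples (1%) receive a persistent
  phase-aligned BAF shift.

What the generator does **not** emulate: linkage disequilibrium between
variants (each is drawn independently; clumping tests construct LD
explicitly), sequencing reads, haplogroup sequence structure, batch
effects beyond plate shifts, and non-Gaussian intensity artifacts.
Passing tests therefore demonstrate correctness of the estimators and
error control under a clean, known generative model — not robustness to
every artifact of real array data.

## Problem sizes and determinism

All randomness flows from a single integer seed; with the seed fixed the
generator is bit-reproducible, and the pipeline writes MD5 checksums into
its manifest so reruns can be compared. Simulation-based checks in the
test suite use cohorts of 600–19,200 samples, 100–200 replicate seeds for
rate estimates, and 50 replicates for coverage checks — sizes at which
every property tested has comfortable statistical margin while the whole
suite runs in minutes on one core. Two statistical-design choices in the
acceptance tests deserve note: the U-shape false-positive criterion is
tested with a one-sided binomial acceptance region at size 5% (200 null
simulations), which tests the *rate* rather than flipping a coin on a
small batch; and the PheWAS false-discovery criterion spikes 20
strong-signal phecodes among 200 null ones so that the false-discovery
proportion has a stable denominator, making its mean across seeds a
concentrated estimate of the controlled quantity.

## A worked example

```{r example, eval = FALSE}
coh <- simulate_cohort(sim_config(n_samples = 2000, seed = 1))
w <- fit_probe_weights(coh$intensities, coh$coverage)
abund <- compute_ml2rmt(coh$intensities, w) |>
  standardize_by_plate(coh$phenotypes)
qc <- compute_sdl2r(coh$intensities) |>
  left_join(coh$phenotypes[c("sample_id", "call_rate")], by = "sample_id") |>
  left_join(baf_concordance_by_sample(coh$baf), by = "sample_id") |>
  apply_exclusions()
dat <- coh$phenotypes |>
  filter(sample_id %in% qc$sample_id[!qc$excluded]) |>
  left_join(abund, by = "sample_id")
linear_association(dat, "ml2rmt", c("age", "bmi"), covariates = "sex")
two_lines_test(filter(dat, sex == "female"), "age", "ml2rmt")
```

Or end to end, writing TSVs and a manifest:

```{r pipeline, eval = FALSE}
run_pipeline(list(out_dir = "run1", seed = 1,
                  simulate = list(n_samples = 2000)))
```

## Known limitations

* The BAF phase-concordance formula is one concrete reading of a metric
  that large-cohort pipelines compute inside dedicated mosaicism callers;
  alternatives (e.g. run-length statistics) would differ in power.
* The two-lines breakpoint is selected by fit, so its segment p-values
  are post-selection quantities; the interior-cutoff guard controls but
  does not eliminate the resulting optimism in the weak-slope regime.
* The PheWAS is logistic on a fixed follow-up window; time-to-event
  structure is ignored by design.
* Probe weights are interpretable regression coefficients, not optimal
  combination weights; a shrinkage estimator would trade
  interpretability for efficiency.
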