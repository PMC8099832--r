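#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] uses to
#' generate a cohort with known ground truth. The defaults define the study
#' conditions emulated throughout the package: a genotyping-array cohort in
#' which the true log mtDNA copy number declines with male sex and age,
#' reverses slope in women at the menopause change point, is shifted by BMI,
#' smoking and a handful of common causal variants, and leaks into
#' probe-level log2 intensity ratios (L2R) through per-probe gains and
#' offsets. A minority of probes are adversarial: their gain is negative or
#' zero, so an unweighted median over all probes is a degraded estimator.
#'
#' @param n_samples Number of samples to simulate.
#' @param n_mt_probes Number of mitochondrial probes.
#' @param n_auto_probes Number of autosomal probes.
#' @param plate_size Samples per genotyping plate (default 96).
#' @param frac_adversarial_probes Fraction of MT probes given a gain drawn
#'   from U(-1, 0], emulating probes whose intensity anticorrelates with
#'   true copy number.
#' @param probe_noise_sd_range Length-2 positive range; each probe's
#'   intrinsic noise SD is drawn uniformly from it.
#' @param mt_noise_multiplier Factor applied to MT-probe noise SDs on top
#'   of `probe_noise_sd_range` (default 12). Mitochondrial probes
#'   cross-hybridize with nuclear homologs, so their effective noise
#'   relative to the true copy-number signal is several-fold higher than
#'   that of autosomal probes; the default keeps the weighted estimate's
#'   correlation with exome coverage moderate rather than near-perfect.
#' @param beta_age Male age effect on true log copy number, per SD of age.
#' @param beta_sex Additive male-vs-female shift in true log copy number.
#' @param beta_bmi,beta_smoke Effects per SD of BMI / pack-years.
#' @param menopause_age Female change-point age in years (default 55).
#' @param pre_slope,post_slope Female age slopes (abundance units per year)
#'   below and above `menopause_age`.
#' @param copy_noise_sd Residual SD of true log copy number.
#' @param coverage_noise_sd SD of the noise added to true copy number to
#'   produce the normalized exome MT coverage.
#' @param missingness_confounding Strength of the coupling between a
#'   sample's latent DNA-quality factor and its genotype missingness; 0
#'   decouples call rate from intensity noise.
#' @param n_variants Number of genotyped variants.
#' @param causal_variant_effects List of `c(index, effect)` pairs: additive
#'   effect of each dosage unit on true log copy number.
#' @param mafs Optional vector of minor allele frequencies (length
#'   `n_variants`); by default the first (causal) variant has MAF 0.3 and
#'   the rest are drawn from U(0.05, 0.5).
#' @param disease_tertile_or Odds ratio per tertile step of true copy number
#'   for the simulated incident disease.
#' @param disease_base_rate Incident-disease probability in the middle
#'   tertile over the follow-up window.
#' @param n_deficit_items Number of frailty-index questionnaire items
#'   (default 49).
#' @param frac_female Fraction of female samples.
#' @param age_range Length-2 range of ages in years.
#' @param n_baf_sites Phased heterozygous sites per sample used for the
#'   B-allele-frequency phase-concordance QC metric (default 2000). The
#'   fixed 0.52 exclusion threshold sits close to the null value 0.5, so
#'   a few thousand sites are needed for a low false-exclusion rate
#'   (null SD is 0.5/sqrt(sites)); simulations that do not exercise the
#'   BAF rule can set this low to save memory.
#' @param frac_mosaic Fraction of samples given a persistent phase-aligned
#'   BAF shift (emulating mosaicism/contamination).
#' @param base_missingness Baseline per-genotype missingness rate.
#' @param noise_scale_sd SD of the log-normal per-sample intensity noise
#'   scale (the latent DNA-quality factor).
#' @param followup_days Follow-up window for incident disease, in days.
#' @param probe_gain,probe_offset Optional fixed MT-probe gains/offsets
#'   (scalar or length `n_mt_probes`); by default gains are drawn from
#'   U(0.5, 1.5) (adversarial probes from U(-1, 0]) and offsets from
#'   N(0, 0.1).
#' @param seed Integer seed; with the seed fixed the generator is
#'   bit-reproducible.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 200, seed = 1)
#' names(cfg)
sim_config <- function(n_samples = 2000,
                       n_mt_probes = 40,
                       n_auto_probes = 60,
                       plate_size = 96,
                       frac_adversarial_probes = 0.2,
                       probe_noise_sd_range = c(0.1, 0.4),
                       mt_noise_multiplier = 12,
                       beta_age = -0.06,
                       beta_sex = -0.05,
                       beta_bmi = -0.05,
                       beta_smoke = -0.05,
                       menopause_age = 55,
                       pre_slope = 0.12,
                       post_slope = -0.12,
                       copy_noise_sd = 1,
                       coverage_noise_sd = 0.5,
                       missingness_confounding = 1,
                       n_variants = 50,
                       causal_variant_effects = list(c(1, 0.15)),
                       mafs = NULL,
                       disease_tertile_or = 1.5,
                       disease_base_rate = 0.10,
                       n_deficit_items = 49,
                       frac_female = 0.5,
                       age_range = c(40, 70),
                       n_baf_sites = 2000,
                       frac_mosaic = 0.01,
                       base_missingness = 0.002,
                       noise_scale_sd = 0.2,
                       followup_days = 3650,
                       probe_gain = NULL,
                       probe_offset = NULL,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_mt_probes = n_mt_probes,
    n_auto_probes = n_auto_probes, plate_size = plate_size,
    frac_adversarial_probes = frac_adversarial_probes,
    probe_noise_sd_range = probe_noise_sd_range,
    mt_noise_multiplier = mt_noise_multiplier,
    beta_age = beta_age, beta_sex = beta_sex, beta_bmi = beta_bmi,
    beta_smoke = beta_smoke, menopause_age = menopause_age,
    pre_slope = pre_slope, post_slope = post_slope,
    copy_noise_sd = copy_noise_sd, coverage_noise_sd = coverage_noise_sd,
    missingness_confounding = missingness_confounding,
    n_variants = n_variants, causal_variant_effects = causal_variant_effects,
    mafs = mafs, disease_tertile_or = disease_tertile_or,
    disease_base_rate = disease_base_rate,
    n_deficit_items = n_deficit_items, frac_female = frac_female,
    age_range = age_range, n_baf_sites = n_baf_sites,
    frac_mosaic = frac_mosaic, base_missingness = base_missingness,
    noise_scale_sd = noise_scale_sd, followup_days = followup_days,
    probe_gain = probe_gain, probe_offset = probe_offset,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- setdiff(names(cfg),
                        c("causal_variant_effects", "mafs",
                          "probe_gain", "probe_offset"))
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      abort(sprintf("sim_config field `%s` must be finite and numeric.", f))
    }
  }
  counts <- c("n_samples", "n_mt_probes", "n_auto_probes", "n_variants",
              "n_deficit_items", "n_baf_sites")
  for (f in counts) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      abort(sprintf("sim_config field `%s` must be a positive count.", f))
    }
  }
  fracs <- c("frac_adversarial_probes", "frac_female", "frac_mosaic",
             "base_missingness", "disease_base_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("sim_config field `%s` must lie in [0, 1].", f))
    }
  }
  if (cfg$plate_size < 2) abort("`plate_size` must be at least 2.")
  if (length(cfg$probe_noise_sd_range) != 2 ||
      any(cfg$probe_noise_sd_range <= 0) ||
      diff(cfg$probe_noise_sd_range) < 0) {
    abort("`probe_noise_sd_range` must be an increasing pair of positive reals.")
  }
  if (cfg$disease_tertile_or <= 0) abort("`disease_tertile_or` must be positive.")
  if (cfg$mt_noise_multiplier <= 0) abort("`mt_noise_multiplier` must be positive.")
  if (!is.null(cfg$mafs)) {
    if (length(cfg$mafs) != cfg$n_variants ||
        any(cfg$mafs <= 0 | cfg$mafs > 0.5)) {
      abort("`mafs` must have length n_variants with values in (0, 0.5].")
    }
  }
  for (f in c("probe_gain", "probe_offset")) {
    v <- cfg[[f]]
    if (!is.null(v) && (!is.numeric(v) || anyNA(v) ||
                        !length(v) %in% c(1L, cfg$n_mt_probes))) {
      abort(sprintf("`%s` must be NULL, a scalar, or length n_mt_probes.", f))
    }
  }
  for (ce in cfg$causal_variant_effects) {
    if (length(ce) != 2 || !is.numeric(ce) || any(!is.finite(ce)) ||
        ce[1] < 1 || ce[1] > cfg$n_variants || ce[1] != round(ce[1])) {
      abort("each causal_variant_effects entry must be c(index, effect) with a valid index.")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, %d MT + %d autosomal probes, plates of %d\n",
              x$n_samples, x$n_mt_probes, x$n_auto_probes, x$plate_size))
  cat(sprintf("  female kink: %+.3f / %+.3f per year at age %g\n",
              x$pre_slope, x$post_slope, x$menopause_age))
  cat(sprintf("  %d variants (%d causal), disease OR per tertile %.2f, seed %d\n",
              x$n_variants, length(x$causal_variant_effects),
              x$disease_tertile_or, x$seed))
  invisible(x)
}
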