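#' Simulate a genotyping-array cohort with known mtDNA ground truth
#'
#' Draws a complete synthetic cohort under the generative model described in
#' the package vignette. The true log mtDNA copy number of sample *i* is
#'
#' \deqn{c_i = s(\mathrm{age}_i, \mathrm{sex}_i) + \beta_{bmi} z(bmi_i) +
#'   \beta_{smoke} z(packyears_i) + \sum_j \gamma_j g_{ij} + \epsilon_i}
#'
#' where the sex/age term is a piecewise-linear kink at `menopause_age` for
#' women (slope `pre_slope` below, `post_slope` above) and a monotone
#' decline plus the `beta_sex` shift for men. Each mitochondrial probe
#' reports `l2r = gain * c + offset + noise`, with a fraction of adversarial
#' probes whose gain is drawn from U(-1, 0]. Exome MT coverage is `c` plus
#' Gaussian noise (shifted to stay positive). A per-sample latent
#' DNA-quality factor scales intensity noise and, when
#' `missingness_confounding != 0`, also drives genotype missingness —
#' reproducing the confounding between call rate and intensity noise that
#' motivates the sample QC stage.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"mito_cohort"` with elements
#'   \describe{
#'     \item{truth}{per-sample ground truth (true log copy number, true
#'       tertile, incident-disease status, latent noise scale).}
#'     \item{probe_truth}{per-probe gain, offset, noise SD, adversarial flag.}
#'     \item{intensities}{long tibble `sample_id, probe_id, panel, l2r`.}
#'     \item{coverage}{`sample_id, normalized_mt_coverage`.}
#'     \item{phenotypes}{covariates, blood markers, frailty items, survival.}
#'     \item{baf}{phased-heterozygous-site B-allele frequencies per sample.}
#'     \item{events}{diagnosis events `sample_id, code, event_date`.}
#'     \item{phecode_map}{the small code-to-phecode map used by the events.}
#'     \item{genotypes}{list of a `variants` tibble and a samples-by-variants
#'       `dosages` matrix with missing entries as `NA`.}
#'   }
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_samples = 300, seed = 42))
#' coh$truth
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  sample_id <- sprintf("S%06d", seq_len(n))

  ## covariates ---------------------------------------------------------
  sex <- ifelse(runif(n) < cfg$frac_female, "female", "male")
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  bmi <- rnorm(n, 27, 4)
  packyears <- ifelse(runif(n) < 0.55, 0, rgamma(n, shape = 1.5, scale = 12))
  plate_idx <- ceiling(seq_len(n) / cfg$plate_size)
  plate_id <- sprintf("P%04d", plate_idx)
  batch_id <- sprintf("B%02d", ceiling(plate_idx / 24))

  ## latent DNA quality: scales intensity noise, drives missingness ----
  u <- rnorm(n)
  noise_scale <- exp(cfg$noise_scale_sd * u)
  ## idiosyncratic missingness variation exists regardless of confounding
  miss_rate <- pmin(0.5, cfg$base_missingness *
                      exp(cfg$missingness_confounding * u + 0.5 * rnorm(n)))
  call_rate <- 1 - miss_rate

  ## genotypes under HWE ------------------------------------------------
  v <- cfg$n_variants
  mafs <- cfg$mafs
  if (is.null(mafs)) {
    mafs <- runif(v, 0.05, 0.5)
    mafs[1] <- 0.3
  }
  geno <- vapply(mafs, function(p) rbinom(n, 2L, p), numeric(n))
  variant_id <- sprintf("var%04d", seq_len(v))
  chrom <- 1L + (seq_len(v) - 1L) %/% 25L
  pos <- ((seq_len(v) - 1L) %% 25L) * 200000L + 1L
  dimnames(geno) <- list(sample_id, variant_id)

  ## true log copy number ----------------------------------------------
  zs <- function(x) as.numeric(scale(x))
  female <- sex == "female"
  sexage <- numeric(n)
  rel <- age - cfg$menopause_age
  sexage[female] <- ifelse(rel[female] < 0,
                           cfg$pre_slope * rel[female],
                           cfg$post_slope * rel[female])
  sexage[!female] <- cfg$beta_sex + cfg$beta_age * zs(age)[!female]
  gterm <- numeric(n)
  for (ce in cfg$causal_variant_effects) {
    gterm <- gterm + ce[2] * unname(geno[, ce[1]])
  }
  c_true <- sexage + cfg$beta_bmi * zs(bmi) + cfg$beta_smoke * zs(packyears) +
    gterm + rnorm(n, 0, cfg$copy_noise_sd)

  ## exome coverage (shifted to stay non-negative) ----------------------
  coverage <- pmax(0, 5 + c_true + rnorm(n, 0, cfg$coverage_noise_sd))

  ## probes --------------------------------------------------------------
  p_mt <- cfg$n_mt_probes
  n_adv <- round(cfg$frac_adversarial_probes * p_mt)
  adversarial <- seq_len(p_mt) <= n_adv
  gain <- ifelse(adversarial, runif(p_mt, -1, 0), runif(p_mt, 0.5, 1.5))
  if (!is.null(cfg$probe_gain)) gain <- rep_len(cfg$probe_gain, p_mt)
  offset <- rnorm(p_mt, 0, 0.1)
  if (!is.null(cfg$probe_offset)) offset <- rep_len(cfg$probe_offset, p_mt)
  sd_mt <- cfg$mt_noise_multiplier *
    runif(p_mt, cfg$probe_noise_sd_range[1], cfg$probe_noise_sd_range[2])
  mt_l2r <- outer(c_true, gain) +
    matrix(offset, n, p_mt, byrow = TRUE) +
    matrix(rnorm(n * p_mt), n, p_mt) *
      outer(noise_scale, sd_mt)
  mt_ids <- sprintf("mt%03d", seq_len(p_mt))

  p_au <- cfg$n_auto_probes
  sd_au <- runif(p_au, cfg$probe_noise_sd_range[1], cfg$probe_noise_sd_range[2])
  ## overall hybridized DNA quantity falls with the quality factor when
  ## missingness confounding is on
  dna_qty <- -0.1 * cfg$missingness_confounding * u
  au_l2r <- dna_qty +
    matrix(rnorm(n * p_au), n, p_au) * outer(noise_scale, sd_au)
  au_ids <- sprintf("auto%03d", seq_len(p_au))

  intensities <- dplyr::bind_rows(
    tibble(
      sample_id = rep(sample_id, times = p_mt),
      probe_id = rep(mt_ids, each = n),
      panel = "MT",
      l2r = as.vector(mt_l2r)
    ),
    tibble(
      sample_id = rep(sample_id, times = p_au),
      probe_id = rep(au_ids, each = n),
      panel = "autosomal",
      l2r = as.vector(au_l2r)
    )
  )

  probe_truth <- tibble(
    probe_id = c(mt_ids, au_ids),
    panel = rep(c("MT", "autosomal"), c(p_mt, p_au)),
    gain = c(gain, rep(NA_real_, p_au)),
    offset = c(offset, rep(NA_real_, p_au)),
    noise_sd = c(sd_mt, sd_au),
    adversarial = c(adversarial & is.null(cfg$probe_gain),
                    rep(FALSE, p_au))
  )

  ## BAF at phased heterozygous sites ------------------------------------
  ns <- cfg$n_baf_sites
  mosaic <- runif(n) < cfg$frac_mosaic
  hap_a_alt <- matrix(runif(n * ns) < 0.5, n, ns)
  s_sign <- ifelse(hap_a_alt, 1, -1)
  baf_mat <- 0.5 + mosaic * s_sign * 0.05 + matrix(rnorm(n * ns, 0, 0.03), n, ns)
  baf_mat <- pmin(1, pmax(0, baf_mat))
  baf <- tibble(
    sample_id = rep(sample_id, times = ns),
    pos = rep(seq_len(ns) * 100000L, each = n),
    baf = as.vector(baf_mat),
    hap_a_alt = as.vector(hap_a_alt)
  ) %>% arrange(.data$sample_id, .data$pos)

  ## frailty questionnaire deficits --------------------------------------
  k <- cfg$n_deficit_items
  frail <- rnorm(n)
  p_def <- plogis(-2.2 + 0.04 * (age - 55) + 0.8 * frail)
  items <- matrix(rbinom(n * k, 1L, rep(p_def, k)), n, k)
  items[matrix(runif(n * k) < 0.02, n, k)] <- NA_integer_
  colnames(items) <- sprintf("fi_item_%02d", seq_len(k))

  ## incident disease driven by true-copy-number tertile -----------------
  tert <- tertile_discretize(c_true)
  t_num <- as.integer(tert$labels) - 1L  # 0, 1, 2
  p_dis <- plogis(qlogis(cfg$disease_base_rate) +
                    log(cfg$disease_tertile_or) * (t_num - 1L))
  incident <- rbinom(n, 1L, p_dis) == 1L
  onset_day <- ifelse(incident, sample.int(cfg$followup_days, n, replace = TRUE),
                      NA_integer_)
  baseline_date <- as.Date("2008-01-01") + sample.int(365L, n, replace = TRUE) - 1L

  phecode_map <- tibble(
    code = c("DX1", "DX2", "DX9"),
    phecode = c(204.1, 204.8, 495),
    excl_low = c(204, 204, 495),
    excl_high = c(204.99, 204.99, 496)
  )
  ev_target <- tibble(sample_id = sample_id[incident], code = "DX1",
                      event_date = baseline_date[incident] + onset_day[incident])
  prevalent <- runif(n) < 0.02
  ev_prev <- tibble(sample_id = sample_id[prevalent], code = "DX1",
                    event_date = baseline_date[prevalent] -
                      sample(30:1000, sum(prevalent), replace = TRUE))
  related <- runif(n) < 0.02
  ev_rel <- tibble(sample_id = sample_id[related], code = "DX2",
                   event_date = baseline_date[related] +
                     sample(-500:2000, sum(related), replace = TRUE))
  noise_ev <- runif(n) < 0.3
  ev_noise <- tibble(sample_id = sample_id[noise_ev], code = "DX9",
                     event_date = baseline_date[noise_ev] +
                       sample(-500:3000, sum(noise_ev), replace = TRUE))
  events <- bind_rows(ev_target, ev_prev, ev_rel, ev_noise) %>%
    arrange(.data$sample_id, .data$event_date)

  ## blood markers, survival ---------------------------------------------
  wbc <- exp(rnorm(n, log(6.5), 0.25))
  neutrophil_pct <- pmin(100, pmax(0, rnorm(n, 60, 8)))
  lymphocyte_pct <- pmin(100, pmax(0, rnorm(n, 30, 7)))
  survival_time <- runif(n, 0, 10)
  death_flag <- rbinom(n, 1L, plogis(-4 + 0.1 * (age - 55)))
  haplogroup <- sample(c("H", "U", "T", "J", "K"), n, replace = TRUE,
                       prob = c(0.45, 0.2, 0.15, 0.1, 0.1))

  ## apply per-sample missingness to genotypes ---------------------------
  dos <- geno * 1.0
  dos[matrix(runif(n * v), n, v) < miss_rate] <- NA_real_

  phenotypes <- tibble(
    sample_id = sample_id, age = age, sex = sex, bmi = bmi,
    packyears = packyears, plate_id = plate_id, batch_id = batch_id,
    call_rate = call_rate, baseline_date = baseline_date,
    wbc = wbc, neutrophil_pct = neutrophil_pct,
    lymphocyte_pct = lymphocyte_pct,
    pc1 = rnorm(n), pc2 = rnorm(n), haplogroup = haplogroup,
    survival_time = survival_time, death_flag = death_flag
  ) %>% dplyr::bind_cols(as_tibble(items))

  truth <- tibble(
    sample_id = sample_id, true_log_copy_number = c_true,
    age = age, sex = sex, bmi = bmi, packyears = packyears,
    plate_id = plate_id, batch_id = batch_id, call_rate = call_rate,
    noise_scale = noise_scale, mosaic = mosaic,
    true_tertile = tert$labels, incident_disease = incident,
    onset_day = onset_day
  )

  structure(
    list(
      config = cfg, truth = truth, probe_truth = probe_truth,
      intensities = intensities,
      coverage = tibble(sample_id = sample_id,
                        normalized_mt_coverage = coverage),
      phenotypes = phenotypes, baf = baf, events = events,
      phecode_map = phecode_map,
      genotypes = list(
        variants = tibble(variant_id = variant_id, chrom = chrom,
                          pos = pos, maf = mafs),
        dosages = dos
      )
    ),
    class = "mito_cohort"
  )
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat("<mito_cohort>\n")
  cat(sprintf("  %d samples, %d probes (%d MT), %d variants, %d events\n",
              nrow(x$truth),
              nrow(x$probe_truth),
              sum(x$probe_truth$panel == "MT"),
              nrow(x$genotypes$variants), nrow(x$events)))
  cat(sprintf("  seed %d\n", x$config$seed))
  invisible(x)
}
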