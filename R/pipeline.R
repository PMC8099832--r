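pipeline_defaults <- list(
  out_dir = "mitoabund_run",
  seed = 1L,
  simulate = list(),          # sim_config() overrides; NULL to read inputs
  inputs = NULL,              # named paths when not simulating
  alpha = 0.05,
  sdl2r_max = 0.36, sdl2r_mode = "fixed",
  baf_max = 0.52, call_rate_min = 0.99,
  min_cases = 250,
  maf_min = 0.05, miss_max = 0.02, r2_min = 0.6, hwe_min = 1e-5,
  p_threshold = 5e-8, r2_threshold = 0.1, window_bp = 1e6,
  assoc_exposures = c("age", "bmi", "packyears", "wbc", "frailty_index"),
  assoc_covariates = c("sex", "batch_id"),
  phewas_covariates = c("age", "sex"),
  gwas_covariates = c("age", "sex")
)

## covariates that are absent or constant in the analysis subset would make
## the design rank-deficient; drop them with a note
usable_covariates <- function(data, cols) {
  cols <- intersect(cols, names(data))
  keep <- vapply(cols, function(cl) {
    length(unique(stats::na.omit(data[[cl]]))) >= 2
  }, logical(1))
  if (any(!keep)) {
    inform(sprintf("dropping constant covariate(s): %s",
                   paste(cols[!keep], collapse = ", ")))
  }
  cols[keep]
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: simulate (or read inputs), fit probe
#' weights, compute and standardize abundance, sample QC, derived
#' phenotypes (frailty index, tertiles), per-SD associations and the
#' two-lines test on the female arm, the tertile PheWAS, and the filtered
#' variant scan with clumping. Each stage's output is written as a TSV
#' under `out_dir` so any stage can be re-run independently from
#' intermediates, and a manifest records file, stage, row count and MD5
#' checksum. All randomness flows from the single configured seed.
#'
#' @param config A named list (or path to a YAML file) overriding the
#'   pipeline defaults: `out_dir`, `seed`, `simulate` (a list of
#'   [sim_config()] overrides, or `NULL` to read `inputs`), `inputs`
#'   (named paths `intensities`, `coverage`, `phenotypes`, `events`,
#'   `phecode_map`, optionally `baf` and `genotypes_vcf`), plus the QC,
#'   PheWAS and variant-filter thresholds.
#' @return The manifest tibble, invisibly; also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- list()
  emit <- function(x, stage, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    write_table(x, path)
    manifest[[length(manifest) + 1]] <<- tibble(
      file = basename(path), stage = stage, n_rows = nrow(x),
      md5 = unname(tools::md5sum(path))
    )
    invisible(path)
  }

  ## -- inputs ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    cohort <- run_stage("simulate", {
      simulate_cohort(do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed))))
    })
    intensities <- cohort$intensities
    coverage <- cohort$coverage
    phenotypes <- cohort$phenotypes
    events <- cohort$events
    phecode_map <- cohort$phecode_map
    baf <- cohort$baf
    genotypes <- cohort$genotypes
    emit(cohort$truth, "simulate", "truth")
  } else {
    inp <- cfg$inputs
    if (is.null(inp)) abort("either `simulate` or `inputs` must be given.")
    intensities <- run_stage("read", read_table(inp$intensities, "intensities"))
    coverage <- run_stage("read", read_table(inp$coverage, "coverage"))
    phenotypes <- run_stage("read", read_table(inp$phenotypes, "phenotypes"))
    events <- if (!is.null(inp$events)) read_table(inp$events, "events")
    phecode_map <- if (!is.null(inp$phecode_map)) read_table(inp$phecode_map, "phecode_map")
    baf <- if (!is.null(inp$baf)) read_table(inp$baf, "baf")
    genotypes <- if (!is.null(inp$genotypes_vcf)) read_dosages_vcf(inp$genotypes_vcf)
  }

  ## -- probe weights and abundance -------------------------------------
  weights <- run_stage("weights",
                       fit_probe_weights(intensities, coverage, alpha = cfg$alpha))
  emit(weights, "weights", "probe_weights")

  abundance <- run_stage("abundance", {
    ml2rmt <- compute_ml2rmt(intensities, weights) %>%
      standardize_by_plate(phenotypes)
    ml2rauto <- compute_ml2rauto(intensities) %>%
      standardize_by_plate(phenotypes, value = "ml2rauto_raw") %>%
      select("sample_id", "ml2rauto_raw", "ml2rauto")
    left_join(ml2rmt, ml2rauto, by = "sample_id")
  })
  emit(abundance, "abundance", "abundance")

  ## -- sample QC --------------------------------------------------------
  qc <- run_stage("qc", {
    m <- compute_sdl2r(intensities) %>%
      left_join(phenotypes[c("sample_id", "call_rate")], by = "sample_id")
    if (!is.null(baf)) {
      m <- left_join(m, baf_concordance_by_sample(baf), by = "sample_id")
    }
    apply_exclusions(m, sdl2r_max = cfg$sdl2r_max, sdl2r_mode = cfg$sdl2r_mode,
                     baf_max = cfg$baf_max, call_rate_min = cfg$call_rate_min)
  })
  emit(qc, "qc", "sample_qc")
  kept <- qc$sample_id[!qc$excluded]
  if (!length(kept)) {
    abort("pipeline stage `qc` failed: all samples excluded; nothing to analyse downstream.")
  }
  inform(sprintf("qc: retained %d / %d samples.", length(kept), nrow(qc)))

  ## -- derived phenotypes ----------------------------------------------
  pheno <- run_stage("pheno", {
    ph <- dplyr::filter(phenotypes, .data$sample_id %in% kept) %>%
      left_join(abundance[c("sample_id", "ml2rmt", "ml2rauto")],
                by = "sample_id")
    fi_cols <- grep("^fi_item_", names(ph), value = TRUE)
    if (length(fi_cols)) {
      ph$frailty_index <- frailty_index(ph[fi_cols])
    }
    usable <- !is.na(ph$ml2rmt)
    tert <- tertile_discretize(ph$ml2rmt[usable])
    ph$tertile <- factor(NA_character_, levels = c("T1", "T2", "T3"))
    ph$tertile[usable] <- tert$labels
    attr(ph, "tertile_spec") <- tert$spec
    ph
  })
  emit(select(pheno, -dplyr::starts_with("fi_item_")), "pheno", "phenotypes_derived")

  ## -- associations and two-lines ---------------------------------------
  assoc <- run_stage("assoc", {
    ex <- intersect(cfg$assoc_exposures, names(pheno))
    ex <- ex[vapply(ex, function(e) sum(!is.na(pheno[[e]])) > 3 &&
                      sd(pheno[[e]], na.rm = TRUE) > 0, logical(1))]
    linear_association(pheno, "ml2rmt", ex,
                       covariates = usable_covariates(pheno, cfg$assoc_covariates))
  })
  emit(assoc, "assoc", "associations")

  women <- dplyr::filter(pheno, .data$sex == "female", !is.na(.data$ml2rmt))
  if (nrow(women) >= 40) {
    tl <- run_stage("twolines", two_lines_test(women, "age", "ml2rmt"))
    emit(glance(tl), "twolines", "twolines")
  }

  ## -- PheWAS -----------------------------------------------------------
  if (!is.null(events) && !is.null(phecode_map)) {
    phw <- run_stage("phewas", {
      baselines <- phenotypes[c("sample_id", "baseline_date")] %>%
        dplyr::filter(.data$sample_id %in% kept)
      asg <- purrr::map(unique(phecode_map$phecode), function(pc) {
        build_case_control(events, phecode_map, baselines, pc) %>%
          mutate(phecode = pc)
      }) %>% bind_rows()
      run_phewas(pheno, asg,
                 covariates = usable_covariates(pheno, cfg$phewas_covariates),
                 min_cases = cfg$min_cases)
    })
    emit(phw, "phewas", "phewas")
  }

  ## -- variant scan ------------------------------------------------------
  if (!is.null(genotypes)) {
    gw <- run_stage("gwas", {
      dos <- genotypes$dosages[kept, , drop = FALSE]
      metrics <- compute_variant_metrics(dos)
      vt <- left_join(genotypes$variants, metrics, by = "variant_id")
      retained <- filter_variants(vt, maf_min = cfg$maf_min,
                                  miss_max = cfg$miss_max,
                                  r2_min = cfg$r2_min, hwe_min = cfg$hwe_min)
      scan <- gwas_scan(pheno, dos[, retained$variant_id, drop = FALSE],
                        outcome = "ml2rmt",
                        covariates = usable_covariates(pheno, cfg$gwas_covariates))
      loci <- clump_signals(scan, retained, dos,
                            p_threshold = cfg$p_threshold,
                            r2_threshold = cfg$r2_threshold,
                            window_bp = cfg$window_bp)
      list(scan = scan, loci = loci, retained = retained)
    })
    emit(left_join(gw$scan$results,
                   gw$retained[c("variant_id", "chrom", "pos")],
                   by = "variant_id"),
         "gwas", "gwas_summary")
    if (nrow(gw$loci)) emit(gw$loci, "gwas", "gwas_loci")
    inform(sprintf("gwas: lambda_GC = %.3f over %d variants.",
                   gw$scan$lambda_gc, nrow(gw$scan$results)))
  }

  manifest <- bind_rows(manifest)
  write_table(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(manifest)
}
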