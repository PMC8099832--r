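phemap <- tibble::tibble(
  code = c("T1", "T2", "R1", "U1"),
  phecode = c(100.1, 100.1, 100.5, 300),
  excl_low = c(100, 100, 100, 300),
  excl_high = c(100.99, 100.99, 100.99, 301)
)

bl <- function(ids, date = as.Date("2010-01-01")) {
  tibble::tibble(sample_id = ids, baseline_date = date)
}

test_that("incident/prevalent/related logic assigns the documented statuses", {
  ids <- c("case_after", "prev_before", "prev_at", "rel_only", "clean")
  ev <- tibble::tibble(
    sample_id = c("case_after", "prev_before", "prev_at", "rel_only"),
    code = c("T1", "T1", "T2", "R1"),
    event_date = as.Date(c("2010-04-11", "2009-12-22", "2010-01-01",
                           "2012-06-01"))
  )
  out <- build_case_control(ev, phemap, bl(ids), 100.1)
  st <- setNames(as.character(out$status), out$sample_id)
  expect_identical(st[["case_after"]], "case")
  expect_identical(st[["prev_before"]], "excluded")   # prevalent
  expect_identical(st[["prev_at"]], "excluded")       # baseline tie is prevalent
  expect_identical(st[["rel_only"]], "excluded")      # related-disease range
  expect_identical(st[["clean"]], "control")
  expect_equal(out$onset_date[out$sample_id == "case_after"],
               as.Date("2010-04-11"))
  # a case with an additional related event stays a case
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(sample_id = "case_after",
                                             code = "R1",
                                             event_date = as.Date("2013-01-01")))
  out2 <- build_case_control(ev2, phemap, bl(ids), 100.1)
  expect_identical(as.character(out2$status[out2$sample_id == "case_after"]),
                   "case")
  expect_error(build_case_control(ev, phemap, bl(ids), 999), "absent")
})

test_that("status partitions samples and is invariant to event ordering", {
  set.seed(23)
  ids <- sprintf("s%04d", 1:400)
  ev <- tibble::tibble(
    sample_id = sample(ids, 600, replace = TRUE),
    code = sample(c("T1", "T2", "R1", "U1"), 600, replace = TRUE),
    event_date = as.Date("2010-01-01") + sample(-700:2000, 600, replace = TRUE)
  )
  out <- build_case_control(ev, phemap, bl(ids), 100.1)
  expect_setequal(out$sample_id, ids)
  expect_equal(nrow(out), length(ids))
  expect_false(anyNA(out$status))
  shuffled <- ev[sample(nrow(ev)), ]
  out2 <- build_case_control(shuffled, phemap, bl(ids), 100.1)
  expect_equal(dplyr::arrange(out, sample_id), dplyr::arrange(out2, sample_id))
})

test_that("phecodes at or below the case threshold are dropped", {
  set.seed(24)
  n <- 2000
  dat <- tibble::tibble(
    sample_id = sprintf("s%04d", 1:n),
    tertile = factor(sample(c("T1", "T2", "T3"), n, TRUE),
                     levels = c("T1", "T2", "T3"))
  )
  mk_asg <- function(pc, n_cases) {
    tibble::tibble(
      sample_id = dat$sample_id,
      phecode = pc,
      status = factor(c(rep("case", n_cases), rep("control", n - n_cases)),
                      levels = c("case", "control", "excluded"))
    )
  }
  asg <- dplyr::bind_rows(mk_asg(100.1, 200), mk_asg(300, 400))
  res <- run_phewas(dat, asg, min_cases = 250, contrasts = "ordinal")
  expect_false(100.1 %in% res$phecode)
  expect_true(300 %in% res$phecode)
  skipped <- attr(res, "skipped")
  expect_match(skipped$reason[skipped$phecode == 100.1], "not > 250")
})

test_that("the generator's tertile odds ratio is recovered by the ordinal contrast", {
  coh <- simulate_cohort(light_config(12000, seed = 25,
                                      disease_tertile_or = 1.5,
                                      frac_mosaic = 0))
  dat <- dplyr::transmute(coh$truth, sample_id,
                          tertile = true_tertile, age, sex)
  asg <- tibble::tibble(
    sample_id = coh$truth$sample_id,
    phecode = 204.1,
    status = factor(ifelse(coh$truth$incident_disease, "case", "control"),
                    levels = c("case", "control", "excluded"))
  )
  res <- run_phewas(dat, asg, covariates = c("age", "sex"), min_cases = 250)
  ord <- dplyr::filter(res, contrast == "ordinal")
  expect_true(ord$ci_low <= 1.5 && 1.5 <= ord$ci_high)
  # pairwise contrasts agree in direction with the monotone ordinal OR
  t3 <- dplyr::filter(res, contrast == "T3_vs_T2")
  t1 <- dplyr::filter(res, contrast == "T1_vs_T2")
  expect_gt(t3$odds_ratio, 1)
  expect_lt(t1$odds_ratio, 1)
})

test_that("separation is skipped with a reason instead of reported", {
  set.seed(26)
  n <- 1200
  tert <- factor(sample(c("T1", "T2", "T3"), n, TRUE),
                 levels = c("T1", "T2", "T3"))
  dat <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), tertile = tert)
  # perfectly separating: cases exactly the T3 samples
  asg <- tibble::tibble(
    sample_id = dat$sample_id, phecode = 1.1,
    status = factor(ifelse(tert == "T3", "case", "control"),
                    levels = c("case", "control", "excluded"))
  )
  res <- run_phewas(dat, asg, min_cases = 100, contrasts = "T3_vs_T2")
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "skipped")$reason, "separation")
})

test_that("the shipped synthetic phecode map loads and drives assignment", {
  path <- system.file("extdata", "phecode_map_synthetic.tsv",
                      package = "mitoabund")
  map <- suppressMessages(read_table(path, "phecode_map"))
  expect_true(all(c("code", "phecode", "excl_low", "excl_high") %in% names(map)))
  # each exclusion range contains its own phecode
  expect_true(all(map$excl_low <= map$phecode & map$phecode <= map$excl_high))
  ev <- tibble::tibble(sample_id = "s1", code = "C91.1",
                       event_date = as.Date("2011-05-01"))
  out <- build_case_control(ev, map, bl("s1"), 204.1)
  expect_identical(as.character(out$status), "case")
})
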