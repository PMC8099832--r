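test_that("compute_l2r matches direct evaluation and is scale invariant", {
  expect_identical(compute_l2r(500, 500), 0)
  expect_identical(compute_l2r(1000, 500), 1)
  expect_equal(compute_l2r(300, 400), -0.41504, tolerance = 1e-4)
  set.seed(5)
  x <- runif(20, 10, 1000); y <- runif(20, 10, 1000); k <- runif(20, 0.01, 50)
  expect_equal(compute_l2r(k * x, k * y), compute_l2r(x, y), tolerance = 1e-12)
  expect_error(compute_l2r(0, 10, probe_id = "mt007", sample_id = "S1"),
               "mt007")
  expect_error(compute_l2r(5, -1), "Non-positive")
})

test_that("probe_l2r derives l2r from intensities and rejects duplicates", {
  tb <- tibble::tibble(sample_id = "s1", probe_id = c("p1", "p2"),
                       panel = "MT",
                       observed_intensity = c(1000, 300),
                       reference_intensity = c(500, 400))
  out <- probe_l2r(tb)
  expect_equal(out$l2r, c(1, log2(0.75)))
  dup <- tibble::tibble(sample_id = "s1", probe_id = "p1", panel = "MT",
                        l2r = c(0, 1))
  expect_error(probe_l2r(dup), "duplicated")
  expect_error(probe_l2r(tb[, -2]), "missing column")
})

test_that("a perfect predictor probe gets weight 1, zero intercept, selected", {
  set.seed(9)
  cov <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                        normalized_mt_coverage = runif(40, 1, 3))
  ints <- tidyr::crossing(sample_id = cov$sample_id,
                          probe_id = c("p1", "p2")) |>
    dplyr::mutate(panel = "MT",
                  l2r = ifelse(probe_id == "p1",
                               cov$normalized_mt_coverage[match(sample_id, cov$sample_id)],
                               rnorm(dplyr::n())))
  w <- suppressWarnings(fit_probe_weights(ints, cov))
  expect_true(w$selected[w$probe_id == "p1"])
  expect_equal(w$weight[w$probe_id == "p1"], 1, tolerance = 1e-6)
  expect_equal(attr(w, "intercept"), 0, tolerance = 1e-6)
})

test_that("pure-noise probes are rarely selected at alpha = 0.05", {
  hits <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    n <- 150
    cov <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                          normalized_mt_coverage = rnorm(n, 2, 0.5))
    ints <- tibble::tibble(sample_id = rep(cov$sample_id, 2),
                           probe_id = rep(c("sig", "noise"), each = n),
                           panel = "MT",
                           l2r = c(cov$normalized_mt_coverage + rnorm(n, 0, 0.3),
                                   rnorm(n)))
    w <- fit_probe_weights(ints, cov)
    w$selected[w$probe_id == "noise"]
  }, logical(1))
  expect_lte(sum(hits), 9)  # ~5% expected under the null
})

test_that("weight fitting validates its calibration set", {
  coh <- shared_cohort()
  tiny_cov <- coh$coverage[1:10, ]  # fewer samples than the 20 probes
  expect_error(fit_probe_weights(coh$intensities, tiny_cov),
               "more samples than probes")
  # collinear probes: duplicate a probe under a new id
  mt <- dplyr::filter(coh$intensities, panel == "MT")
  dup <- dplyr::filter(mt, probe_id == "mt001") |>
    dplyr::mutate(probe_id = "mt_copy")
  expect_error(fit_probe_weights(dplyr::bind_rows(mt, dup), coh$coverage),
               "collinear")
})

test_that("weighted median follows the stated conventions", {
  mk <- function(l2r, ids) tibble::tibble(sample_id = "s1", probe_id = ids,
                                          panel = "MT", l2r = l2r)
  w3 <- tibble::tibble(probe_id = c("a", "b", "c"), weight = 1,
                       p_value = 0.01, selected = TRUE)
  expect_equal(compute_ml2rmt(mk(c(0.1, 0.2, 0.3), c("a", "b", "c")), w3)$ml2rmt_raw,
               0.2)
  w2 <- tibble::tibble(probe_id = c("a", "b"), weight = c(2, 1),
                       p_value = 0.01, selected = TRUE)
  # weighted values {0.2, 0.3}: even count -> mean of the middle two
  expect_equal(compute_ml2rmt(mk(c(0.1, 0.3), c("a", "b")), w2)$ml2rmt_raw, 0.25)
  w1 <- tibble::tibble(probe_id = c("a", "b", "c"), weight = c(0, 0, 2),
                       p_value = c(0.9, 0.9, 0.01),
                       selected = c(FALSE, FALSE, TRUE))
  expect_equal(compute_ml2rmt(mk(c(5, 7, 0.4), c("a", "b", "c")), w1)$ml2rmt_raw,
               0.8)
})

test_that("unweighted variants use plain medians over all probes or a subset", {
  coh <- shared_cohort()
  ua <- compute_ml2rmt(coh$intensities, method = "unweighted_all")
  mt <- dplyr::filter(coh$intensities, panel == "MT")
  byhand <- tapply(mt$l2r, mt$sample_id, median)
  expect_equal(ua$ml2rmt_raw, as.numeric(byhand[ua$sample_id]))
  sub <- c("mt001", "mt002", "mt003")
  us <- compute_ml2rmt(coh$intensities, method = "unweighted_subset",
                       subset_probes = sub)
  mts <- dplyr::filter(mt, probe_id %in% sub)
  byhand2 <- tapply(mts$l2r, mts$sample_id, median)
  expect_equal(us$ml2rmt_raw, as.numeric(byhand2[us$sample_id]))
})

test_that("plate standardization matches hand computation and flags degenerate plates", {
  est <- tibble::tibble(sample_id = c("a", "b", "c", "d", "e", "f"),
                        ml2rmt_raw = c(1, 2, 3, 5, 5, 5))
  plates <- tibble::tibble(sample_id = est$sample_id,
                           plate_id = rep(c("P1", "P2"), each = 3))
  expect_warning(out <- standardize_by_plate(est, plates), "zero spread")
  expect_equal(out$ml2rmt[out$plate_id == "P1"], c(-1, 0, 1))
  expect_true(all(is.na(out$ml2rmt[out$plate_id == "P2"])))

  single <- tibble::tibble(sample_id = c("a", "b", "c"),
                           ml2rmt_raw = c(1, 2, 9))
  sp <- tibble::tibble(sample_id = single$sample_id,
                       plate_id = c("P1", "P1", "P9"))
  expect_warning(out2 <- standardize_by_plate(single, sp), "single")
  expect_true(is.na(out2$ml2rmt[3]))
})

test_that("plate standardization is idempotent", {
  coh <- shared_cohort()
  raw <- compute_ml2rmt(coh$intensities, method = "unweighted_all")
  once <- standardize_by_plate(raw, coh$phenotypes)
  twice <- standardize_by_plate(once, value = "ml2rmt")
  expect_equal(twice$ml2rmt, once$ml2rmt, tolerance = 1e-9)
})

test_that("mL2Rauto summarises autosomal probes and reflects DNA-quantity confounding", {
  base <- tidyr::crossing(sample_id = c("s1", "s2"),
                          probe_id = sprintf("a%d", 1:5)) |>
    dplyr::mutate(panel = "autosomal", l2r = ifelse(sample_id == "s1", 0, 1))
  au <- compute_ml2rauto(base)
  expect_equal(au$ml2rauto_raw, c(0, 1))
  au_mean <- compute_ml2rauto(base, stat = "mean")
  expect_equal(au_mean$ml2rauto_raw, c(0, 1))

  coh <- shared_cohort()  # positive missingness confounding by default
  a <- compute_ml2rauto(coh$intensities)
  cr <- coh$phenotypes$call_rate[match(a$sample_id, coh$phenotypes$sample_id)]
  expect_gt(cor(a$ml2rauto_raw, cr, method = "spearman"), 0)
})
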