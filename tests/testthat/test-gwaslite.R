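test_that("HWE test matches the stated examples and allele-label symmetry", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(50, 0, 50), 1e-5)
  expect_equal(hwe_test(100, 0, 0), 1)  # monomorphic
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  expect_error(hwe_test(1.5, 5, 5), "integers")

  # chi-square variant: exact HWE proportions give statistic 0
  expect_equal(hwe_test(25, 50, 25, method = "chisq"), 1)
  expect_equal(hwe_test(50, 0, 50, method = "chisq"),
               pchisq(100, 1, lower.tail = FALSE))

  set.seed(31)
  for (i in 1:25) {
    tb <- rmultinom(1, sample(10:80, 1), c(0.3, 0.4, 0.3))[, 1]
    expect_equal(hwe_test(tb[1], tb[2], tb[3]),
                 hwe_test(tb[3], tb[2], tb[1]), tolerance = 1e-12)
  }
})

test_that("exact HWE p agrees with the enumeration oracle on random small tables", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    aa <- sample(0:n, 1)
    ab <- sample(0:(n - aa), 1)
    bb <- n - aa - ab
    expect_equal(hwe_test(aa, ab, bb), oracle_hwe_exact(aa, ab, bb),
                 tolerance = 1e-9)
  }
})

test_that("variant filters apply the stated thresholds with a per-filter report", {
  v <- tibble::tibble(
    variant_id = sprintf("v%d", 1:5),
    maf = c(0.04, 0.10, 0.10, 0.10, 0.10),
    missingness = c(0.00, 0.03, 0.00, 0.00, 0.00),
    imputation_r2 = c(0.9, 0.9, 0.5, 0.9, 0.9),
    hwe_p = c(0.5, 0.5, 0.5, 1e-6, 0.5)
  )
  out <- filter_variants(v)
  expect_identical(out$variant_id, "v5")
  rep <- attr(out, "report")
  expect_equal(rep$n_excluded[rep$filter == "maf"], 1L)
  expect_equal(rep$n_excluded[rep$filter == "missingness"], 1L)
  expect_equal(rep$n_excluded[rep$filter == "imputation_r2"], 1L)
  expect_equal(rep$n_excluded[rep$filter == "hwe"], 1L)

  # idempotent and order-invariant
  again <- filter_variants(out)
  expect_equal(again, out, ignore_attr = TRUE)
  shuf <- filter_variants(v[sample(5), ])
  expect_setequal(shuf$variant_id, out$variant_id)

  # absent metric columns are skipped, not fatal
  partial <- filter_variants(v[c("variant_id", "maf")])
  rep2 <- attr(partial, "report")
  expect_false(rep2$applied[rep2$filter == "hwe"])
  expect_equal(nrow(partial), 4)
})

test_that("variant metrics computed from dosages match direct counting", {
  set.seed(33)
  dos <- cbind(a = rbinom(400, 2, 0.3), b = rbinom(400, 2, 0.45))
  dos[sample(400, 20), "a"] <- NA
  rownames(dos) <- sprintf("s%03d", 1:400)
  m <- compute_variant_metrics(dos)
  expect_equal(m$missingness, c(20 / 400, 0))
  af_a <- mean(dos[, "a"], na.rm = TRUE) / 2
  expect_equal(m$maf[1], min(af_a, 1 - af_a))
  cnt <- table(factor(dos[, "b"], levels = 0:2))
  expect_equal(m$hwe_p[2], hwe_test(cnt[[1]], cnt[[2]], cnt[[3]]))
})

test_that("the scan is calibrated under the null and detects a causal variant", {
  # average the inflation factor over a few null replicates so the check
  # measures calibration rather than one draw's Monte-Carlo error
  lambdas <- vapply(1:3, function(s) {
    set.seed(33 + s)
    n <- 1000; m <- 5000
    dos <- matrix(rbinom(n * m, 2, 0.3), n, m,
                  dimnames = list(sprintf("s%04d", 1:n), sprintf("v%04d", 1:m)))
    dat <- tibble::tibble(sample_id = rownames(dos), y = rnorm(n),
                          age = rnorm(n))
    gwas_scan(dat, dos, outcome = "y", covariates = "age")$lambda_gc
  }, numeric(1))
  expect_gt(mean(lambdas), 0.95)
  expect_lt(mean(lambdas), 1.05)

  # inject a causal variant: it should rank first by p
  set.seed(34)
  n <- 1000
  dos <- matrix(rbinom(n * 100, 2, 0.3), n, 100,
                dimnames = list(sprintf("s%04d", 1:n), sprintf("v%04d", 1:100)))
  dat <- tibble::tibble(sample_id = rownames(dos), age = rnorm(n))
  dat$y2 <- rnorm(n) + 0.3 * dos[, 17]
  scan2 <- gwas_scan(dat, dos, outcome = "y2", covariates = "age")
  expect_identical(scan2$results$variant_id[which.min(scan2$results$p)],
                   "v0017")
  expect_equal(glance(scan2)$n_variants, 100)
})

test_that("constant dosages are skipped with a warning", {
  set.seed(35)
  dos <- cbind(ok = rbinom(100, 2, 0.4), flat = rep(1, 100))
  rownames(dos) <- sprintf("s%03d", 1:100)
  dat <- tibble::tibble(sample_id = rownames(dos), y = rnorm(100))
  expect_warning(scan <- gwas_scan(dat, dos, outcome = "y"), "skipped")
  expect_true(is.na(scan$results$p[scan$results$variant_id == "flat"]))
})

test_that("greedy clumping separates loci and counts independent signals", {
  set.seed(36)
  n <- 500
  base <- rbinom(n, 2, 0.4)
  correlated <- ifelse(runif(n) < 0.95, base, rbinom(n, 2, 0.4))
  indep <- rbinom(n, 2, 0.4)
  far <- rbinom(n, 2, 0.4)
  dos <- cbind(lead = base, linked = correlated, free = indep, distant = far)
  rownames(dos) <- sprintf("s%03d", 1:n)
  variants <- tibble::tibble(
    variant_id = c("lead", "linked", "free", "distant"),
    chrom = c(1, 1, 1, 2), pos = c(1e6, 1.2e6, 1.4e6, 1e6)
  )
  res <- tibble::tibble(
    variant_id = variants$variant_id,
    p = c(1e-12, 1e-10, 1e-9, 1e-9)
  )
  out <- clump_signals(res, variants, dos)
  expect_equal(nrow(out), 2)
  l1 <- out[out$lead_variant == "lead", ]
  expect_equal(l1$n_signals, 2L)  # "free" is independent, "linked" is not
  expect_match(l1$signals, "free")
  expect_false(grepl("linked", l1$signals))
  expect_equal(out$n_signals[out$lead_variant == "distant"], 1L)

  # single significant variant: one locus, one signal
  solo <- clump_signals(tibble::tibble(variant_id = "lead", p = 1e-9),
                        variants, dos)
  expect_equal(nrow(solo), 1)
  expect_equal(solo$n_signals, 1L)
})

test_that("clumping matches a brute-force enactment on random instances", {
  set.seed(37)
  for (i in 1:15) {
    m <- sample(3:10, 1)
    n <- 300
    dos <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.5)), n, m)
    # induce some LD by copying columns with noise
    for (j in seq_len(m - 1)) {
      if (runif(1) < 0.4) {
        flip <- runif(n) < 0.1
        dos[, j + 1] <- ifelse(flip, rbinom(n, 2, 0.4), dos[, j])
      }
    }
    colnames(dos) <- sprintf("v%02d", 1:m)
    variants <- tibble::tibble(
      variant_id = colnames(dos),
      chrom = sample(1:2, m, TRUE),
      pos = sample(1:5, m, TRUE) * 4e5
    )
    res <- tibble::tibble(variant_id = colnames(dos),
                          p = 10^-runif(m, 4, 12))
    mine <- clump_signals(res, variants, dos, p_threshold = 1e-5)
    ora <- oracle_clump(res, variants, dos, 1e-5, 0.1, 1e6)
    expect_equal(nrow(mine), length(ora))
    for (k in seq_along(ora)) {
      expect_identical(mine$lead_variant[k], ora[[k]]$lead)
      expect_equal(mine$n_signals[k], ora[[k]]$n_signals)
    }
  }
})
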