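# Allele-count association scan and fixed-effects meta-analysis.

# panel with exact per-group ALT allele counts at each variant
count_panel <- function(case_alt, ctrl_alt, n_case = 100, n_ctrl = 100) {
  cols <- mapply(function(a, c_) {
    c(rep(1L, a), rep(0L, 2 * n_case - a),
      rep(1L, c_), rep(0L, 2 * n_ctrl - c_))
  }, case_alt, ctrl_alt)
  toy_panel(matrix(cols, ncol = length(case_alt)))
}

test_that("the 2x2 scan matches hand arithmetic", {
  panel <- count_panel(30, 20)
  res <- association_scan(panel, cases = 1:100, controls = 101:200)
  expect_equal(res$or, (30 * 180) / (20 * 170), tolerance = 1e-12)
  expect_equal(res$chisq, 400 * (30 * 180 - 20 * 170)^2 /
                 (200 * 200 * 50 * 350), tolerance = 1e-12)
  expect_equal(res$se, sqrt(1 / 30 + 1 / 170 + 1 / 20 + 1 / 180))
  expect_identical(res$effect_allele, "ALT")
})

test_that("identical case and control counts give OR 1, chisq 0, p 1", {
  panel <- count_panel(40, 40)
  res <- association_scan(panel, 1:100, 101:200)
  expect_equal(res$or, 1)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
})

test_that("the MAF filter is strictly exclusive at 1%", {
  # MAF 0.5% (4/400 alleles) excluded; MAF exactly 1% excluded; 1.25% kept
  panel <- count_panel(c(2, 2, 3), c(2, 2, 2))
  res <- association_scan(panel, 1:100, 101:200)
  expect_identical(res$site_index, 3L)
})

test_that("swapping cases and controls inverts the OR, keeps chisq", {
  panel <- count_panel(c(30, 55), c(20, 35))
  a <- association_scan(panel, 1:100, 101:200)
  b <- association_scan(panel, 101:200, 1:100)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
})

test_that("zero cells get the Haldane correction and are flagged", {
  panel <- count_panel(0, 30)
  res <- association_scan(panel, 1:100, 101:200)
  expect_true(res$zero_cell)
  expect_equal(res$or, (0.5 * 170.5) / (200.5 * 30.5))
  expect_true(is.finite(res$se))
  # test statistic itself uses the uncorrected table
  expect_equal(res$chisq, 400 * (0 * 170 - 200 * 30)^2 /
                 (200 * 200 * 30 * 370))
})

test_that("disjointness and emptiness are enforced", {
  panel <- count_panel(30, 20)
  expect_error(association_scan(panel, 1:100, 50:150), "disjoint")
  expect_error(association_scan(panel, integer(0), 1:10))
})

test_that("null calibration: type-I error close to 0.05", {
  # labels assigned independently of genotypes -> every variant is null
  panel <- random_panel(600, 12000, seed = 42)
  set.seed(99)
  idx <- sample(600)
  res <- association_scan(panel, idx[1:300], idx[301:600],
                          maf_threshold = 0.01)
  expect_gte(nrow(res), 10000)
  rate <- mean(res$p < 0.05)
  # binomial tolerance: 4 * sqrt(.05*.95/n)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("median chi-square grows with case count at a causal variant", {
  set.seed(7)
  stat_at <- function(n) {
    replicate(40, {
      f_case <- 0.35
      f_ctrl <- 0.25
      hap <- cbind(c(rbinom(2 * n, 1, f_case), rbinom(2 * n, 1, f_ctrl)))
      panel <- toy_panel(hap)
      association_scan(panel, 1:n, (n + 1):(2 * n))$chisq
    })
  }
  expect_gt(median(stat_at(400)), median(stat_at(100)))
})

test_that("meta-analysis matches equal-weight arithmetic", {
  a <- fake_assoc(log(2), 0.2)
  b <- fake_assoc(0, 0.2, population = "AFR")
  m <- meta_analyze(a, b)
  expect_equal(m$log_or, (log(2) + 0) / 2, tolerance = 1e-4)
  expect_equal(m$se, 0.2 / sqrt(2), tolerance = 1e-12)
})

test_that("two identical studies: same effect, smaller SE, no heterogeneity", {
  a <- fake_assoc(c(0.4, -0.2), c(0.1, 0.15))
  b <- fake_assoc(c(0.4, -0.2), c(0.1, 0.15), population = "AFR")
  m <- meta_analyze(a, b)
  expect_equal(m$log_or, c(0.4, -0.2))
  expect_equal(m$se, c(0.1, 0.15) / sqrt(2))
  expect_equal(m$q, c(0, 0))
  expect_equal(m$i2, c(0, 0))
  expect_false(any(m$heterogeneous))
})

test_that("meta effect lies between the study effects; unshared dropped", {
  a <- fake_assoc(c(0.6, 0.1), c(0.3, 0.1), pos = c(1000L, 2000L))
  b <- fake_assoc(c(0.1, 0.5, 0.2), c(0.1, 0.2, 0.1),
                  pos = c(1000L, 2000L, 3000L), population = "AFR")
  b$site_index <- 1:3
  m <- meta_analyze(a, b)
  expect_identical(nrow(m), 2L)
  expect_identical(attr(m, "n_dropped_unshared"), 1L)
  expect_true(all(m$log_or >= pmin(a$log_or, b$log_or[1:2]) &
                  m$log_or <= pmax(a$log_or, b$log_or[1:2])))
})

test_that("meta-analysis agrees with metafor", {
  skip_if_not_installed("metafor")
  a <- fake_assoc(c(0.35, -0.1, 0.8), c(0.12, 0.4, 0.21))
  b <- fake_assoc(c(0.15, 0.3, 0.5), c(0.2, 0.17, 0.33),
                  population = "AFR")
  m <- meta_analyze(a, b)
  for (i in 1:3) {
    rma <- metafor::rma(yi = c(a$log_or[i], b$log_or[i]),
                        sei = c(a$se[i], b$se[i]), method = "FE")
    expect_equal(m$log_or[i], as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(m$se[i], rma$se, tolerance = 1e-10)
    expect_equal(unname(m$q[i]), rma$QE, tolerance = 1e-10)
  }
})

test_that("heterogeneity flag follows the I2 > 25% and Q p < 0.05 rule", {
  a <- fake_assoc(1.5, 0.1)
  b <- fake_assoc(-1.5, 0.1, population = "AFR")
  m <- meta_analyze(a, b)
  expect_gt(m$i2, 25)
  expect_lt(m$q_p, 0.05)
  expect_true(m$heterogeneous)
})
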