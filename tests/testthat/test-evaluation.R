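# Accuracy aggregation, ancestry stratification, tagging and MAF
# diagnostics.

test_that("Fisher-z aggregation matches closed-form arithmetic", {
  s <- accuracy_summary(c(0.5, 0.6))
  expect_equal(s$mean_r, tanh((atanh(0.5) + atanh(0.6)) / 2),
               tolerance = 1e-12)
  expect_equal(s$mean_r, 0.5521, tolerance = 3e-4)
  expect_true(s$ci_lower <= s$mean_r && s$mean_r <= s$ci_upper)

  same <- accuracy_summary(rep(0.42, 8))
  expect_equal(same$mean_r, 0.42, tolerance = 1e-12)
  expect_equal(same$ci_lower, same$ci_upper)

  expect_warning(one <- accuracy_summary(1), "clipped")
  expect_lt(one$mean_r, 1)
})

test_that("Fisher transform round-trips", {
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)
})

test_that("accuracy Z-test matches the closed form and is monotone in n", {
  z0 <- compare_accuracies(0.5, 100, 0.5, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  cmp <- compare_accuracies(0.77, 5000, 0.45, 5000)
  manual <- (atanh(0.77) - atanh(0.45)) / sqrt(2 / (5000 - 3))
  expect_equal(cmp$z, manual, tolerance = 1e-12)
  expect_gt(cmp$z, 26)
  expect_lt(cmp$z, 27.5)

  p_small <- compare_accuracies(0.6, 50, 0.5, 50)$p
  p_big <- compare_accuracies(0.6, 500, 0.5, 500)$p
  expect_lt(p_big, p_small)
  expect_error(compare_accuracies(0.5, 3, 0.5, 100), "exceed 3")

  many <- compare_accuracies(c(0.6, 0.62, 0.58), 200, c(0.5, 0.5, 0.5), 200)
  expect_equal(many$median_p, median(many$p))
})

test_that("ancestry strata follow the published bounds, edges downward", {
  s <- stratify_by_ancestry(c(0.9, 0.5, 0.8, 0.2, 0.05, 1, 0))
  expect_equal(as.character(s$stratum),
               c("high", "intermediate", "intermediate", "low", "low",
                 NA, NA))
  expect_error(stratify_by_ancestry(1.2), "\\[0, 1\\]")
  expect_identical(stratify_by_ancestry(c(0, 0.1, 0.11, 1))$decile,
                   c(1L, 1L, 2L, 10L))
})

test_that("ancestry-accuracy slope matches hand OLS", {
  expect_equal(ancestry_accuracy_slope(rep(0.2, 10))$slope_per_10pct, 0,
               tolerance = 1e-12)
  lin <- (seq(0.05, 0.95, 0.1) * 1.34 / 0.1 + 3) / 100
  expect_equal(ancestry_accuracy_slope(lin)$slope_per_10pct, 1.34,
               tolerance = 1e-9)

  y <- c(1, 2, 4, 3, 5, 6, 8, 7, 9, 10) / 100
  x <- seq(0.05, 0.95, 0.1) / 0.1
  slope_hand <- sum((x - mean(x)) * (100 * y - mean(100 * y))) /
    sum((x - mean(x))^2)
  expect_equal(ancestry_accuracy_slope(y)$slope_per_10pct, slope_hand,
               tolerance = 1e-12)

  expect_error(ancestry_accuracy_slope(c(0.1, 0.2, rep(NA, 8))),
               "fewer than 3")
})

test_that("a PRS identical to the causal set tags every causal variant", {
  s <- small_sim()
  panel <- s$pops$eur
  arch <- build_architecture(panel$positions, m = 20, h2 = 0.5, seed = 5)
  dos <- genotype_dosage(panel, sites = arch$causal_indices)
  poly <- arch$causal_indices[apply(dos, 2, var) > 0]
  arch <- make_arch(poly, rep(0.1, length(poly)))
  model <- admixprs:::new_prs_model(
    data.frame(variant_id = sprintf("v%d", panel$positions[poly]),
               pos = panel$positions[poly], site_index = poly,
               effect_allele = "ALT", weight = 0.1, p = 1e-5),
    "EUR", list())
  rep_ <- causal_tagging_summary(arch, list(self = model),
                                 list(EUR = panel, AFR = s$pops$afr))
  cts <- rep_$counts[rep_$counts$panel == "EUR", ]
  expect_identical(cts$n_exact_causal, length(poly))
  expect_identical(cts$`tag_r2_gt_0.8`, length(poly))
  sc <- rep_$ld_scores
  expect_true(all(sc$ld_score_eur >= 1 - 1e-9))
  expect_equal(sc$ld_score_norm_eur, sc$ld_score_eur / length(poly))
})

test_that("tagging counts are monotone across thresholds", {
  s <- small_sim()
  panel <- s$pops$eur
  arch <- build_architecture(panel$positions, m = 100, h2 = 0.5, seed = 6)
  sites <- seq(5, length(panel$positions), by = 97)[1:40]
  model <- admixprs:::new_prs_model(
    data.frame(variant_id = sprintf("v%d", panel$positions[sites]),
               pos = panel$positions[sites], site_index = sites,
               effect_allele = "ALT", weight = 0.1, p = 1e-4),
    "EUR", list())
  rep_ <- causal_tagging_summary(arch, list(m1 = model),
                                 list(EUR = panel, AFR = s$pops$afr))
  for (pn in c("EUR", "AFR")) {
    cts <- rep_$counts[rep_$counts$panel == pn, ]
    expect_true(cts$`tag_r2_gt_0.8` <= cts$`tag_r2_gt_0.6`)
    expect_true(cts$`tag_r2_gt_0.6` <= cts$`tag_r2_gt_0.4`)
    expect_true(cts$`tag_r2_gt_0.4` <= cts$`tag_r2_gt_0.2`)
    expect_true(cts$n_exact_causal <= cts$`tag_r2_gt_0.2`)
  }
  expect_true(is.finite(rep_$ld_score_correlation["m1"]) ||
              is.na(rep_$ld_score_correlation["m1"]))
})

test_that("tagging window excludes distant causal variants", {
  # PRS variant perfectly correlated with a causal variant outside the
  # window contributes nothing
  hap <- cbind(rep(c(0L, 1L), 20), rep(c(0L, 1L), 20))
  panel <- haplotype_panel(c(1000L, 5000000L), hap, "EUR")
  arch <- make_arch(1, 0.2)
  model <- admixprs:::new_prs_model(
    data.frame(variant_id = "far", pos = 5000000L, site_index = 2L,
               effect_allele = "ALT", weight = 1, p = 1e-8),
    "EUR", list())
  rep_ <- causal_tagging_summary(arch, list(m = model),
                                 list(EUR = panel), window_bp = 1e6)
  expect_identical(rep_$counts$`tag_r2_gt_0.2`, 0L)
  expect_equal(rep_$ld_scores$ld_score_eur, 0)
})

test_that("MAF spectrum table counts selected variants per bin", {
  # two selected variants; one has AFR MAF 0.004 -> AFR <1% fraction 0.5
  n <- 500
  hap_eur <- cbind(rbinom(2 * n, 1, 0.3), rbinom(2 * n, 1, 0.25))
  hap_afr <- cbind(rbinom(2 * n, 1, 0.3), c(rep(1L, 4), rep(0L, 2 * n - 4)))
  eur <- haplotype_panel(c(1000L, 2000L), hap_eur, "EUR")
  afr <- haplotype_panel(c(1000L, 2000L), hap_afr, "AFR")
  model <- admixprs:::new_prs_model(
    data.frame(variant_id = c("a", "b"), pos = c(1000L, 2000L),
               site_index = 1:2, effect_allele = "ALT",
               weight = c(0.1, 0.2), p = 1e-3),
    "EUR", list())
  tab <- maf_spectrum_table(list(EUR = model),
                            list(EUR = eur, AFR = afr))
  afr_rare <- tab[tab$panel == "AFR" & tab$bin == "[0,0.01)", ]
  expect_equal(afr_rare$fraction, 0.5)
  eur_rare <- tab[tab$panel == "EUR" & tab$bin == "[0,0.01)", ]
  expect_equal(eur_rare$fraction, 0)
  expect_true(all(abs(tapply(tab$fraction, tab$panel, sum) - 1) < 1e-12))
  expect_error(maf_spectrum_table(list(EUR = model), list(EUR = eur),
                                  bins = c(0.1, 0.5)))
})

test_that("accuracy of a PRS against itself is 1; permutation is null", {
  set.seed(31)
  g <- rnorm(300)
  expect_equal(prs_accuracy(g, g), 1)
  perm <- replicate(200, cor(g, sample(g)))
  expect_lt(abs(mean(perm)), 0.02)
  expect_error(prs_accuracy(g, rep(1, 300)), "constant")
})
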