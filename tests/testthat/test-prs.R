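# PRS construction: LD, clumping vs oracle, scoring, local-ancestry
# weighting, mixture fit.

test_that("ld_r2 matches hand Pearson arithmetic", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)), 9 / 11)
  expect_error(ld_r2(c(1, 1, 1, 1), c(0, 1, 1, 0)), "zero-variance")
})

test_that("greedy clumping matches the exhaustive oracle on small panels", {
  for (seed in 1:6) {
    panel <- random_panel(120, 40, seed = seed)
    set.seed(seed + 100)
    labels <- sample(120)
    assoc <- association_scan(panel, labels[1:60], labels[61:120],
                              maf_threshold = 0.01)
    for (p_thr in c(0.5, 0.2)) {
      model <- clump_and_threshold(assoc, panel, p_thr,
                                   r2_threshold = 0.2, window_bp = 20000)
      expect_identical(model$variants$site_index,
                       clump_oracle(assoc, panel, p_thr, 0.2, 20000))
    }
  }
})

test_that("selected variants respect p threshold and pairwise LD bound", {
  s <- small_sim()
  panel <- s$pops$eur
  arch <- build_architecture(panel$positions, m = 50, h2 = 0.8, seed = 2)
  liab <- compute_liability(panel, arch, seed = 3)
  des <- study_design(prevalence = 0.05, n_cases = 15, n_controls = 15,
                      n_test_per_pop = 0)
  asc <- ascertain_samples(liab, des, seed = 4)
  assoc <- association_scan(panel, asc$cases, asc$controls)
  ref <- subset_panel(panel, c(asc$cases, asc$controls))
  model <- clump_and_threshold(assoc, ref, 0.05)
  v <- model$variants
  expect_true(all(v$p < 0.05))
  if (nrow(v) > 1) {
    dos <- genotype_dosage(ref, sites = v$site_index)
    for (i in seq_len(nrow(v) - 1)) {
      for (j in (i + 1):nrow(v)) {
        if (abs(v$pos[i] - v$pos[j]) <= 1e6)
          expect_lt(cor(dos[, i], dos[, j])^2, 0.2)
      }
    }
  }
})

test_that("an empty association set yields an empty model, not an error", {
  panel <- random_panel(50, 10, seed = 3)
  set.seed(1)
  lab <- sample(50)
  assoc <- association_scan(panel, lab[1:25], lab[26:50])
  expect_message(model <- clump_and_threshold(assoc, panel, 1e-30),
                 "empty model")
  expect_identical(nrow(model$variants), 0L)
  s <- score_prs(panel, model)
  expect_true(all(s == 0))
})

test_that("scoring is the weighted effect-allele dosage sum", {
  panel <- toy_panel(rbind(0L, 0L, 1L, 0L, 1L, 1L)) # dosages 0,1,2
  model <- admixprs:::new_prs_model(
    data.frame(variant_id = "v1000", pos = 1000L, site_index = 1L,
               effect_allele = "ALT", weight = log(2), p = 1e-4),
    "EUR", list())
  expect_equal(unname(score_prs(panel, model)),
               c(0, log(2), 2 * log(2)), ignore_attr = TRUE)

  flipped <- model
  flipped$variants$effect_allele <- "REF"
  expect_equal(unname(score_prs(panel, flipped)),
               log(2) * (2 - c(0, 1, 2)), ignore_attr = TRUE)

  zero <- model
  zero$variants$weight <- 0
  expect_true(all(score_prs(panel, zero) == 0))

  bad <- model
  bad$variants$effect_allele <- "G"
  expect_error(score_prs(panel, bad), "neither REF nor ALT")
})

test_that("scoring is linear and reports missing variants", {
  panel <- random_panel(30, 8, seed = 5)
  w1 <- admixprs:::new_prs_model(
    data.frame(variant_id = "a", pos = panel$positions[2],
               site_index = 2L, effect_allele = "ALT", weight = 0.4,
               p = 0.001), "EUR", list())
  w2 <- admixprs:::new_prs_model(
    data.frame(variant_id = "b", pos = panel$positions[5],
               site_index = 5L, effect_allele = "ALT", weight = -0.7,
               p = 0.001), "EUR", list())
  both <- admixprs:::new_prs_model(rbind(w1$variants, w2$variants),
                                   "EUR", list())
  expect_equal(score_prs(panel, both),
               score_prs(panel, w1) + score_prs(panel, w2),
               ignore_attr = TRUE)

  missing <- admixprs:::new_prs_model(
    data.frame(variant_id = "x", pos = 999999L, site_index = 99L,
               effect_allele = "ALT", weight = 5, p = 0.001),
    "EUR", list())
  s <- score_prs(panel, missing)
  expect_true(all(s == 0))
  expect_true(all(attr(s, "n_missing") == 1L))
})

test_that("local-ancestry scoring degenerates to single-population scores", {
  s <- small_sim()
  cfg <- s$cfg
  cfg$n_admixed <- 10L
  adm1 <- simulate_admixture(s$pops$founders_eur, s$pops$founders_afr,
                             cfg, theta = 1) # all EUR
  adm0 <- simulate_admixture(s$pops$founders_eur, s$pops$founders_afr,
                             cfg, theta = 0) # all AFR
  sites <- seq(1, length(s$pops$eur$positions), by = 400)
  mv <- data.frame(variant_id = sprintf("v%d", sites),
                   pos = s$pops$eur$positions[sites],
                   site_index = sites,
                   effect_allele = rep(c("ALT", "REF"),
                                       length.out = length(sites)),
                   weight = NA, p = NA)
  set.seed(3)
  w_eur <- rnorm(nrow(mv)); w_afr <- rnorm(nrow(mv))
  me <- admixprs:::new_prs_model(transform(mv, weight = w_eur), "EUR", list())
  ma <- admixprs:::new_prs_model(transform(mv, weight = w_afr), "AFR", list())
  expect_equal(
    score_local_ancestry_prs(adm1$panel, adm1$tracts, mv, w_eur, w_afr),
    score_prs(adm1$panel, me), ignore_attr = TRUE)
  expect_equal(
    score_local_ancestry_prs(adm0$panel, adm0$tracts, mv, w_eur, w_afr),
    score_prs(adm0$panel, ma), ignore_attr = TRUE)
})

test_that("heterozygous-ancestry site follows the published equation", {
  # one variant; effect allele carried on the EUR-ancestry haplotype;
  # rho = 0.5: PRS = 0.5 * (0.2 * 1) + 0.5 * (0.1 * 0) = 0.10
  L <- 1e6
  panel <- haplotype_panel(500000L, matrix(c(1L, 0L), nrow = 2), "ADMIXED",
                           "adm_1")
  tracts <- ancestry_tracts(data.frame(
    haplotype_id = c("adm_1_h1", "adm_1_h2"), individual_id = "adm_1",
    start = 0, end = L, ancestry = c("EUR", "AFR")), L)
  mv <- data.frame(pos = 500000L, effect_allele = "ALT")
  expect_equal(unname(score_local_ancestry_prs(panel, tracts, mv,
                                               0.2, 0.1)), 0.10)
})

test_that("mixture weights are recovered by least squares", {
  set.seed(11)
  prs_e <- rnorm(400)
  prs_a <- 0.3 * prs_e + rnorm(400) # correlated, like real PRS pairs

  w <- fit_mixture_prs(prs_e, prs_a, prs_e)
  expect_equal(w$alpha1, 1, tolerance = 1e-10)
  expect_equal(w$alpha2, 0, tolerance = 1e-10)
  expect_equal(w$intercept, 0, tolerance = 1e-10)

  target <- 0.3 * prs_e + 0.7 * prs_a + rnorm(400, 0, 1e-3)
  w <- fit_mixture_prs(prs_e, prs_a, target)
  expect_lt(abs(w$alpha1 - 0.3), 1e-2)
  expect_lt(abs(w$alpha2 - 0.7), 1e-2)
  expect_equal(predict_mixture(w, 0, 0), w$intercept)

  expect_error(fit_mixture_prs(prs_e, 2 * prs_e + 1, target), "collinear")
})

test_that("cross-validated mixture fit supports stratification", {
  set.seed(21)
  prs_e <- rnorm(300)
  prs_a <- rnorm(300)
  y_bin <- rbinom(300, 1, plogis(prs_e + prs_a))
  w <- fit_mixture_prs(prs_e, prs_a, y_bin, k = 5, stratified = TRUE,
                       seed = 2)
  expect_identical(w$folds, 5L)
  expect_true(is.finite(w$alpha1) && is.finite(w$alpha2))
  w2 <- fit_mixture_prs(prs_e, prs_a, y_bin, k = 5, stratified = TRUE,
                        seed = 2)
  expect_equal(w, w2)
})
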