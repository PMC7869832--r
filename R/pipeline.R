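# End-to-end replicate orchestration and aggregation.

#' Build an experiment configuration
#'
#' Defaults reproduce the full-scale study design: 63 Mb region, 200,000
#' diploids per source population, m = 1,000 causal variants, h2 = 0.5,
#' 10,000 cases and 10,000 controls per GWAS, 5,000 test samples per
#' population, all 5,000 admixed individuals as test, PRS selection at
#' p < 0.01 with r2 < 0.2 clumping in a 1 Mb window, African-GWAS
#' down-sampling fractions {0.01, 0.05, 0.1, 0.5, 1}, and 50 replicates.
#' Desk-scale runs override the sizes.
#'
#' @param sim a [sim_config()].
#' @param design a [study_design()].
#' @param m,h2 causal-architecture parameters (study grid: m in
#'   {200, 500, 1000}, h2 in {0.33, 0.50, 0.67}).
#' @param p_thresholds PRS p-value threshold grid; the first entry is the
#'   primary threshold used for the strategy comparison.
#' @param r2_threshold,window_bp clumping parameters.
#' @param afr_downsample_fractions fractions of the African GWAS cases
#'   and controls to retain (1 = full size); each fraction re-runs the
#'   African GWAS, the meta-analysis, clumping, and the mixture fit.
#' @param n_replicates number of independent replicates.
#' @param master_seed master seed; replicate seeds derive from it via
#'   [derive_seed()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              design = study_design(),
                              m = 1000, h2 = 0.5,
                              p_thresholds = c(0.01, 1e-4, 1e-6),
                              r2_threshold = 0.2,
                              window_bp = 1e6,
                              afr_downsample_fractions = c(0.01, 0.05, 0.1, 0.5, 1),
                              n_replicates = 50,
                              master_seed = 1) {
  stopifnot(inherits(sim, "sim_config"), inherits(design, "study_design"),
            length(p_thresholds) >= 1, all(p_thresholds > 0),
            all(afr_downsample_fractions > 0),
            all(afr_downsample_fractions <= 1),
            1 %in% afr_downsample_fractions,
            n_replicates >= 1)
  structure(list(sim = sim, design = design, m = as.integer(m), h2 = h2,
                 p_thresholds = p_thresholds, r2_threshold = r2_threshold,
                 window_bp = window_bp,
                 afr_downsample_fractions = sort(afr_downsample_fractions),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

strategy_grid <- function() {
  expand.grid(variant_source = c("EUR", "AFR", "META"),
              weight_source = c("EUR", "AFR", "META", "LOCAL"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run one end-to-end replicate
#'
#' Executes simulate -> phenotype -> ascertain -> GWAS (EUR; AFR at each
#' down-sampling fraction; fixed-effects meta) -> clumping/thresholding ->
#' scoring of the twelve variant-source x weight-source strategies on the
#' three test cohorts -> mixture fit -> evaluation. The replicate seed is
#' derived deterministically from `(master_seed, replicate_id)`.
#'
#' @param config an [experiment_config()].
#' @param replicate_id integer replicate identifier.
#' @param keep_genotypes keep the simulated panels in the result (large;
#'   default FALSE).
#' @return An object of class `replicate_result`: list with `accuracy`
#'   (data.frame: strategy, cohort/stratum, fraction, r, r2_liability,
#'   n), `model_sizes`, `tagging`, `maf_table`, `slopes`, `mixture`,
#'   `seed`, `replicate_id`.
#' @export
run_replicate <- function(config, replicate_id = 1, keep_genotypes = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- derive_seed(config$master_seed, replicate_id)
  scfg <- config$sim
  scfg$seed <- seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("replicate %d failed at stage '%s': %s",
                   replicate_id, name, conditionMessage(e)), call. = FALSE))
  }

  pops <- stage("simulate_sources", simulate_source_populations(scfg))
  adm <- stage("simulate_admixture",
               simulate_admixture(pops$founders_eur, pops$founders_afr, scfg))
  rho <- compute_global_ancestry(adm$tracts)

  arch <- stage("architecture",
                build_architecture(pops$eur$positions, config$m, config$h2,
                                   seed = derive_seed(seed, 11L)))
  liab <- stage("liability", list(
    eur = compute_liability(pops$eur, arch, seed = derive_seed(seed, 21L)),
    afr = compute_liability(pops$afr, arch, seed = derive_seed(seed, 22L)),
    adm = compute_liability(adm$panel, arch, seed = derive_seed(seed, 23L))))

  asc <- stage("ascertain", list(
    eur = ascertain_samples(liab$eur, config$design,
                            seed = derive_seed(seed, 31L)),
    afr = ascertain_samples(liab$afr, config$design,
                            seed = derive_seed(seed, 32L))))

  ref_eur <- subset_panel(pops$eur, c(asc$eur$cases, asc$eur$controls))
  assoc_eur <- stage("gwas_eur",
                     association_scan(pops$eur, asc$eur$cases, asc$eur$controls))

  test_panels <- list(
    EUR = subset_panel(pops$eur, asc$eur$test),
    AFR = subset_panel(pops$afr, asc$afr$test),
    ADMIXED = adm$panel)
  true_g <- list(EUR = liab$eur$G[asc$eur$test],
                 AFR = liab$afr$G[asc$afr$test],
                 ADMIXED = liab$adm$G)
  liab_test <- list(EUR = liab$eur$liability[asc$eur$test],
                    AFR = liab$afr$liability[asc$afr$test],
                    ADMIXED = liab$adm$liability)
  strat <- stratify_by_ancestry(rho)

  p_main <- config$p_thresholds[1]
  grid <- strategy_grid()
  acc_rows <- list()
  model_sizes <- list()
  mixture_rows <- list()
  slope_rows <- list()
  tagging <- NULL
  maf_table <- NULL

  for (frac in config$afr_downsample_fractions) {
    # a down-sampled African GWAS is a smaller GWAS: re-ascertain the
    # subset, re-estimate ORs, re-run the meta-analysis and re-clump
    n_c <- max(1L, floor(frac * config$design$n_cases))
    sub <- with_seed(derive_seed(seed, 41L + round(1000 * frac)), list(
      cases = sort(sample(asc$afr$cases, n_c)),
      controls = sort(sample(asc$afr$controls, n_c))))
    assoc_afr <- stage("gwas_afr",
                       association_scan(pops$afr, sub$cases, sub$controls))
    assoc_meta <- stage("meta", meta_analyze(assoc_eur, assoc_afr))

    ref_afr <- subset_panel(pops$afr, c(sub$cases, sub$controls))
    ref_meta <- combine_panels(ref_eur, ref_afr)
    assocs <- list(EUR = assoc_eur, AFR = assoc_afr, META = assoc_meta)
    refs <- list(EUR = ref_eur, AFR = ref_afr, META = ref_meta)

    models <- stage("clump", lapply(c(EUR = "EUR", AFR = "AFR", META = "META"),
      function(s) clump_and_threshold(assocs[[s]], refs[[s]], p_main,
                                      config$r2_threshold, config$window_bp)))
    for (s in names(models))
      model_sizes[[paste(s, frac)]] <- data.frame(
        variant_source = s, fraction = frac,
        n_variants = nrow(models[[s]]$variants))

    # twelve strategies: weights from each GWAS, plus local-ancestry
    for (gi in seq_len(nrow(grid))) {
      vs <- grid$variant_source[gi]
      ws <- grid$weight_source[gi]
      model <- models[[vs]]
      strat_name <- sprintf("%s.%s", tolower(vs), tolower(ws))
      if (nrow(model$variants) == 0) {
        acc_rows[[paste(strat_name, frac, "skip")]] <- data.frame(
          strategy = strat_name, cohort = NA_character_, fraction = frac,
          r = NA_real_, r2_liability = NA_real_, n = 0L,
          status = "skipped_empty_model")
        next
      }
      if (ws == "LOCAL") {
        wts <- lapply(list(assocs$EUR, assocs$AFR), function(a) {
          rw <- reweight_model(model, a)
          rw$variants$weight
        })
        scores <- list(ADMIXED = score_local_ancestry_prs(
          adm$panel, adm$tracts, model$variants, wts[[1]], wts[[2]]))
      } else {
        scored_model <- if (ws == vs) model else reweight_model(model, assocs[[ws]])
        scores <- lapply(test_panels, score_prs, model = scored_model)
      }
      for (cohort in names(scores)) {
        sc <- scores[[cohort]]
        cohorts <- if (cohort == "ADMIXED")
          c("ADMIXED", levels(strat$stratum)) else cohort
        for (ch in cohorts) {
          sel <- if (ch %in% levels(strat$stratum))
            which(strat$stratum == ch) else seq_along(sc)
          if (length(sel) < 4 || stats::sd(sc[sel]) == 0) next
          acc_rows[[paste(strat_name, frac, ch)]] <- data.frame(
            strategy = strat_name, cohort = ch, fraction = frac,
            r = stats::cor(true_g[[cohort]][sel], sc[sel]),
            r2_liability = stats::cor(liab_test[[cohort]][sel], sc[sel])^2,
            n = length(sel), status = "ok")
        }
        if (cohort == "ADMIXED") {
          d10 <- decile_r2(sc, liab_test$ADMIXED, rho)
          sl <- tryCatch(ancestry_accuracy_slope(d10)$slope_per_10pct,
                         error = function(e) NA_real_)
          slope_rows[[paste(strat_name, frac)]] <- data.frame(
            strategy = strat_name, fraction = frac, slope_per_10pct = sl)
        }
      }
    }

    # two-PRS linear mixture, fitted in the independent AFR test cohort
    if (nrow(models$EUR$variants) > 0 && nrow(models$AFR$variants) > 0) {
      fit_eur <- score_prs(test_panels$AFR, models$EUR)
      fit_afr <- score_prs(test_panels$AFR, models$AFR)
      mw <- tryCatch(
        fit_mixture_prs(fit_eur, fit_afr, liab_test$AFR),
        error = function(e) NULL)
      if (!is.null(mw)) {
        adm_eur <- score_prs(adm$panel, models$EUR)
        adm_afr <- score_prs(adm$panel, models$AFR)
        mix <- predict_mixture(mw, adm_eur, adm_afr)
        for (ch in c("ADMIXED", levels(strat$stratum))) {
          sel <- if (ch == "ADMIXED") seq_along(mix)
          else which(strat$stratum == ch)
          if (length(sel) < 4 || stats::sd(mix[sel]) == 0) next
          acc_rows[[paste("mixture", frac, ch)]] <- data.frame(
            strategy = "mixture", cohort = ch, fraction = frac,
            r = stats::cor(true_g$ADMIXED[sel], mix[sel]),
            r2_liability = stats::cor(liab_test$ADMIXED[sel], mix[sel])^2,
            n = length(sel), status = "ok")
        }
        d10 <- decile_r2(mix, liab_test$ADMIXED, rho)
        sl <- tryCatch(ancestry_accuracy_slope(d10)$slope_per_10pct,
                       error = function(e) NA_real_)
        slope_rows[[paste("mixture", frac)]] <- data.frame(
          strategy = "mixture", fraction = frac, slope_per_10pct = sl)
        mixture_rows[[as.character(frac)]] <- data.frame(
          fraction = frac, alpha1 = mw$alpha1, alpha2 = mw$alpha2,
          intercept = mw$intercept)
      }
    }

    if (frac == 1) {
      tagging <- stage("tagging", causal_tagging_summary(
        arch, models, list(EUR = ref_eur, AFR = ref_afr),
        window_bp = config$window_bp))
      maf_table <- stage("maf_table", maf_spectrum_table(
        models, list(EUR = pops$eur, AFR = pops$afr, ADMIXED = adm$panel)))
    }
  }

  out <- list(replicate_id = as.integer(replicate_id), seed = seed,
              accuracy = do.call(rbind, c(acc_rows, make.row.names = FALSE)),
              model_sizes = do.call(rbind, c(model_sizes,
                                             make.row.names = FALSE)),
              slopes = do.call(rbind, c(slope_rows, make.row.names = FALSE)),
              mixture = do.call(rbind, c(mixture_rows,
                                         make.row.names = FALSE)),
              tagging = tagging, maf_table = maf_table,
              rho = rho,
              causal_maf = data.frame(
                eur = panel_maf(pops$eur, sites = arch$causal_indices),
                afr = panel_maf(pops$afr, sites = arch$causal_indices)))
  if (keep_genotypes) out$panels <- c(pops, list(admixed = adm$panel))
  structure(out, class = "replicate_result")
}

#' Aggregate replicate results into experiment-level tables
#'
#' Variant counts per strategy as mean and (min-max) range; accuracies
#' per strategy x cohort aggregated with the Fisher z-transformation and
#' 95% CI; mean ancestry slopes; mean MAF-bin fractions.
#'
#' @param results list of `replicate_result`s (consistent configurations).
#' @return list of data.frames: `model_sizes`, `accuracy`, `slopes`,
#'   `maf_table`.
#' @export
aggregate_replicates <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "replicate_result")))
  ids <- vapply(results, `[[`, integer(1), "replicate_id")
  results <- results[order(ids)] # aggregates are order-invariant

  sizes <- do.call(rbind, lapply(results, `[[`, "model_sizes"))
  agg_sizes <- do.call(rbind, lapply(
    split(sizes, list(sizes$variant_source, sizes$fraction), drop = TRUE),
    function(d) data.frame(
      variant_source = d$variant_source[1], fraction = d$fraction[1],
      mean_n = mean(d$n_variants), min_n = min(d$n_variants),
      max_n = max(d$n_variants))))

  acc <- do.call(rbind, lapply(seq_along(results), function(i) {
    a <- results[[i]]$accuracy
    a$replicate <- results[[i]]$replicate_id
    a
  }))
  acc_ok <- acc[acc$status == "ok" & !is.na(acc$r), ]
  agg_acc <- do.call(rbind, lapply(
    split(acc_ok, list(acc_ok$strategy, acc_ok$cohort, acc_ok$fraction),
          drop = TRUE),
    function(d) {
      s <- accuracy_summary(d$r)
      data.frame(strategy = d$strategy[1], cohort = d$cohort[1],
                 fraction = d$fraction[1], mean_r = s$mean_r,
                 ci_lower = s$ci_lower, ci_upper = s$ci_upper,
                 mean_r2_liability = mean(d$r2_liability),
                 n_replicates = nrow(d))
    }))

  slopes <- do.call(rbind, lapply(results, `[[`, "slopes"))
  agg_slopes <- do.call(rbind, lapply(
    split(slopes, list(slopes$strategy, slopes$fraction), drop = TRUE),
    function(d) data.frame(
      strategy = d$strategy[1], fraction = d$fraction[1],
      mean_slope_per_10pct = mean(d$slope_per_10pct, na.rm = TRUE),
      n_replicates = sum(!is.na(d$slope_per_10pct)))))

  mafs <- do.call(rbind, lapply(results, `[[`, "maf_table"))
  agg_maf <- NULL
  if (!is.null(mafs))
    agg_maf <- do.call(rbind, lapply(
      split(mafs, list(mafs$model, mafs$panel, mafs$bin), drop = TRUE),
      function(d) data.frame(model = d$model[1], panel = d$panel[1],
                             bin = d$bin[1],
                             mean_fraction = mean(d$fraction))))

  lapply(list(model_sizes = agg_sizes, accuracy = agg_acc,
              slopes = agg_slopes, maf_table = agg_maf),
         function(d) { if (!is.null(d)) rownames(d) <- NULL; d })
}
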