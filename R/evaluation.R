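# Accuracy metrics, ancestry stratification, and LD/allele-frequency
# diagnostics for the PRS strategies.

#' PRS accuracy: Pearson correlation with the true genetic liability
#'
#' @param true_g true genetic liability vector.
#' @param prs aligned PRS vector.
#' @return Pearson r.
#' @export
prs_accuracy <- function(true_g, prs) {
  stopifnot(length(true_g) == length(prs), length(prs) >= 3)
  if (stats::sd(prs) == 0)
    stop("constant PRS vector: accuracy is undefined")
  stats::cor(true_g, prs)
}

#' Aggregate per-replicate accuracies via the Fisher z-transformation
#'
#' Transforms each replicate correlation with `z = atanh(r)`, averages,
#' attaches the normal-theory 95% CI of the mean z across replicates,
#' and back-transforms with `tanh`. Correlations at exactly +/-1 are
#' clipped to +/-(1 - 1e-12) with a warning (atanh singularity; arises
#' only in degenerate inputs).
#'
#' @param r_values numeric vector of per-replicate correlations.
#' @return list with `mean_r`, `ci_lower`, `ci_upper`, `n_replicates`.
#' @export
#' @examples
#' accuracy_summary(c(0.5, 0.6)) # mean 0.5521
accuracy_summary <- function(r_values) {
  stopifnot(length(r_values) >= 1, all(is.finite(r_values)))
  z <- atanh(clip_r(r_values))
  mz <- mean(z)
  se <- if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else 0
  list(mean_r = tanh(mz),
       ci_lower = tanh(mz - 1.96 * se),
       ci_upper = tanh(mz + 1.96 * se),
       n_replicates = length(z))
}

#' Z-test comparing two correlation-based accuracies
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. Vectorized over replicates; the replicate
#' p-values are summarized by their median.
#'
#' @param r1,r2 accuracy (Pearson r) of the two PRS approaches, possibly
#'   vectors over replicates.
#' @param n1,n2 evaluation-sample sizes (must exceed 3).
#' @return list with vectors `z`, `p`, and scalar `median_p`.
#' @export
#' @examples
#' compare_accuracies(0.77, 5000, 0.45, 5000) # z ~ 26.8
compare_accuracies <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) <= 3)) stop("sample sizes must exceed 3")
  z <- (atanh(clip_r(r1)) - atanh(clip_r(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, median_p = stats::median(p))
}

#' Stratify individuals by global European ancestry
#'
#' Strata follow the published open intervals: high (0.8 < rho < 1),
#' intermediate (0.2 < rho <= 0.8), low (0 < rho <= 0.2); a rho exactly
#' on an interior edge is assigned downward (0.8 is intermediate, 0.2 is
#' low). Unadmixed individuals (rho exactly 0 or 1) belong to no
#' ancestry stratum (NA): they are genomically indistinguishable from
#' the source populations. Deciles of `[0, 1]` (bins `(0, 0.1], ...,
#' (0.9, 1]`, with 0 in the first decile) are assigned to everyone for
#' the ancestry-slope analysis.
#'
#' @param rho numeric vector of global European-ancestry proportions.
#' @return data.frame with columns `rho`, `stratum` (ordered factor
#'   low < intermediate < high), `decile` (integer 1-10).
#' @export
stratify_by_ancestry <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  stratum <- cut(rho, breaks = c(-Inf, 0.2, 0.8, Inf),
                 labels = c("low", "intermediate", "high"),
                 ordered_result = TRUE)
  stratum[rho == 0 | rho == 1] <- NA
  decile <- pmax(1L, as.integer(ceiling(rho * 10)))
  data.frame(rho = rho, stratum = stratum, decile = decile)
}

#' Variance explained per ancestry decile
#'
#' Squared Pearson correlation between the PRS and the total trait
#' liability, within each decile of global European ancestry.
#'
#' @param prs,liability aligned vectors over admixed individuals.
#' @param rho global European-ancestry proportions.
#' @param min_n minimum individuals per decile (default 20); smaller
#'   deciles give NA, keeping unstable within-decile correlation
#'   estimates out of the slope fit.
#' @return numeric vector of length 10 (R-squared per decile).
#' @export
decile_r2 <- function(prs, liability, rho, min_n = 20) {
  strat <- stratify_by_ancestry(rho)
  vapply(1:10, function(d) {
    sel <- strat$decile == d
    if (sum(sel) < min_n || stats::sd(prs[sel]) == 0) return(NA_real_)
    stats::cor(prs[sel], liability[sel])^2
  }, numeric(1))
}

#' Ancestry-accuracy slope from per-decile variance explained
#'
#' Ordinary least squares of decile R-squared (in percent) on the decile
#' midpoint of global European ancestry, reported as the change in
#' percent variance explained per 10% increase in European ancestry.
#'
#' @param per_decile_r2 numeric vector of length 10 (proportions, NA for
#'   unpopulated deciles); at least 3 populated deciles required.
#' @return list with `slope_per_10pct`, `intercept_pct`, `n_deciles`.
#' @export
ancestry_accuracy_slope <- function(per_decile_r2) {
  stopifnot(length(per_decile_r2) == 10)
  ok <- !is.na(per_decile_r2)
  if (sum(ok) < 3)
    stop("fewer than 3 populated ancestry deciles; cannot fit a slope")
  mid10 <- (seq(0.05, 0.95, by = 0.1) / 0.1)[ok] # midpoints in 10% units
  y <- 100 * per_decile_r2[ok]
  fit <- stats::lm(y ~ mid10)
  list(slope_per_10pct = unname(stats::coef(fit)[2]),
       intercept_pct = unname(stats::coef(fit)[1]),
       n_deciles = sum(ok))
}

#' LD tagging of causal variants by PRS variants
#'
#' For each PRS strategy and each population panel: the number of PRS
#' variants that are themselves causal; the number tagging at least one
#' causal variant at `r^2` above each threshold (within +/- `window_bp`,
#' self-pairs included, so counts at looser thresholds are always >=
#' counts at stricter ones); and, per causal variant, the LD score
#' `sum r^2` over PRS variants in the window plus its PRS-size-normalized
#' version. Causal variants monomorphic in a panel contribute r^2 = 0
#' there.
#'
#' @param arch a `trait_architecture`.
#' @param prs_models named list of `prs_model`s.
#' @param panels named list of `haplotype_panel`s (e.g. EUR and AFR LD
#'   panels).
#' @param window_bp tagging window (default +/- 1 Mb).
#' @param thresholds r-squared thresholds for the tagging counts.
#' @return An object of class `tagging_report`: list with `counts`
#'   (data.frame: model, panel, n_prs_variants, n_exact_causal and one
#'   `tag_r2_gt_*` column per threshold), `ld_scores` (data.frame:
#'   model, causal site, LD score per panel, normalized score), and
#'   `ld_score_correlation` (per model, Pearson r between the two
#'   panels' LD scores; NA unless exactly two panels).
#' @export
causal_tagging_summary <- function(arch, prs_models, panels,
                                   window_bp = 1e6,
                                   thresholds = c(0.8, 0.6, 0.4, 0.2)) {
  stopifnot(inherits(arch, "trait_architecture"), length(panels) >= 1)
  thresholds <- sort(thresholds, decreasing = TRUE)
  counts <- list()
  ldsc <- list()
  ldcor <- list()
  for (mn in names(prs_models)) {
    model <- prs_models[[mn]]
    nv <- nrow(model$variants)
    per_panel_scores <- list()
    for (pn in names(panels)) {
      panel <- panels[[pn]]
      causal_pos <- panel$positions[arch$causal_indices]
      if (nv == 0) {
        message("empty PRS model '", mn, "': empty tagging report row")
        row <- data.frame(model = mn, panel = pn, n_prs_variants = 0L,
                          n_exact_causal = 0L)
        for (th in thresholds) row[[sprintf("tag_r2_gt_%g", th)]] <- 0L
        counts[[paste(mn, pn)]] <- row
        per_panel_scores[[pn]] <- rep(0, length(arch$causal_indices))
        next
      }
      dos_prs <- genotype_dosage(panel, sites = model$variants$site_index)
      dos_cau <- genotype_dosage(panel, sites = arch$causal_indices)
      sd_prs <- apply(dos_prs, 2, stats::sd)
      sd_cau <- apply(dos_cau, 2, stats::sd)
      ok_p <- sd_prs > 0
      ok_c <- sd_cau > 0
      r2 <- matrix(0, nv, length(arch$causal_indices))
      if (any(ok_p) && any(ok_c))
        r2[ok_p, ok_c] <- stats::cor(dos_prs[, ok_p, drop = FALSE],
                                     dos_cau[, ok_c, drop = FALSE])^2
      in_window <- abs(outer(model$variants$pos, causal_pos, "-")) <= window_bp
      r2[!in_window] <- 0
      best <- apply(r2, 1, max)
      row <- data.frame(model = mn, panel = pn, n_prs_variants = nv,
                        n_exact_causal = sum(model$variants$pos %in% causal_pos))
      for (th in thresholds)
        row[[sprintf("tag_r2_gt_%g", th)]] <- sum(best > th)
      counts[[paste(mn, pn)]] <- row
      per_panel_scores[[pn]] <- colSums(r2)
    }
    sc <- data.frame(model = mn, causal_index = arch$causal_indices)
    for (pn in names(panels)) {
      sc[[paste0("ld_score_", tolower(pn))]] <- per_panel_scores[[pn]]
      sc[[paste0("ld_score_norm_", tolower(pn))]] <-
        if (nv > 0) per_panel_scores[[pn]] / nv else 0
    }
    ldsc[[mn]] <- sc
    ldcor[[mn]] <- if (length(panels) == 2 && nv > 0 &&
                       stats::sd(per_panel_scores[[1]]) > 0 &&
                       stats::sd(per_panel_scores[[2]]) > 0)
      stats::cor(per_panel_scores[[1]], per_panel_scores[[2]])
    else NA_real_
  }
  structure(list(counts = do.call(rbind, c(counts, make.row.names = FALSE)),
                 ld_scores = do.call(rbind, c(ldsc, make.row.names = FALSE)),
                 ld_score_correlation = unlist(ldcor)),
            class = "tagging_report")
}

#' MAF spectrum of selected PRS variants across populations
#'
#' Bins each PRS strategy's selected variants by their MAF computed in
#' each panel and reports the fraction per bin; the `<1%` bin makes
#' cross-population rarity of selected variants explicit.
#'
#' @param prs_models named list of `prs_model`s.
#' @param panels named list of `haplotype_panel`s.
#' @param bins increasing MAF bin edges starting at 0 and ending at 0.5.
#' @return data.frame with columns `model`, `panel`, `bin`, `fraction`,
#'   `count`.
#' @export
maf_spectrum_table <- function(prs_models, panels,
                               bins = c(0, 0.01, 0.05, 0.1, 0.2, 0.5)) {
  stopifnot(length(bins) >= 2, bins[1] == 0,
            !is.unsorted(bins, strictly = TRUE))
  out <- list()
  for (mn in names(prs_models)) {
    v <- prs_models[[mn]]$variants
    for (pn in names(panels)) {
      if (nrow(v) == 0) {
        next
      }
      maf <- panel_maf(panels[[pn]], sites = v$site_index)
      cuts <- cut(maf, breaks = bins, right = FALSE,
                  include.lowest = FALSE)
      # MAF can equal the top edge 0.5; fold it into the last bin
      cuts[maf >= bins[length(bins)]] <- levels(cuts)[nlevels(cuts)]
      tab <- table(cuts)
      out[[paste(mn, pn)]] <- data.frame(
        model = mn, panel = pn, bin = names(tab),
        fraction = as.vector(tab) / nrow(v), count = as.vector(tab))
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
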