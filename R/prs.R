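# PRS construction: clumping + thresholding, scoring, local-ancestry
# weighting, and the two-PRS linear mixture.

#' Squared Pearson correlation between two dosage vectors
#'
#' @param dosages_a,dosages_b equal-length numeric vectors, each with
#'   nonzero variance.
#' @return LD r-squared in `[0, 1]`.
#' @export
#' @examples
#' ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)) # 9/11
ld_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  if (stats::sd(dosages_a) == 0 || stats::sd(dosages_b) == 0)
    stop("zero-variance dosage vector: drop monomorphic variants before computing LD")
  stats::cor(dosages_a, dosages_b)^2
}

#' Select PRS variants by p-value thresholding and LD clumping
#'
#' Greedy clumping: passing variants (`p < p_threshold`) are sorted by
#' ascending p (ties by larger chi-square, then lower variant index);
#' repeatedly the best remaining variant becomes an index variant and all
#' remaining variants within `window_bp` of it with reference-panel
#' `r^2 >= r2_threshold` are removed. Selected variants keep their
#' `log(OR)` as the PRS weight.
#'
#' @param assoc an `assoc_result`.
#' @param reference_panel `haplotype_panel` supplying LD (the GWAS's own
#'   training genotypes; for meta-analysis results, both training sets
#'   combined).
#' @param p_threshold inclusion threshold on the association p-value.
#' @param r2_threshold LD pruning threshold (default 0.2).
#' @param window_bp clumping window (default 1 Mb, applied as +/- 1 Mb).
#' @return An object of class `prs_model`; its `variants` data.frame has
#'   columns `variant_id`, `pos`, `site_index`, `effect_allele`, `weight`,
#'   `p`. An empty model (no passing variant) is returned, not an error.
#' @export
clump_and_threshold <- function(assoc, reference_panel, p_threshold = 0.01,
                                r2_threshold = 0.2, window_bp = 1e6) {
  stopifnot(inherits(assoc, "assoc_result") || is.data.frame(assoc))
  pass <- assoc[assoc$p < p_threshold, , drop = FALSE]
  params <- list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_bp = window_bp)
  src <- attr(assoc, "population") %||% "unknown"
  if (nrow(pass) == 0) {
    message("clump_and_threshold: no variant passes p < ", p_threshold,
            "; returning an empty model")
    return(new_prs_model(pass[, c("variant_id", "pos", "site_index",
                                  "effect_allele", "p")], src, params))
  }
  if (max(pass$site_index) > length(reference_panel$positions))
    stop("reference panel does not cover the association variants")

  ord <- order(pass$p, -pass$chisq, pass$site_index)
  pass <- pass[ord, ]
  dos <- genotype_dosage(reference_panel, sites = pass$site_index)
  v <- apply(dos, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0),
            " variant(s) monomorphic in the LD reference dropped from clumping")
    pass <- pass[v > 0, , drop = FALSE]
    dos <- dos[, v > 0, drop = FALSE]
  }

  n <- nrow(pass)
  alive <- rep(TRUE, n)
  selected <- integer(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    selected <- c(selected, i)
    alive[i] <- FALSE
    cand <- which(alive & abs(pass$pos - pass$pos[i]) <= window_bp)
    if (length(cand)) {
      r2 <- as.vector(stats::cor(dos[, i], dos[, cand, drop = FALSE]))^2
      alive[cand[r2 >= r2_threshold]] <- FALSE
    }
  }
  sel <- pass[selected, , drop = FALSE]
  sel <- sel[order(sel$site_index), ]
  variants <- data.frame(variant_id = sel$variant_id, pos = sel$pos,
                         site_index = sel$site_index,
                         effect_allele = sel$effect_allele,
                         weight = sel$log_or, p = sel$p)
  new_prs_model(variants, src, params)
}

new_prs_model <- function(variants, variant_source, params,
                          weight_source = variant_source) {
  rownames(variants) <- NULL
  if (!"weight" %in% names(variants) && nrow(variants) == 0)
    variants$weight <- numeric(0)
  structure(list(variants = variants, variant_source = variant_source,
                 weight_source = weight_source, params = params),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model: %d variants (source %s, weights %s), p < %g, r2 < %g, window %g bp\n",
              nrow(x$variants), x$variant_source, x$weight_source,
              x$params$p_threshold %||% NA, x$params$r2_threshold %||% NA,
              x$params$window_bp %||% NA))
  invisible(x)
}

#' Replace the weights of a PRS model with another study's estimates
#'
#' Keeps the selected variant set but looks each variant up in a second
#' association scan and uses that study's log(OR), aligned to the model's
#' effect alleles. Variants the weighting study did not test (for
#' example, rare there and excluded by its MAF filter) get weight 0 and
#' are counted in attribute `n_unweighted`.
#'
#' @param model a `prs_model`.
#' @param assoc the `assoc_result` supplying the new weights.
#' @return A `prs_model` with updated weights and `weight_source`.
#' @export
reweight_model <- function(model, assoc) {
  v <- model$variants
  j <- match(v$site_index, assoc$site_index)
  b_alt <- ifelse(assoc$effect_allele[j] == "ALT",
                  assoc$log_or[j], -assoc$log_or[j])
  w <- ifelse(v$effect_allele == "ALT", b_alt, -b_alt)
  w[is.na(w)] <- 0
  v$weight <- w
  out <- new_prs_model(v, model$variant_source, model$params,
                       weight_source = attr(assoc, "population") %||% "unknown")
  attr(out, "n_unweighted") <- sum(is.na(j))
  out
}

#' Score a PRS on a panel
#'
#' `score_i = sum_v weight_v * dosage_iv`, with dosage counted on the
#' model's effect allele (an effect allele equal to the panel REF counts
#' `2 - ALT dosage`). Model variants absent from the panel contribute 0
#' and are reported per individual in attribute `n_missing`.
#'
#' @param panel a `haplotype_panel`.
#' @param model a `prs_model`.
#' @return named numeric vector of scores, one per diploid individual.
#' @export
score_prs <- function(panel, model) {
  v <- model$variants
  n <- n_individuals(panel)
  if (nrow(v) == 0) {
    s <- stats::setNames(rep(0, n), panel$individual_ids)
    attr(s, "n_missing") <- rep(0L, n)
    return(s)
  }
  if (!all(v$effect_allele %in% c("ALT", "REF")))
    stop("effect allele matches neither REF nor ALT for variant(s) ",
         paste(v$variant_id[!v$effect_allele %in% c("ALT", "REF")],
               collapse = ", "))
  j <- match(v$pos, panel$positions)
  present <- !is.na(j)
  n_missing <- sum(!present)
  dos <- genotype_dosage(panel, sites = j[present])
  flip <- v$effect_allele[present] == "REF"
  if (any(flip))
    dos[, flip] <- 2L - dos[, flip]
  s <- as.vector(dos %*% v$weight[present])
  names(s) <- panel$individual_ids
  attr(s, "n_missing") <- rep(n_missing, n)
  s
}

#' Local-ancestry-weighted PRS for admixed individuals
#'
#' For each haplotype allele the weight is chosen by the ancestry of the
#' tract covering that variant on that haplotype (a variant exactly on a
#' tract boundary belongs to the left-closed tract; 0-based half-open
#' convention). The EUR-ancestry partial sum is multiplied by the
#' individual's global ancestry `rho_EUR` and the AFR partial sum by
#' `1 - rho_EUR`:
#' `PRS_i = rho_i * sum_{alleles on EUR tracts} w_EUR g + (1 - rho_i) *
#' sum_{alleles on AFR tracts} w_AFR g`.
#' For an unadmixed individual (`rho` 0 or 1, single-ancestry tracts) the
#' score equals [score_prs()] with the corresponding weights exactly.
#'
#' @param panel the ADMIXED `haplotype_panel`.
#' @param tracts the matching `ancestry_tracts`.
#' @param model_variants data.frame with columns `pos`, `effect_allele`
#'   (the selected variant set, e.g. `model$variants`).
#' @param weights_eur,weights_afr numeric weights aligned to
#'   `model_variants` rows (European- and African-GWAS effects).
#' @return named numeric vector of scores.
#' @export
score_local_ancestry_prs <- function(panel, tracts, model_variants,
                                     weights_eur, weights_afr) {
  stopifnot(nrow(model_variants) == length(weights_eur),
            length(weights_eur) == length(weights_afr))
  if (nrow(model_variants) == 0)
    return(stats::setNames(rep(0, n_individuals(panel)),
                           panel$individual_ids))
  j <- match(model_variants$pos, panel$positions)
  if (anyNA(j))
    stop("panel does not cover all model variants")
  rho <- compute_global_ancestry(tracts)
  if (!identical(names(rho), panel$individual_ids))
    stop("tracts and panel describe different individuals")
  L <- attr(tracts, "region_length")
  if (any(model_variants$pos < 0 | model_variants$pos >= L))
    stop("model variant position outside the tract-covered region")

  pos <- model_variants$pos
  flip <- model_variants$effect_allele == "REF"
  n <- n_individuals(panel)
  tr_by_hap <- split(tracts[, c("start", "ancestry")], tracts$haplotype_id)
  score <- numeric(n)
  for (i in seq_len(n)) {
    acc_eur <- 0
    acc_afr <- 0
    for (k in 1:2) {
      h <- 2L * i - 2L + k
      hid <- sprintf("%s_h%d", panel$individual_ids[i], k)
      tr <- tr_by_hap[[hid]]
      if (is.null(tr) || nrow(tr) == 0) stop("no tracts for haplotype ", hid)
      tr <- tr[order(tr$start), ]
      anc <- tr$ancestry[findInterval(pos, tr$start)]
      allele <- as.integer(hap_int(panel, h, j))
      allele[flip] <- 1L - allele[flip]
      is_eur <- anc == "EUR"
      acc_eur <- acc_eur + sum(weights_eur[is_eur] * allele[is_eur])
      acc_afr <- acc_afr + sum(weights_afr[!is_eur] * allele[!is_eur])
    }
    score[i] <- rho[i] * acc_eur + (1 - rho[i]) * acc_afr
  }
  stats::setNames(score, panel$individual_ids)
}

#' Fit the two-PRS linear mixture
#'
#' Least-squares fit of `target ~ alpha1 * prs_eur + alpha2 * prs_afr +
#' intercept` in a fitting cohort (the caller passes a cohort disjoint
#' from the evaluation cohort). Optionally k-fold cross-validation, with
#' stratified folds for binary targets.
#'
#' @param prs_eur,prs_afr,target aligned numeric vectors over the fitting
#'   cohort.
#' @param k `NULL` for a single fit, or a fold count for k-fold CV (the
#'   reported coefficients are then averaged over folds).
#' @param stratified stratify folds on a binary target.
#' @param seed seed for fold assignment.
#' @return An object of class `mixture_weights`: list with `alpha1`,
#'   `alpha2`, `intercept`, `r2` (in-sample, or mean held-out across
#'   folds), `n`, `folds`.
#' @export
fit_mixture_prs <- function(prs_eur, prs_afr, target, k = NULL,
                            stratified = FALSE, seed = 1) {
  stopifnot(length(prs_eur) == length(prs_afr),
            length(prs_afr) == length(target))
  if (abs(stats::cor(prs_eur, prs_afr)) > 1 - 1e-12)
    stop("PRS columns are collinear (|correlation| = 1); fit a single-PRS model instead")
  fit1 <- function(idx_fit, idx_val) {
    fit <- stats::lm(target ~ prs_eur + prs_afr,
                     data = data.frame(target = target[idx_fit],
                                       prs_eur = prs_eur[idx_fit],
                                       prs_afr = prs_afr[idx_fit]))
    pred <- stats::predict(fit, data.frame(prs_eur = prs_eur[idx_val],
                                           prs_afr = prs_afr[idx_val]))
    c(stats::coef(fit), r2 = stats::cor(pred, target[idx_val])^2)
  }
  n <- length(target)
  if (is.null(k)) {
    est <- fit1(seq_len(n), seq_len(n))
    folds <- 1L
  } else {
    stopifnot(k >= 2, k <= n)
    fold_id <- with_seed(seed, {
      if (stratified) {
        stopifnot(length(unique(target)) == 2)
        id <- integer(n)
        for (lev in unique(target)) {
          sel <- which(target == lev)
          id[sel] <- sample(rep_len(seq_len(k), length(sel)))
        }
        id
      } else sample(rep_len(seq_len(k), n))
    })
    ests <- sapply(seq_len(k), function(f)
      fit1(which(fold_id != f), which(fold_id == f)))
    est <- rowMeans(ests)
    folds <- as.integer(k)
  }
  structure(list(intercept = unname(est[1]), alpha1 = unname(est[2]),
                 alpha2 = unname(est[3]), r2 = unname(est["r2"]),
                 n = n, folds = folds),
            class = "mixture_weights")
}

#' @export
print.mixture_weights <- function(x, ...) {
  cat(sprintf("mixture_weights: alpha1 (EUR) = %.4f, alpha2 (AFR) = %.4f, intercept = %.4f (n = %d, folds = %d)\n",
              x$alpha1, x$alpha2, x$intercept, x$n, x$folds))
  invisible(x)
}

#' Apply fitted mixture weights to two PRS vectors
#' @param weights a `mixture_weights` object.
#' @param prs_eur,prs_afr aligned PRS vectors.
#' @return numeric vector of combined scores.
#' @export
predict_mixture <- function(weights, prs_eur, prs_afr) {
  weights$intercept + weights$alpha1 * prs_eur + weights$alpha2 * prs_afr
}
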