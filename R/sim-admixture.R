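# Pedigree-based two-way admixture with true local-ancestry tracts.
#
# Each admixed haplotype is produced by explicit meiosis down a pedigree
# of `admix_generations` generations: crossovers are a Poisson process
# (one expected crossover per Morgan per meiosis, no interference), and
# pedigree founders are drawn from the EUR/AFR founder panels. The
# ancestry of every copied segment is recorded exactly, so tracts are
# truth, not inference.

# A gamete is a list of parallel vectors: segment start (bp, 0-based),
# founder haplotype id, ancestry code (1 = EUR, 2 = AFR). Segment i ends
# where segment i+1 starts (or at region end).

new_gamete <- function(start, founder, ancestry)
  list(start = start, founder = founder, ancestry = ancestry)

# One meiosis: recombine two parental gametes.
meiosis <- function(g1, g2, l_morgan, region_bp) {
  k <- stats::rpois(1L, l_morgan)
  first <- sample.int(2L, 1L)
  if (k == 0L) return(if (first == 1L) g1 else g2)
  cuts <- sort(stats::runif(k, 0, region_bp))
  bounds <- c(0, cuts)
  parents <- list(g1, g2)
  src <- rep(c(first, 3L - first), length.out = k + 1L)
  starts <- founders <- ancs <- vector("list", k + 1L)
  ends <- c(cuts, region_bp)
  for (i in seq_len(k + 1L)) {
    p <- parents[[src[i]]]
    lo <- bounds[i]; hi <- ends[i]
    if (lo >= hi) next
    j0 <- findInterval(lo, p$start)
    j1 <- findInterval(hi, p$start, left.open = TRUE)
    idx <- j0:j1
    s <- p$start[idx]; s[1] <- lo
    starts[[i]] <- s
    founders[[i]] <- p$founder[idx]
    ancs[[i]] <- p$ancestry[idx]
  }
  g <- new_gamete(unlist(starts), unlist(founders), unlist(ancs))
  # merge segments copied from the same founder haplotype
  keep <- c(TRUE, g$founder[-1L] != g$founder[-length(g$founder)])
  new_gamete(g$start[keep], g$founder[keep], g$ancestry[keep])
}

# Recursively sample the gamete transmitted through `depth` generations.
sample_gamete <- function(depth, draw_founder, l_morgan, region_bp) {
  if (depth == 1L) {
    f <- draw_founder()
    g1 <- new_gamete(0, f$hap1, f$ancestry)
    g2 <- new_gamete(0, f$hap2, f$ancestry)
  } else {
    g1 <- sample_gamete(depth - 1L, draw_founder, l_morgan, region_bp)
    g2 <- sample_gamete(depth - 1L, draw_founder, l_morgan, region_bp)
  }
  meiosis(g1, g2, l_morgan, region_bp)
}

#' Simulate an admixed population with true local-ancestry tracts
#'
#' Generates `config$n_admixed` diploid admixed individuals by explicit
#' meiosis over `config$admix_generations` generations of random mating.
#' Each individual draws a European-ancestry proportion
#' `theta_i ~ Uniform(0,1)` once, and every pedigree founder of that
#' individual is an EUR founder independently with probability `theta_i`
#' (AFR otherwise); this populates the full 0-100% global-ancestry
#' spectrum. Pass `theta` to fix the proportions instead.
#'
#' @param founders_eur,founders_afr founder `haplotype_panel`s sharing one
#'   variant coordinate space.
#' @param config a [sim_config()]; uses `n_admixed`, `admix_generations`,
#'   `region_length_bp`, `recombination_rate`, `seed`.
#' @param theta `NULL` (default: Uniform(0,1) per individual), a numeric
#'   scalar/vector of per-individual founder EUR probabilities, or an
#'   `n_admixed` x 2 matrix giving the probability separately for the
#'   pedigree behind each of the two haplotypes.
#' @param no_reuse if `TRUE`, every founder individual is used at most
#'   once across the whole cohort; errors when the pool is exhausted.
#' @return list with `panel` (ADMIXED `haplotype_panel`) and `tracts`
#'   (an `ancestry_tracts` object).
#' @export
simulate_admixture <- function(founders_eur, founders_afr, config,
                               theta = NULL, no_reuse = FALSE) {
  stopifnot(inherits(founders_eur, "haplotype_panel"),
            inherits(founders_afr, "haplotype_panel"))
  if (!identical(founders_eur$positions, founders_afr$positions))
    stop("founder panels do not share the same variant coordinate space")
  n <- config$n_admixed
  g <- config$admix_generations
  region_bp <- config$region_length_bp
  l_morgan <- region_bp * config$recombination_rate

  n_eur_f <- n_individuals(founders_eur)
  n_afr_f <- n_individuals(founders_afr)
  founders_per_hap <- 2L^(g - 1L)
  if (no_reuse) {
    need <- n * 2L * founders_per_hap # upper bound, all one ancestry
    if (need > n_eur_f + n_afr_f)
      stop(sprintf(
        "founder pool too small for no-reuse admixture: need up to %d founder individuals, have %d",
        need, n_eur_f + n_afr_f))
  }

  with_seed(derive_seed(config$seed, 7L), {
    if (is.null(theta)) theta <- stats::runif(n)
    th <- if (is.matrix(theta)) theta else cbind(theta, theta)
    stopifnot(nrow(th) == n || nrow(th) == 1L)
    if (nrow(th) == 1L) th <- th[rep(1L, n), , drop = FALSE]
    stopifnot(all(th >= 0 & th <= 1))

    pool <- list(eur = sample.int(n_eur_f), afr = sample.int(n_afr_f))
    used <- c(eur = 0L, afr = 0L)
    draw_founder_for <- function(p_eur) function() {
      anc <- if (stats::runif(1) < p_eur) 1L else 2L
      key <- c("eur", "afr")[anc]
      n_pool <- if (anc == 1L) n_eur_f else n_afr_f
      if (no_reuse) {
        if (used[[key]] >= n_pool)
          stop(sprintf("founder pool too small: %s founders exhausted (%d available)",
                       toupper(key), n_pool))
        used[key] <<- used[[key]] + 1L
        ind <- pool[[key]][used[[key]]]
      } else ind <- sample.int(n_pool, 1L)
      # global founder haplotype ids: EUR occupy 1..2*n_eur_f, AFR after
      off <- if (anc == 1L) 0L else 2L * n_eur_f
      list(hap1 = off + 2L * ind - 1L, hap2 = off + 2L * ind,
           ancestry = anc)
    }

    gametes <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      gametes[[2L * i - 1L]] <- sample_gamete(g, draw_founder_for(th[i, 1]),
                                              l_morgan, region_bp)
      gametes[[2L * i]] <- sample_gamete(g, draw_founder_for(th[i, 2]),
                                         l_morgan, region_bp)
    }
  })

  positions <- founders_eur$positions
  S <- length(positions)
  hap <- matrix(raw(1), nrow = 2L * n, ncol = S)
  all_founder_haps <- rbind(founders_eur$haplotypes, founders_afr$haplotypes)
  ids <- sprintf("adm_%d", seq_len(n))
  tract_rows <- vector("list", 2L * n)
  for (h in seq_len(2L * n)) {
    gm <- gametes[[h]]
    ends <- c(gm$start[-1L], region_bp)
    for (s in seq_along(gm$start)) {
      j0 <- findInterval(gm$start[s], positions, left.open = TRUE) + 1L
      j1 <- findInterval(ends[s] - 1e-9, positions)
      if (j0 <= j1)
        hap[h, j0:j1] <- all_founder_haps[gm$founder[s], j0:j1]
    }
    keep <- c(TRUE, gm$ancestry[-1L] != gm$ancestry[-length(gm$ancestry)])
    st <- gm$start[keep]
    tract_rows[[h]] <- data.frame(
      haplotype_id = sprintf("%s_h%d", ids[ceiling(h / 2)], 2L - h %% 2L),
      individual_id = ids[ceiling(h / 2)],
      start = st, end = c(st[-1L], region_bp),
      ancestry = c("EUR", "AFR")[gm$ancestry[keep]])
  }
  tracts <- ancestry_tracts(do.call(rbind, tract_rows), region_bp)
  panel <- haplotype_panel(positions, hap, "ADMIXED", ids)
  list(panel = panel, tracts = tracts)
}

#' Construct an ancestry-tracts object
#'
#' Per-haplotype ancestry segments in 0-based half-open coordinates that
#' must tile `[0, region_length)` without gaps or overlaps.
#'
#' @param df data.frame with columns `haplotype_id`, `individual_id`,
#'   `start`, `end`, `ancestry` ("EUR"/"AFR").
#' @param region_length region length in bp.
#' @export
ancestry_tracts <- function(df, region_length) {
  stopifnot(all(c("haplotype_id", "individual_id", "start", "end",
                  "ancestry") %in% names(df)),
            all(df$ancestry %in% c("EUR", "AFR")))
  rownames(df) <- NULL
  structure(df, region_length = as.double(region_length),
            class = c("ancestry_tracts", "data.frame"))
}

#' @export
print.ancestry_tracts <- function(x, ...) {
  cat(sprintf("ancestry_tracts: %d tracts, %d haplotypes, region %.3g Mb\n",
              nrow(x), length(unique(x$haplotype_id)),
              attr(x, "region_length") / 1e6))
  invisible(x)
}

validate_tiling <- function(tracts) {
  L <- attr(tracts, "region_length")
  for (hid in unique(tracts$haplotype_id)) {
    tr <- tracts[tracts$haplotype_id == hid, ]
    tr <- tr[order(tr$start), ]
    ok <- tr$start[1] == 0 && tr$end[nrow(tr)] == L &&
      all(tr$end > tr$start) &&
      (nrow(tr) == 1 || all(tr$start[-1] == tr$end[-nrow(tr)]))
    if (!ok)
      stop("ancestry tracts do not tile the region for haplotype ", hid)
  }
  invisible(TRUE)
}

#' Global European-ancestry proportion per individual
#'
#' `rho_EUR` is the fraction of base pairs, across both haplotypes, lying
#' in EUR-ancestry tracts.
#'
#' @param tracts an `ancestry_tracts` object.
#' @return named numeric vector (one entry per individual) in `[0, 1]`.
#' @export
compute_global_ancestry <- function(tracts) {
  stopifnot(inherits(tracts, "ancestry_tracts"))
  validate_tiling(tracts)
  L <- attr(tracts, "region_length")
  len <- tracts$end - tracts$start
  eur_bp <- tapply(len * (tracts$ancestry == "EUR"), tracts$individual_id,
                   sum)
  rho <- as.vector(eur_bp) / (2 * L)
  names(rho) <- names(eur_bp)
  # restore cohort order (tapply sorts alphabetically)
  ord <- unique(tracts$individual_id)
  rho[ord]
}
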