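# Liability-threshold trait model with known genetic truth.

#' Evenly spaced indices through an ordered variant list
#'
#' Selects `m` unique indices evenly spaced over ranks `1..n` (ranks, not
#' base pairs, so exactly `m` variants are causal regardless of variant
#' density).
#' @param n total variant count.
#' @param m number of indices to select.
#' @return sorted integer vector of length `m`.
#' @export
evenly_spaced_indices <- function(n, m) {
  stopifnot(m >= 1, n >= m)
  unique(as.integer(round(seq(1, n, length.out = m))))
}

#' Build a shared causal architecture
#'
#' Selects `m` causal variants evenly spaced through the ordered variant
#' list of the shared coordinate space and draws their effect sizes
#' `beta ~ N(0, h2/m)`. The same architecture (indices and betas) is
#' applied to every population: effect sizes are completely shared.
#'
#' @param positions the shared variant positions (or any object whose
#'   length is the variant count), or a `haplotype_panel`.
#' @param m causal variant count.
#' @param h2 trait heritability in `(0, 1]`.
#' @param seed integer seed.
#' @return An object of class `trait_architecture`: list with `m`, `h2`,
#'   `causal_indices`, `betas`.
#' @export
#' @examples
#' arch <- build_architecture(1:100, m = 10, h2 = 0.5, seed = 1)
build_architecture <- function(positions, m = 1000, h2 = 0.5, seed = 1) {
  if (inherits(positions, "haplotype_panel")) positions <- positions$positions
  n <- length(positions)
  if (m > n)
    stop(sprintf("m = %d causal variants requested but only %d variants available", m, n))
  stopifnot(h2 > 0, h2 <= 1)
  idx <- evenly_spaced_indices(n, m)
  betas <- with_seed(seed, stats::rnorm(length(idx), 0, sqrt(h2 / m)))
  structure(list(m = as.integer(m), h2 = h2,
                 causal_indices = idx, betas = betas),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("trait_architecture: m = %d causal variants, h2 = %.3g\n",
              x$m, x$h2))
  invisible(x)
}

#' Compute genetic, environmental, and total liability
#'
#' Raw score `X = sum_i beta_i g_i` over the causal variants; the
#' standardized genetic liability is `G = (X - mean(X)) / sd(X) * sqrt(h2)`
#' and the environmental component `E = (eps - mean(eps)) / sd(eps) *
#' sqrt(1 - h2)` with `eps ~ N(0, 1 - h2)`; total liability is `G + E`.
#' Standardization is within the given population sample, using the
#' sample (n-1) denominator, so `var(G) == h2` and `var(E) == 1 - h2`
#' hold exactly. With `h2 = 1`, `E` is identically zero.
#'
#' @param panel a `haplotype_panel` covering all causal indices.
#' @param arch a `trait_architecture`.
#' @param seed integer seed for the environmental draw.
#' @return An object of class `liability_table`: data.frame with columns
#'   `individual_id`, `X`, `G`, `E`, `liability`.
#' @export
compute_liability <- function(panel, arch, seed = 1) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (max(arch$causal_indices) > length(panel$positions))
    stop("panel does not cover all causal indices")
  dos <- genotype_dosage(panel, sites = arch$causal_indices)
  x <- as.vector(dos %*% arch$betas)
  if (stats::sd(x) == 0)
    stop("raw genetic score X has zero variance (all causal variants monomorphic in this sample?)")
  g <- (x - mean(x)) / stats::sd(x) * sqrt(arch$h2)
  if (arch$h2 < 1) {
    eps <- with_seed(seed, stats::rnorm(length(x), 0, sqrt(1 - arch$h2)))
    e <- (eps - mean(eps)) / stats::sd(eps) * sqrt(1 - arch$h2)
  } else {
    e <- rep(0, length(x))
  }
  structure(data.frame(individual_id = panel$individual_ids,
                       X = x, G = g, E = e, liability = g + e),
            class = c("liability_table", "data.frame"))
}

#' Case-control-test study design
#'
#' @param prevalence disease prevalence (liability-threshold tail mass).
#' @param n_cases,n_controls requested case and control counts.
#' @param n_test_per_pop testing-sample size per source population.
#' @return An object of class `study_design`.
#' @export
study_design <- function(prevalence = 0.05, n_cases = 10000,
                         n_controls = 10000, n_test_per_pop = 5000) {
  stopifnot(prevalence > 0, prevalence < 1,
            n_cases >= 1, n_controls >= 1, n_test_per_pop >= 0)
  structure(list(prevalence = prevalence, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_test_per_pop = as.integer(n_test_per_pop)),
            class = "study_design")
}

#' Ascertain case, control, and testing samples
#'
#' Cases are the `n_cases` individuals with highest total liability among
#' the top `prevalence` fraction of the liability distribution (ties
#' broken by individual index, for determinism). Controls and testing
#' samples are drawn uniformly without replacement from the remainder;
#' the three sets are disjoint.
#'
#' @param liability a `liability_table`.
#' @param design a [study_design()].
#' @param seed integer seed for the control/test draw.
#' @return list of integer index vectors `cases`, `controls`, `test`.
#' @export
ascertain_samples <- function(liability, design, seed = 1) {
  n <- nrow(liability)
  n_tail <- floor(design$prevalence * n)
  if (design$n_cases > n_tail)
    stop(sprintf(
      "prevalence tail holds %d individuals but %d cases requested",
      n_tail, design$n_cases))
  ord <- order(-liability$liability, seq_len(n)) # ties by index
  cases <- sort(ord[seq_len(design$n_cases)])
  rest <- setdiff(seq_len(n), ord[seq_len(n_tail)])
  need <- design$n_controls + design$n_test_per_pop
  if (need > length(rest))
    stop(sprintf("need %d controls+test individuals but only %d remain below the case tail",
                 need, length(rest)))
  picked <- with_seed(seed, sample(rest, need))
  list(cases = cases,
       controls = sort(picked[seq_len(design$n_controls)]),
       test = sort(picked[design$n_controls + seq_len(design$n_test_per_pop)]))
}
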