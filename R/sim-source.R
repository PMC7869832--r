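# Source-population genotype simulation (coalescent bridge, R surface).

#' Simulate the two source populations
#'
#' Simulates European-like (EUR) and African-like (AFR) haplotype panels
#' under the configured two-population out-of-Africa demographic model.
#' Both panels (and the optional founder panels) live on the identical
#' variant coordinate space: the union of biallelic segregating sites of
#' the joint simulation. Multi-allelic / recurrently mutated sites are
#' dropped (their count is reported as an attribute).
#'
#' @param config a [sim_config()].
#' @return list with elements `eur`, `afr` (haplotype panels) and, when
#'   `config$n_founders_per_pop > 0`, `founders_eur`, `founders_afr`.
#'   Attribute `n_dropped_multiallelic` carries the dropped-site count.
#' @export
simulate_source_populations <- function(config) {
  res <- run_coalescent(config, mode = "panel")
  S <- res$meta$n_sites
  n_afr_h <- 2L * config$n_afr
  n_eur_h <- 2L * config$n_eur
  nf_h <- 2L * config$n_founders_per_pop
  stopifnot(nrow(res$haplotypes) == n_afr_h + n_eur_h + 2L * nf_h)

  rows <- function(from, n) res$haplotypes[seq(from, length.out = n), ,
                                           drop = FALSE]
  afr_start <- 1L
  afr_f_start <- afr_start + n_afr_h
  eur_start <- afr_f_start + nf_h
  eur_f_start <- eur_start + n_eur_h

  out <- list(
    eur = haplotype_panel(res$positions, rows(eur_start, n_eur_h), "EUR"),
    afr = haplotype_panel(res$positions, rows(afr_start, n_afr_h), "AFR"))
  if (nf_h > 0) {
    out$founders_eur <- haplotype_panel(
      res$positions, rows(eur_f_start, nf_h), "EUR",
      sprintf("eur_f_%d", seq_len(config$n_founders_per_pop)))
    out$founders_afr <- haplotype_panel(
      res$positions, rows(afr_f_start, nf_h), "AFR",
      sprintf("afr_f_%d", seq_len(config$n_founders_per_pop)))
  }
  attr(out, "n_dropped_multiallelic") <- res$meta$n_dropped_multiallelic
  out
}

#' Per-site allele counts without materializing genotypes
#'
#' Counts-only variant of [simulate_source_populations()]: returns the
#' derived-allele count of every biallelic site in each source population.
#' Scales to hundreds of thousands of diploids because no genotype matrix
#' is ever formed; founders are not included in the counts
#' (`n_founders_per_pop` is forced to 0).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `position`, `ac_eur`, `ac_afr` plus
#'   attributes `an_eur`, `an_afr` (total allele numbers).
#' @export
site_frequency_summary <- function(config) {
  config$n_founders_per_pop <- 0L
  res <- run_coalescent(config, mode = "counts")
  out <- data.frame(position = res$positions,
                    ac_eur = res$ac_eur, ac_afr = res$ac_afr)
  attr(out, "an_eur") <- 2L * config$n_eur
  attr(out, "an_afr") <- 2L * config$n_afr
  attr(out, "n_dropped_multiallelic") <- res$meta$n_dropped_multiallelic
  out
}

#' Fraction of evenly spaced causal variants that are rare
#'
#' Selects `m` causal variants evenly spaced through the ordered variant
#' list (same rule as [build_architecture()]) and returns, per population,
#' the fraction whose within-population MAF is below `maf_cut`. Used to
#' characterize how much of the causal architecture is invisible to a
#' GWAS restricted to common variants.
#'
#' @param config a [sim_config()].
#' @param m number of causal variants.
#' @param maf_cut MAF threshold (default 0.01).
#' @return named numeric vector with elements `eur` and `afr`.
#' @export
causal_rare_fraction <- function(config, m = 1000, maf_cut = 0.01) {
  sfs <- site_frequency_summary(config)
  idx <- evenly_spaced_indices(nrow(sfs), m)
  f_eur <- sfs$ac_eur[idx] / attr(sfs, "an_eur")
  f_afr <- sfs$ac_afr[idx] / attr(sfs, "an_afr")
  c(eur = mean(pmin(f_eur, 1 - f_eur) < maf_cut),
    afr = mean(pmin(f_afr, 1 - f_afr) < maf_cut))
}
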