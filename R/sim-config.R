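# Simulation configuration: region, rates, sample sizes, demography.

#' Default two-population out-of-Africa demographic parameters
#'
#' The three-population out-of-Africa parameterization of Gravel et al.
#' (2011), collapsed to the two simulated populations (the East Asian
#' branch is dropped). Times are in generations before present, sizes in
#' diploids, migration in per-generation fractions.
#'
#' @return Named list of demographic parameters.
#' @export
default_demography <- function() {
  list(
    N_ancestral       = 7310,   # ancestral African size
    N_afr_modern      = 14474,  # African expansion size
    N_ooa_bottleneck  = 1861,   # out-of-Africa bottleneck size
    N_eur_initial     = 1032,   # European size at onset of growth
    eur_growth_rate   = 0.0038, # per-generation exponential growth
    T_afr_expand_gen  = 5920,   # African expansion (~148 kya / 25 y)
    T_ooa_split_gen   = 2040,   # out-of-Africa split (~51 kya)
    T_eur_growth_gen  = 920,    # start of European growth (~23 kya)
    m_afr_eur_recent  = 2.5e-5, # AFR<->EUR migration after growth onset
    m_afr_ooa         = 15e-5   # AFR<->OOA migration during bottleneck
  )
}

#' Build a genotype-simulation configuration
#'
#' Defaults reproduce the study conditions of the simulation design:
#' a chromosome-20-like 63 Mb region, mutation rate 2e-8 per bp per
#' generation, 200,000 diploids per source population, 1,000 founders
#' per population, 5,000 admixed individuals, and 8 generations of
#' two-way admixture. Tests and desk-scale runs pass smaller values.
#'
#' @param region_length_bp Simulated region length in base pairs.
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param recombination_rate Uniform per-bp per-generation recombination
#'   rate (ignored where `recombination_map` is given).
#' @param recombination_map Optional data.frame with columns `left`
#'   (0-based segment start, bp; first must be 0) and `rate` giving a
#'   piecewise-constant recombination map.
#' @param n_eur,n_afr Diploid sample counts for the two source populations.
#' @param n_founders_per_pop Additional diploids per population reserved
#'   as admixture founders.
#' @param n_admixed Diploid admixed sample count.
#' @param admix_generations Generations since the single admixture pulse.
#' @param seed Integer seed; fully determines all downstream randomness.
#' @param demographic_params Named list as from [default_demography()].
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(region_length_bp = 5e5, n_eur = 50, n_afr = 50,
#'                   n_founders_per_pop = 10, n_admixed = 20, seed = 1)
sim_config <- function(region_length_bp = 63e6,
                       mutation_rate = 2e-8,
                       recombination_rate = 1e-8,
                       recombination_map = NULL,
                       n_eur = 200000,
                       n_afr = 200000,
                       n_founders_per_pop = 1000,
                       n_admixed = 5000,
                       admix_generations = 8,
                       seed = 1,
                       demographic_params = default_demography()) {
  stopifnot(
    region_length_bp >= 1, mutation_rate > 0, recombination_rate > 0,
    n_eur >= 1, n_afr >= 1, n_founders_per_pop >= 0, n_admixed >= 1,
    admix_generations >= 1, is.numeric(seed), length(seed) == 1
  )
  if (!is.null(recombination_map)) {
    stopifnot(is.data.frame(recombination_map),
              all(c("left", "rate") %in% names(recombination_map)),
              recombination_map$left[1] == 0,
              !is.unsorted(recombination_map$left, strictly = TRUE),
              all(recombination_map$rate >= 0))
  }
  needed <- names(default_demography())
  missing <- setdiff(needed, names(demographic_params))
  if (length(missing))
    stop("demographic_params missing: ", paste(missing, collapse = ", "))
  structure(
    list(region_length_bp = as.double(region_length_bp),
         mutation_rate = mutation_rate,
         recombination_rate = recombination_rate,
         recombination_map = recombination_map,
         n_eur = as.integer(n_eur), n_afr = as.integer(n_afr),
         n_founders_per_pop = as.integer(n_founders_per_pop),
         n_admixed = as.integer(n_admixed),
         admix_generations = as.integer(admix_generations),
         seed = as.integer(seed),
         demographic_params = demographic_params),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%.3g Mb region, mu=%.3g, r=%.3g", x$region_length_bp / 1e6,
              x$mutation_rate, x$recombination_rate), "\n")
  cat(sprintf("  EUR %d + AFR %d diploids (+%d founders/pop), %d admixed, %d admix generations, seed %d\n",
              x$n_eur, x$n_afr, x$n_founders_per_pop, x$n_admixed,
              x$admix_generations, x$seed))
  invisible(x)
}
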