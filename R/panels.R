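# Haplotype panels: phased biallelic haplotypes for one population.

#' Construct a haplotype panel
#'
#' Phased biallelic haplotypes for one population. Alleles are coded 0
#' (ancestral / REF) and 1 (derived / ALT) and stored as a raw matrix with
#' haplotypes in rows and variants in columns (two consecutive rows per
#' diploid individual). Positions are 0-based base-pair coordinates,
#' strictly increasing.
#'
#' @param positions integer vector of 0-based physical positions.
#' @param haplotypes raw or integer matrix, haplotypes x variants,
#'   values in {0,1}; an even number of rows.
#' @param population one of "EUR", "AFR", "ADMIXED".
#' @param individual_ids optional character ids, one per diploid.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(positions, haplotypes,
                            population = c("EUR", "AFR", "ADMIXED"),
                            individual_ids = NULL) {
  population <- match.arg(population)
  if (is.numeric(haplotypes)) {
    stopifnot(all(haplotypes %in% c(0, 1)))
    storage.mode(haplotypes) <- "integer"
    hap <- haplotypes
    storage.mode(hap) <- "raw"
  } else {
    stopifnot(is.raw(haplotypes), is.matrix(haplotypes))
    hap <- haplotypes
  }
  stopifnot(ncol(hap) == length(positions),
            nrow(hap) %% 2L == 0L,
            !is.unsorted(positions, strictly = TRUE))
  n_ind <- nrow(hap) / 2L
  if (is.null(individual_ids))
    individual_ids <- sprintf("%s_%d", tolower(population), seq_len(n_ind))
  stopifnot(length(individual_ids) == n_ind, !anyDuplicated(individual_ids))
  structure(
    list(positions = as.integer(positions), haplotypes = hap,
         population = population, individual_ids = individual_ids),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %s, %d diploid individuals, %d variants, [%d, %d] bp\n",
              x$population, n_individuals(x), length(x$positions),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Number of diploid individuals in a panel
#' @param panel a `haplotype_panel`.
#' @export
n_individuals <- function(panel) nrow(panel$haplotypes) %/% 2L

#' Extract an integer haplotype sub-matrix
#' @noRd
hap_int <- function(panel, haps = NULL, sites = NULL) {
  m <- panel$haplotypes[haps %||% seq_len(nrow(panel$haplotypes)),
                        sites %||% seq_along(panel$positions), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Genotype dosages (counts of the ALT allele)
#'
#' @param panel a `haplotype_panel`.
#' @param individuals optional integer indices of diploids (default all).
#' @param sites optional integer indices of variants (default all).
#' @return integer matrix, individuals x variants, values in {0,1,2}.
#' @export
genotype_dosage <- function(panel, individuals = NULL, sites = NULL) {
  individuals <- individuals %||% seq_len(n_individuals(panel))
  h1 <- hap_int(panel, 2L * individuals - 1L, sites)
  h2 <- hap_int(panel, 2L * individuals, sites)
  d <- h1 + h2
  rownames(d) <- panel$individual_ids[individuals]
  d
}

#' ALT allele frequency per variant
#'
#' @inheritParams genotype_dosage
#' @return numeric vector of ALT allele frequencies.
#' @export
alt_freq <- function(panel, individuals = NULL, sites = NULL) {
  haps <- NULL
  if (!is.null(individuals))
    haps <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  h <- hap_int(panel, haps, sites)
  colMeans(h)
}

#' Minor allele frequency per variant
#' @inheritParams genotype_dosage
#' @return numeric vector of MAFs in `[0, 0.5]`.
#' @export
panel_maf <- function(panel, individuals = NULL, sites = NULL) {
  f <- alt_freq(panel, individuals, sites)
  pmin(f, 1 - f)
}

#' Subset a panel to a set of individuals
#' @param panel a `haplotype_panel`.
#' @param individuals integer indices of diploids to keep.
#' @export
subset_panel <- function(panel, individuals) {
  stopifnot(all(individuals >= 1), all(individuals <= n_individuals(panel)))
  haps <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  haplotype_panel(panel$positions,
                  panel$haplotypes[haps, , drop = FALSE],
                  panel$population,
                  panel$individual_ids[individuals])
}

#' Stack two panels over the same variant coordinate space
#'
#' Used to build the combined LD reference for meta-analysis clumping.
#' The result carries the population label of `a`.
#' @param a,b `haplotype_panel`s over identical positions.
#' @export
combine_panels <- function(a, b) {
  if (!identical(a$positions, b$positions))
    stop("panels do not share the same variant coordinate space")
  haplotype_panel(a$positions, rbind(a$haplotypes, b$haplotypes),
                  a$population,
                  make.unique(c(a$individual_ids, b$individual_ids)))
}
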