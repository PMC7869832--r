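# Shared fixtures: one small coalescent simulation reused across files
# (memoized so the bridge runs once per test session), plus hand-built
# synthetic panels for exact-arithmetic tests.

.sim_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 11) {
  sim_config(region_length_bp = 1e6, n_eur = 300, n_afr = 300,
             n_founders_per_pop = 40, n_admixed = 60, seed = seed)
}

small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- small_sim_config()
    pops <- simulate_source_populations(cfg)
    adm <- simulate_admixture(pops$founders_eur, pops$founders_afr, cfg)
    .sim_cache$small <- list(cfg = cfg, pops = pops, adm = adm)
  }
  .sim_cache$small
}

# Panel with explicitly chosen haplotypes (individuals x variants given
# as dosage-style 0/1 haplotype rows).
toy_panel <- function(hap_matrix, positions = NULL,
                      population = "EUR") {
  if (is.null(positions)) positions <- seq_len(ncol(hap_matrix)) * 1000L
  haplotype_panel(positions, hap_matrix, population)
}

# Panel of independent Bernoulli haplotypes (no LD), used for null
# calibration tests.
random_panel <- function(n_ind, n_var, freq_range = c(0.05, 0.5),
                         seed = 1, population = "EUR") {
  set.seed(seed)
  f <- runif(n_var, freq_range[1], freq_range[2])
  hap <- matrix(rbinom(2L * n_ind * n_var, 1L, rep(f, each = 2L * n_ind)),
                nrow = 2L * n_ind)
  haplotype_panel(sort(sample.int(n_var * 1000L, n_var)), hap, population)
}

# Exhaustive reference for clumping: greedy by p, re-checking every
# pairwise (window, r2) exclusion against the full LD matrix.
clump_oracle <- function(assoc, reference_panel, p_threshold,
                         r2_threshold = 0.2, window_bp = 1e6) {
  pass <- assoc[assoc$p < p_threshold, , drop = FALSE]
  if (nrow(pass) == 0) return(integer(0))
  dos <- genotype_dosage(reference_panel, sites = pass$site_index)
  v <- apply(dos, 2, var)
  pass <- pass[v > 0, , drop = FALSE]
  dos <- dos[, v > 0, drop = FALSE]
  ord <- order(pass$p, -pass$chisq, pass$site_index)
  selected <- integer(0)
  removed <- rep(FALSE, nrow(pass))
  for (i in ord) {
    if (removed[i]) next
    selected <- c(selected, i)
    for (j in ord) {
      if (removed[j] || j == i) next
      if (abs(pass$pos[j] - pass$pos[i]) <= window_bp &&
          cor(dos[, i], dos[, j])^2 >= r2_threshold)
        removed[j] <- TRUE
    }
    removed[i] <- TRUE
  }
  sort(pass$site_index[selected])
}

# Minimal hand-built association results for meta-analysis tests.
fake_assoc <- function(log_or, se, pos = seq_along(log_or) * 1000L,
                       effect_allele = "ALT", maf = 0.3, alt_freq = maf,
                       population = "EUR", n_cases = 100, n_controls = 100) {
  df <- data.frame(
    variant_id = sprintf("v%d", pos), pos = pos,
    site_index = seq_along(pos), effect_allele = effect_allele,
    maf = maf, alt_freq = alt_freq,
    or = exp(log_or), log_or = log_or, se = se,
    chisq = (log_or / se)^2,
    p = 2 * pnorm(-abs(log_or / se)), zero_cell = FALSE)
  structure(df, population = population, n_cases = n_cases,
            n_controls = n_controls,
            class = c("assoc_result", "data.frame"))
}

make_arch <- function(causal_indices, betas, h2 = 0.5) {
  structure(list(m = length(causal_indices), h2 = h2,
                 causal_indices = as.integer(causal_indices),
                 betas = betas),
            class = "trait_architecture")
}
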