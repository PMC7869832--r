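---
title: "Simulating PRS transferability across ancestries: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating PRS transferability across ancestries: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Polygenic risk scores (PRSs) built from European-ancestry GWASs lose
accuracy when applied to African-ancestry or admixed individuals, even
when causal variants and their effects are fully shared. `admixprs`
provides a seeded, end-to-end simulation pipeline that isolates the two
drivers of that loss — population differences in allele frequency and in
linkage disequilibrium (LD) tagging — and quantifies how variant
selection and weighting strategies change accuracy as a function of
global genetic ancestry.

# Genotype simulation

Haplotypes for a European-like (EUR) and an African-like (AFR)
population are drawn from a coalescent model through a bundled msprime
bridge script (`inst/python/coalescent_sim.py`), using a two-population
collapse of the classic out-of-Africa demographic parameterization of
Gravel and colleagues (2011): an ancestral African population of 7,310
diploids expanding to 14,474 about 5,920 generations ago; an
out-of-Africa bottleneck of 1,861 at the split 2,040 generations ago;
and exponential European growth at 0.38% per generation from size 1,032
starting 920 generations ago, with symmetric migration (1.5e-4 during
the bottleneck epoch, 2.5e-5 afterwards). The East Asian branch of the
original three-population model plays no role here and is dropped. All
parameters live in `default_demography()` and can be overridden through
`sim_config()`.

The mutation rate defaults to 2e-8 per bp per generation. The
recombination rate is a free choice of the design; we default to a
uniform 1e-8 per bp per generation (about 1 cM/Mb, the genome-wide
human average), with an optional piecewise-constant map accepted by
`sim_config(recombination_map=)`. Sites carrying more than one mutation
(multi-allelic or recurrent) are dropped and counted, so every retained
site is strictly biallelic with alleles coded 0/1; both populations
share one variant coordinate space (the union of segregating sites of
the joint simulation).

Two access modes exist. `simulate_source_populations()` materializes
phased haplotype panels (raw-byte matrices, haplotypes x variants) and
is used by the pipeline. `site_frequency_summary()` returns per-site
derived-allele counts per population without ever forming a genotype
matrix (counts are accumulated on the marginal trees), which is how
full-scale quantities such as the causal rare-variant fraction are
computed at 200,000 diploids per population on a desk machine.

# Admixture with exact local ancestry

`simulate_admixture()` builds each admixed haplotype by explicit
meiosis down a pedigree of `admix_generations` (default 8) generations:
crossovers are a Poisson process with one expected event per Morgan per
meiosis (no interference), and every copied segment records which
founder haplotype — and therefore which ancestry — it came from. Tracts
are truth by construction; no ancestry inference is performed anywhere.

Eight generations of random mating from a balanced founder pool would
concentrate global European ancestry (rho_EUR) near 0.5 and could never
populate the 0-100% ancestry range the analyses stratify over. Each
admixed individual therefore draws theta_i ~ Uniform(0,1) once, and
each of its pedigree founders is European with probability theta_i.
This is a modeling device to realize the full ancestry spectrum, not a
claim about any particular admixed population's history.

Global ancestry is defined from the tracts: rho_EUR equals the
EUR-ancestry base pairs divided by total base pairs across both
haplotypes (`compute_global_ancestry()`), and the closed-form check
used in the tests is that a single admixture pulse g generations ago
yields about `(g-1) * 2*theta*(1-theta)` ancestry switches per Morgan
per haplotype.

A consequence of simulating one region rather than a genome is that
rho_EUR is granular: on a 2 Mb region (0.02 Morgan) a haplotype almost
always descends from a single founder lineage, so rho concentrates near
{0, 0.5, 1} and intermediate ancestry deciles are sparsely populated.
At the full 63 Mb scale the spectrum fills in. This granularity is why
`decile_r2()` requires at least 20 individuals per decile (below) and
why desk-scale stratum contrasts are read as medians over replicates.

# Trait model and ascertainment

`build_architecture()` places m causal variants (default 1,000) at
evenly spaced *ranks* of the ordered variant list — not evenly spaced
base pairs — so exactly m variants are causal regardless of local
variant density, and draws effects beta ~ N(0, h2/m) (default
h2 = 0.5). The identical architecture applies to every population:
heritability is constant and effect sizes are completely shared, so any
accuracy loss is attributable to frequency and LD differences alone.

`compute_liability()` forms the raw score X = sum(beta_i * g_i),
standardizes it to the genetic liability G = scale(X) * sqrt(h2), and
adds an environmental component E = scale(eps) * sqrt(1-h2) with
eps ~ N(0, 1-h2); the total liability is G + E. Standardization is
within each population sample and uses the sample (n-1) denominator —
the same convention as R's `var` — so `var(G) == h2` and
`var(E) == 1 - h2` hold exactly on every run. Because causal variants
span the whole frequency spectrum, most are rare (MAF < 1%) in both
populations; that fact, recomputed at full scale, is the package's
headline acceptance quantity.

`ascertain_samples()` implements liability-threshold case-control
sampling at 5% prevalence: cases are the top of the liability
distribution within the prevalence tail (ties broken by individual
index for determinism), controls and test samples are uniform draws
from the remainder, and the three sets are disjoint.

# GWAS and meta-analysis

`association_scan()` performs the allele-count test: for each variant
with study-sample MAF strictly above 1%, the 2x2 case/control x
effect/other allele table gives OR = ad/bc, SE(log OR) =
sqrt(1/a+1/b+1/c+1/d), and a 1-df chi-square without continuity
correction. There are no covariates in the simulation, so an
allele-count test is equivalent in spirit to the logistic fit real
pipelines use and is orders of magnitude faster. The effect allele is
recorded explicitly as the study-sample minor allele, which makes
cross-population weight transfer unambiguous. Zero cells receive the
Haldane-Anscombe +0.5 correction for the OR and SE only — the test
statistic is untouched — and are flagged.

`meta_analyze()` combines two scans over their shared variants by
fixed-effects inverse-variance weighting on the ALT-allele scale,
reporting Cochran's Q, I^2, and the conventional heterogeneity flag
(I^2 > 25% and Q p < 0.05). Variants tested in only one study are
excluded and counted.

# PRS construction

`clump_and_threshold()` selects variants by p < 0.01 (main grid; 1e-4
and 1e-6 also supported) and greedy LD clumping at r^2 < 0.2 within a
1 Mb window, with LD computed in the GWAS's own training genotypes (for
meta-analysis selection, both training sets stacked). Ties in p are
broken by larger chi-square, then lower variant index, so selection is
deterministic. The greedy output is verified in the tests against an
exhaustive oracle that re-checks every pairwise exclusion.

Scoring (`score_prs()`) is the weighted effect-allele dosage sum;
weights are log(OR). `reweight_model()` keeps a selected variant set
but swaps in another study's effects (sign-aligned through the recorded
effect alleles); variants the weighting study never tested — typically
because they are rare there — contribute zero and are counted. This is
the mechanism behind the variant-source x weight-source strategy grid.

`score_local_ancestry_prs()` implements local-ancestry weighting: each
haplotype allele takes the European or African weight according to the
true ancestry of the tract covering that position on that haplotype
(a variant on a tract boundary belongs to the left-closed tract, per
the 0-based half-open convention), and the two partial sums are
combined as rho * EUR-part + (1-rho) * AFR-part. Assignment is per
haplotype allele rather than per diploid genotype because only the
former is well defined at heterozygous-ancestry sites. For an
unadmixed individual the score reduces exactly to the single-population
score, which the tests assert.

`fit_mixture_prs()` fits the two-PRS linear mixture
alpha1 * PRS_EUR + alpha2 * PRS_AFR (+ intercept) by least squares in a
fitting cohort — in the pipeline, the independent African test cohort —
and supports k-fold (optionally stratified) cross-validation. An
intercept is included: it absorbs the arbitrary location of PRS sums
and leaves the correlation-based accuracy metrics untouched. The
default fitting target is the total trait liability, the observable
phenotype analogue; fitting against the true genetic liability is
available for diagnostics.

# Evaluation

Accuracy is Pearson's r between the true genetic liability G and the
PRS. Replicate values are aggregated on the Fisher z scale
(`accuracy_summary()`), with normal-theory 95% CIs of the mean z and
back-transformation by tanh; r at exactly +/-1 is clipped to
1 - 1e-12 with a warning (it only arises in degenerate inputs).
Strategy comparisons use the z-test
(atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), summarized across
replicates by the median p. For admixed strata the n entering the test
is the stratum size, not the full test-set size.

Admixed individuals are stratified by rho_EUR into high (> 0.8),
intermediate (0.2, 0.8], and low (0, 0.2] European ancestry; the
published bounds are open intervals, so interior edges are assigned
downward (0.8 is intermediate, 0.2 is low) and individuals with rho
exactly 0 or 1 belong to no stratum — they are unadmixed, genomically
indistinguishable from the source populations, and appear only in the
whole-cohort admixed metrics and the decile binning (which by design
covers all of [0, 1]). At desk scale such individuals are common
because of the ancestry granularity discussed above, which is also why
the desk profile simulates a large admixed cohort: the open-interval
strata need tens of members each. The ancestry-accuracy slope regresses per-decile
variance explained of the total liability (as a percentage) on the
decile midpoint and is reported per 10% of European ancestry; deciles
with fewer than 20 individuals are dropped (at least 3 populated
deciles are required) because a squared correlation over a handful of
individuals is noise that would otherwise dominate the fit.

`causal_tagging_summary()` reproduces the tagging diagnostics: per PRS
variant, the maximum r^2 to any causal variant within +/-1,000 kb in
each population (self-pairs count, with r^2 = 1); per causal variant,
the LD score (sum of r^2 over PRS variants in the window) and its
PRS-size-normalized version; and the cross-population correlation of
LD scores. Causal variants monomorphic in a panel contribute r^2 = 0
there. `maf_spectrum_table()` bins selected variants by MAF in each
population with an explicit < 1% bin.

# Pipeline, seeding, and scale

`run_replicate()` executes the whole chain for one replicate —
simulate, admix, phenotype, ascertain, EUR and AFR GWASs (the AFR GWAS
optionally down-sampled to 1-100% of its cases and controls, each
fraction a genuinely smaller GWAS that is re-estimated, re-meta-analyzed
and re-clumped), the twelve variant-source x weight-source strategies,
the mixture PRS, and the evaluation tables. Replicate seeds derive from
`derive_seed(master_seed, replicate_id)`, a documented 31-bit
multiplicative hash, so any subset of replicates can be re-run
bit-identically; `aggregate_replicates()` is invariant to replicate
order.

Two problem sizes are used in this package's own runs. The full-scale
configuration (the `experiment_config()` default) mirrors the study
design: 63 Mb region, 200,000 diploids per source population, 1,000
founders per population, 5,000 admixed individuals, 10,000 cases and
10,000 controls, 5,000 test samples per population, 50 replicates. The
desk profile used by the test suite is 2 Mb and 10,000 diploids per
GWAS population (500 cases — the entire 5% prevalence tail — 500
controls, 500 test per population, 2,000 admixed, 10 replicates), chosen
so one replicate runs in well under a minute: with roughly 1,500
independent common variants on 2 Mb and 1,000 study individuals, the
expected PRS accuracy in the training ancestry is around r = 0.5-0.7,
which leaves clear signal for the stratum ordering while remaining far
from the full-scale operating point. The full-scale causal
rare-variant fraction is computed exactly (counts mode) at 200,000
diploids per population on a 20 Mb region: the quantity is a property
of the site-frequency spectrum, so it depends on sample size and
demography but not on region length.

# What the generator does and does not emulate

The simulation captures out-of-Africa demography (bottleneck, drift,
growth), recombination-driven LD decay, admixture with exact local
ancestry, liability-threshold ascertainment, and Winner's-curse-free
effect sharing. It does not emulate: genotyping arrays or imputation
(every segregating site is observed), genotyping error, a non-uniform
recombination map (unless supplied), assortative mating (admixture is
random mating, which shortens no tract systematically), sex
chromosomes, population-specific causal effects, or gene-environment
interaction. Passing desk-scale tests therefore demonstrates the
mechanisms — frequency and LD-driven transferability loss and its
mitigation by diverse discovery — not calibrated real-data effect
sizes. Desk-scale accuracies are lower than full-scale ones simply
because the GWASs are smaller; orderings, spreads, and slopes are the
meaningful quantities. Two patterns sit near their boundary at desk
power. The fraction of European-selected variants that are rare in the
African population rises with GWAS power (selection increasingly
favors European-drifted common variants) and clears one half only
around the 500-case operating point. And the contrast between the
low-European-ancestry stratum and the African cohort is the least
stable quantity in the whole design: the open-interval low stratum
holds only a few dozen individuals per desk replicate, and the
within-stratum ancestry variance adds allele-frequency-drift noise to
a European-derived PRS that, at desk GWAS power, is of the same order
as the tagging gain from partial European ancestry — so the full-scale
ordering of that single pair is not reliably reproduced at this scale,
and the corresponding acceptance check documents exactly that.

# Numerical choices

- Sample-variance (n-1) convention everywhere, making the liability
  variance identities exact as asserted.
- Liability ties at the case threshold break by individual index;
  clumping ties break by chi-square then variant index: all stages are
  deterministic given the seed.
- Fisher z singularity handled by clipping |r| to 1 - 1e-12 with a
  warning.
- Zero 2x2 cells: Haldane-Anscombe +0.5 for OR/SE only, flagged.
- Monomorphic variants: excluded from GWAS by the MAF filter, dropped
  from clumping with a warning if a reference panel renders a variant
  monomorphic, contribute r^2 = 0 to tagging, and fail fast in
  `ld_r2()`.
- Empty selections propagate as empty models and empty report rows,
  never as errors.
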