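# Plain-text interchange: VCF panels, BED-like tracts, TSV tables.

#' Write a haplotype panel as a phased VCF
#'
#' One contig, 1-based positions (internal 0-based coordinates + 1),
#' REF "A" / ALT "T" placeholder alleles, phased GT per diploid.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @param chrom contig name (default "chr20").
#' @export
write_panel_vcf <- function(panel, path, chrom = "chr20") {
  n <- n_individuals(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    sprintf("##source=admixprs;population=%s", panel$population),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individual_ids), collapse = "\t")), con)
  h <- hap_int(panel)
  gt <- matrix(paste(h[seq(1, nrow(h), 2), , drop = FALSE],
                     h[seq(2, nrow(h), 2), , drop = FALSE], sep = "|"),
               nrow = n)
  lines <- paste(chrom, panel$positions + 1L,
                 sprintf("v%d", panel$positions), "A", "T", ".", "PASS",
                 ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Expects biallelic, fully phased genotypes (as written by
#' [write_panel_vcf()] or any conforming VCF).
#'
#' @param path VCF path.
#' @param population population label for the panel.
#' @export
read_panel_vcf <- function(path, population = "EUR") {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  stopifnot(header[1] == "#CHROM", length(header) > 9)
  ids <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  pos <- vapply(rows, function(r) as.integer(r[2]), integer(1)) - 1L
  gt <- vapply(rows, function(r) r[-(1:9)],
               character(length(ids)))  # ids x sites
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(ids))
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  if (!all(sep == "|")) stop("unphased genotype in ", path)
  a2 <- substr(gt, 3, 3)
  hap <- matrix(0L, nrow = 2 * length(ids), ncol = length(pos))
  hap[seq(1, nrow(hap), 2), ] <- as.integer(a1)
  hap[seq(2, nrow(hap), 2), ] <- as.integer(a2)
  haplotype_panel(pos, hap, population, ids)
}

#' Write ancestry tracts as BED-like text
#'
#' 0-based half-open `haplotype_id, start, end, ancestry` columns (full
#' floating-point precision: recombination breakpoints are continuous),
#' tab separated, with a `track` comment line carrying the region length.
#' @param tracts an `ancestry_tracts`.
#' @param path output path.
#' @export
write_tracts_bed <- function(tracts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#region_length=%.17g", attr(tracts, "region_length")), con)
  utils::write.table(
    data.frame(tracts$haplotype_id, sprintf("%.17g", tracts$start),
               sprintf("%.17g", tracts$end), tracts$ancestry,
               tracts$individual_id),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ancestry tracts written by [write_tracts_bed()]
#' @param path input path.
#' @export
read_tracts_bed <- function(path) {
  first <- readLines(path, n = 1)
  stopifnot(startsWith(first, "#region_length="))
  region <- as.double(sub("#region_length=", "", first))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("haplotype_id", "start", "end",
                                        "ancestry", "individual_id"))
  ancestry_tracts(df[, c("haplotype_id", "individual_id", "start", "end",
                         "ancestry")], region)
}

#' Write PRS model weights as TSV
#' @param model a `prs_model`.
#' @param path output path.
#' @export
write_weights_tsv <- function(model, path) {
  v <- model$variants
  utils::write.table(
    data.frame(variant_id = v$variant_id, pos = v$pos,
               effect_allele = v$effect_allele, weight = v$weight,
               p = v$p, variant_source = model$variant_source,
               weight_source = model$weight_source),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-individual scores as TSV
#' @param scores named numeric vector as returned by [score_prs()].
#' @param path output path.
#' @export
write_scores_tsv <- function(scores, path) {
  n_missing <- attr(scores, "n_missing") %||% rep(0L, length(scores))
  utils::write.table(
    data.frame(individual_id = names(scores), score = as.vector(scores),
               n_missing = n_missing),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PRS weight file written by [write_weights_tsv()]
#'
#' Accepts any TSV with columns `variant_id`, `pos`, `effect_allele`,
#' `weight` (and optionally `p`, `variant_source`, `weight_source`), so
#' externally prepared weight files can be scored with [score_prs()].
#'
#' @param path input path.
#' @return a `prs_model`.
#' @export
read_weights_tsv <- function(path) {
  tab <- utils::read.delim(path)
  needed <- c("variant_id", "pos", "effect_allele", "weight")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("weight file lacks column(s): ", paste(missing, collapse = ", "))
  v <- data.frame(variant_id = as.character(tab$variant_id),
                  pos = as.integer(tab$pos),
                  site_index = NA_integer_,
                  effect_allele = as.character(tab$effect_allele),
                  weight = as.numeric(tab$weight),
                  p = if ("p" %in% names(tab)) tab$p else NA_real_)
  new_prs_model(v, unique(tab$variant_source %||% "external")[1],
                list(),
                weight_source = unique(tab$weight_source %||% "external")[1])
}

#' Write a trait architecture as TSV
#' @param arch a `trait_architecture`.
#' @param path output path.
#' @export
write_architecture_tsv <- function(arch, path) {
  utils::write.table(
    data.frame(causal_index = arch$causal_indices, beta = arch$betas,
               m = arch$m, h2 = arch$h2),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a liability table as TSV
#' @param liability a `liability_table`.
#' @param path output path.
#' @export
write_liability_tsv <- function(liability, path) {
  utils::write.table(as.data.frame(liability), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
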