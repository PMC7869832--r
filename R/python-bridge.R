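# Bridge to the bundled msprime simulation script.

find_python <- function() {
  py <- Sys.getenv("ADMIXPRS_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py))
    stop("no python interpreter found; set ADMIXPRS_PYTHON or put python on PATH")
  py
}

bridge_script <- function() {
  p <- system.file("python", "coalescent_sim.py", package = "admixprs")
  if (!nzchar(p)) stop("bundled coalescent_sim.py not found")
  p
}

#' Run the coalescent bridge and read its binary outputs
#'
#' @param config a `sim_config`.
#' @param mode "panel" (full haplotypes) or "counts" (per-site
#'   derived-allele counts per population).
#' @return list with positions, meta, and either `haplotypes` (raw matrix,
#'   haplotypes x sites) or `ac_eur`/`ac_afr` count vectors.
#' @noRd
run_coalescent <- function(config, mode = c("panel", "counts")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  out_dir <- tempfile("admixprs_sim_")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)

  cfg <- config
  cfg$mode <- mode
  if (!is.null(cfg$recombination_map))
    cfg$recombination_map <- as.list(cfg$recombination_map)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], cfg_path,
                       auto_unbox = TRUE, digits = NA)

  res <- suppressWarnings(system2(
    find_python(), c(bridge_script(), cfg_path, out_dir),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0) {
    msg <- paste(res, collapse = "\n")
    if (status == 3L)
      stop("coalescent simulation produced no biallelic segregating site: ", msg)
    stop("coalescent simulation failed (exit ", status, "): ", msg)
  }

  meta <- jsonlite::read_json(file.path(out_dir, "meta.json"),
                              simplifyVector = TRUE)
  S <- meta$n_sites
  positions <- readBin(file.path(out_dir, "positions.bin"), "integer",
                       n = S, size = 4L, endian = "little")
  out <- list(meta = meta, positions = positions)
  if (mode == "panel") {
    H <- meta$n_haplotypes
    raw <- readBin(file.path(out_dir, "haplotypes.bin"), "raw", n = S * H)
    stopifnot(length(raw) == S * H)
    dim(raw) <- c(H, S) # site-major bytes -> haplotypes in rows
    out$haplotypes <- raw
  } else {
    out$ac_eur <- readBin(file.path(out_dir, "counts_eur.bin"), "integer",
                          n = S, size = 4L, endian = "little")
    out$ac_afr <- readBin(file.path(out_dir, "counts_afr.bin"), "integer",
                          n = S, size = 4L, endian = "little")
  }
  out
}
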