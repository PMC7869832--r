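# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not
#' perturb the caller's RNG stream. A `NULL` seed leaves the stream alone.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit mixing of (master seed, stream id) so that each
#' pipeline stage and replicate gets its own reproducible stream. Uses a
#' fixed multiplicative hash (documented, stable across platforms);
#' results stay strictly below 2^31.
#'
#' @param master integer master seed.
#' @param stream integer stream / replicate identifier.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(master) %% m)
  x <- (x * 48271) %% m
  x <- (x + as.double(stream) * 69621 + 1) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1) + 1)
}

# Clip correlations away from +/-1 before atanh (Fisher z singularity).
clip_r <- function(r, tol = 1e-12) {
  out_of_range <- abs(r) >= 1
  if (any(out_of_range, na.rm = TRUE)) {
    warning("correlation at +/-1 clipped before Fisher transformation")
    r <- pmin(pmax(r, -1 + tol), 1 - tol)
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
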