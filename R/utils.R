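#' @keywords internal
"_PACKAGE"

## Seed plumbing ---------------------------------------------------------
##
## Every stochastic operation in the package is a pure function of an
## integer seed. A master seed fans out to per-stage child seeds through a
## counter-based LCG step so stages can be re-run independently without
## sharing RNG state.

#' Derive a child seed from a master seed and a counter
#'
#' Deterministic fan-out of one master seed into independent per-stage
#' seeds. Uses a Lehmer step modulo 2^31 - 1 so derived seeds stay valid
#' 32-bit R integers.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer distinguishing the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1)
#' child_seed(42, 2)
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  for (k in seq_len(length(counter))) {
    x <- (x * 48271 + as.numeric(counter[k]) + 1) %% m
  }
  as.integer(max(1, x))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Small numeric helpers -------------------------------------------------

#' Full width at half maximum to Gaussian sigma
#' @param fwhm full width at half maximum (same units as the result).
#' @return standard deviation of the equivalent Gaussian.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## shift a 3D array by an integer offset, padding with `fill`
shift_array <- function(a, off, fill = NA) {
  d <- dim(a)
  src <- lapply(1:3, function(k) {
    idx <- seq_len(d[k]) - off[k]
    idx[idx < 1 | idx > d[k]] <- NA
    idx
  })
  out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  ## NA indices yield NA cells; fill them (only call with fill != NA on
  ## NA-free inputs).
  if (!is.na(fill)) out[is.na(out)] <- fill
  out
}

## The 13 unique lattice direction vectors of 26-connectivity (opposite
## directions collapsed).
unique_directions_26 <- function() {
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dirs <- dirs[!(dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] == 0), , drop = FALSE]
  keep <- apply(dirs, 1, function(v) {
    nz <- v[v != 0]
    nz[length(nz)] > 0  # canonical: last nonzero component positive
  })
  dirs[keep, , drop = FALSE]
}

## All 26 neighbour offsets.
all_directions_26 <- function() {
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dirs[!(dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] == 0), , drop = FALSE]
}
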