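## Gray-level discretization ---------------------------------------------

#' Discretize masked intensities into a fixed number of gray levels
#'
#' Fixed-bin-count mapping of the within-mask `[min, max]` intensity range
#' onto levels `1..n_levels`: the minimum maps to 1, the maximum to
#' `n_levels`, monotonically in between. Voxels outside the mask are NA.
#' A constant region collapses onto level 1 and is flagged degenerate.
#'
#' @param image an `activity_volume` (or bare 3D array).
#' @param mask logical 3D array, nonempty.
#' @param n_levels number of gray levels (64 for the study pipeline).
#' @return object of class `discretized_volume`: list with `levels`
#'   (integer array, NA outside mask), `mask`, `n_levels`,
#'   `original_range`, `degenerate`.
#' @export
discretize <- function(image, mask, n_levels = 64L) {
  vals <- if (inherits(image, "activity_volume")) image$values else image
  if (!identical(dim(vals), dim(mask))) stop("mask and image dimensions differ")
  if (!any(mask)) stop("empty mask")
  x <- vals[mask]
  mn <- min(x); mx <- max(x)
  lev <- array(NA_integer_, dim(vals))
  degenerate <- (mx - mn) <= 0
  if (degenerate) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(n_levels, as.integer(floor(n_levels * (x - mn) / (mx - mn))) + 1L)
  }
  structure(list(levels = lev, mask = mask, n_levels = as.integer(n_levels),
                 original_range = c(mn, mx), degenerate = degenerate),
            class = "discretized_volume")
}
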