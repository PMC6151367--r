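## First-order histogram features (IF_HIST) ------------------------------

#' First-order histogram features
#'
#' Thirteen first-order statistics of the within-mask intensity
#' distribution. Moments (mean, variance, skewness, kurtosis, ...) are
#' computed on the raw intensities with population normalization (divide
#' by n); Entropy and Uniformity are computed on the discretized
#' gray-level histogram (probabilities summing to 1, entropy in bits).
#' Kurtosis is the Pearson form (3 for a Gaussian). Constant regions
#' yield the documented sentinels: Skewness = Kurtosis = 0, Entropy = 0,
#' Uniformity = 1.
#'
#' @param image an `activity_volume` (or 3D array).
#' @param mask logical 3D array.
#' @param disc optional [discretize()] result reused for
#'   Entropy/Uniformity (recomputed at 64 levels when NULL).
#' @return named numeric of length 13 with attribute `degenerate`.
#' @export
histogram_features <- function(image, mask, disc = NULL) {
  vals <- if (inherits(image, "activity_volume")) image$values else image
  if (!any(mask)) stop("empty mask")
  x <- vals[mask]
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n          # population variance
  s <- sqrt(v)
  degenerate <- s <= 0
  skew <- if (degenerate) 0 else sum((x - m)^3) / n / s^3
  kurt <- if (degenerate) 0 else sum((x - m)^4) / n / s^4
  if (is.null(disc)) disc <- discretize(vals, mask)
  p <- tabulate(disc$levels[mask], nbins = disc$n_levels) / n
  p_pos <- p[p > 0]
  entropy <- -sum(p_pos * log2(p_pos))
  uniformity <- sum(p_pos^2)
  out <- c(
    "Maximum" = max(x), "Minimum" = min(x), "Mean" = m,
    "Median" = stats::median(x),
    "Mean absolute deviation (MAD)" = mean(abs(x - m)),
    "Root mean square (RMS)" = sqrt(mean(x^2)),
    "Energy" = sum(x^2), "Entropy" = entropy,
    "Kurtosis" = kurt, "Skewness" = skew,
    "Standard deviation" = s, "Uniformity" = uniformity, "Variance" = v)
  attr(out, "degenerate") <- degenerate
  out
}
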