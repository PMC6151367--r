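## Gray-level co-occurrence matrix features (IF_TX-GLCM) -----------------

#' Gray-level co-occurrence matrix
#'
#' Distance-1 co-occurrences accumulated over the 13 unique direction
#' vectors of 26-connectivity (pairs with both voxels inside the mask),
#' symmetrized and normalized to a probability matrix. Merging the
#' directional matrices (rather than averaging per-direction features) is
#' the package's convention; `per_direction = TRUE` returns the 13
#' unmerged count matrices instead.
#'
#' @param disc a [discretize()] result.
#' @param per_direction return a list of per-direction count matrices.
#' @return `n_levels x n_levels` probability matrix (or list of count
#'   matrices).
#' @export
glcm_matrix <- function(disc, per_direction = FALSE) {
  L <- disc$levels
  n <- disc$n_levels
  dirs <- unique_directions_26()
  mats <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    Lp <- shift_array(L, dirs[r, ])          # Lp[v] = L[v - d]
    ok <- !is.na(L) & !is.na(Lp)
    C <- matrix(0, n, n)
    if (any(ok)) {
      enc <- (L[ok] - 1L) * n + Lp[ok]       # column-major cell id
      cnt <- tabulate(enc, nbins = n * n)
      C <- matrix(cnt, n, n, byrow = TRUE)   # row = L[v], col = L[v-d]
    }
    mats[[r]] <- C
  }
  if (per_direction) return(mats)
  Csum <- Reduce(`+`, mats)
  P <- Csum + t(Csum)                        # symmetrize
  tot <- sum(P)
  if (tot == 0) return(P)
  P / tot
}

glcm_features_from_matrix <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(n) * px)                 # symmetric: mu_x = mu_y
  sig2 <- sum((seq_len(n) - mu)^2 * px)
  pp <- P[P > 0]
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  ## sum average via the diagonal-sum marginal p_{x+y}
  k <- i + j
  sum_avg <- sum(k * P)
  c("Energy" = sum(P^2),
    "Contrast" = sum((i - j)^2 * P),
    "Entropy" = -sum(pp * log2(pp)),
    "Homogeneity" = sum(P / (1 + abs(i - j))),
    "Correlation" = corr,
    "SumAverage" = sum_avg,
    "Variance" = sum((i - mu)^2 * P),
    "Dissimilarity" = sum(abs(i - j) * P),
    "Autocorrelation" = sum(i * j * P))
}

#' GLCM texture features
#'
#' Nine co-occurrence statistics (Energy, Contrast, Entropy, Homogeneity,
#' Correlation, SumAverage, Variance, Dissimilarity, Autocorrelation) on
#' the merged symmetric probability matrix. SumAverage is the mean of the
#' `i + j` diagonal marginal (twice the marginal gray-level mean for a
#' symmetric matrix); Variance and Correlation use the marginal mean.
#' A mask without any voxel pair (single voxel) yields the sentinel
#' vector of a one-cell matrix, flagged degenerate.
#'
#' @param disc a [discretize()] result.
#' @return named numeric of length 9 with attribute `degenerate`.
#' @export
glcm_features <- function(disc) {
  P <- glcm_matrix(disc)
  if (sum(P) == 0) {
    ## no pairs: all mass notionally at one cell
    out <- c("Energy" = 1, "Contrast" = 0, "Entropy" = 0, "Homogeneity" = 1,
             "Correlation" = 0, "SumAverage" = 2, "Variance" = 0,
             "Dissimilarity" = 0, "Autocorrelation" = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- glcm_features_from_matrix(P)
  attr(out, "degenerate") <- FALSE
  out
}
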