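## Neighborhood gray tone difference matrix features (IF_TX-NGTDM) -------

#' Neighborhood gray tone difference matrix
#'
#' For every in-mask voxel, the mean gray level of its available
#' 26-neighbours (restricted to the mask) is computed; the matrix column
#' `s_i` accumulates `|i - neighbourhood mean|` over the voxels of level
#' `i`, alongside the level occupancy counts `n_i`. Voxels with no
#' in-mask neighbour are skipped.
#'
#' @param disc a [discretize()] result.
#' @return data.frame with one row per gray level: `level`, `n`, `p`, `s`.
#' @export
ngtdm_matrix <- function(disc) {
  L <- disc$levels
  dirs <- all_directions_26()
  nb_sum <- array(0, dim(L))
  nb_cnt <- array(0, dim(L))
  Lz <- L; Lz[is.na(Lz)] <- 0
  inm <- !is.na(L)
  for (r in seq_len(nrow(dirs))) {
    Lp <- shift_array(Lz, dirs[r, ], fill = 0)
    Ip <- shift_array(array(as.numeric(inm), dim(L)), dirs[r, ], fill = 0)
    nb_sum <- nb_sum + Lp * Ip
    nb_cnt <- nb_cnt + Ip
  }
  use <- inm & nb_cnt > 0
  diffs <- abs(L[use] - nb_sum[use] / nb_cnt[use])
  lev <- L[use]
  n_levels <- disc$n_levels
  s <- as.numeric(tapply(diffs, factor(lev, levels = seq_len(n_levels)), sum))
  s[is.na(s)] <- 0
  n_i <- tabulate(lev, nbins = n_levels)
  N <- sum(n_i)
  data.frame(level = seq_len(n_levels), n = n_i, p = n_i / N, s = s)
}

#' NGTDM texture features
#'
#' The five neighbourhood gray-tone difference statistics (Coarseness,
#' Contrast, Busyness, Complexity, Strength) with epsilon-guarded
#' denominators (eps = 1e-12). A constant region has zero difference
#' sums everywhere: Contrast, Busyness, Complexity and Strength are 0 and
#' Coarseness is capped at the documented maximum 1e6.
#'
#' @param disc a [discretize()] result.
#' @return named numeric of length 5 with attribute `degenerate`.
#' @export
ngtdm_features <- function(disc) {
  eps <- 1e-12
  tab <- ngtdm_matrix(disc)
  present <- tab$p > 0
  N <- sum(tab$n)
  Ng <- sum(present)
  p <- tab$p; s <- tab$s; i <- tab$level
  ps <- sum(p * s)
  coarseness <- min(1 / (ps + eps), 1e6)
  if (Ng > 1) {
    ii <- i[present]; pp <- p[present]
    d2 <- outer(ii, ii, function(a, b) (a - b)^2)
    pipj <- outer(pp, pp)
    contrast <- sum(pipj * d2) / (Ng * (Ng - 1)) * sum(s) / N
    num_bus <- ps
    den_bus <- sum(abs(outer(ii * pp, ii * pp, "-")))
    busyness <- if (den_bus > eps) num_bus / den_bus else 0
    dd <- outer(ii, ii, function(a, b) abs(a - b))
    psum <- outer(pp * s[present], pp * s[present], function(a, b) a + b)
    ## complexity: |i-j| * (p_i s_i + p_j s_j) / (p_i + p_j)
    pden <- outer(pp, pp, "+")
    complexity <- sum(dd * psum / pden) / N
    strength <- sum(outer(pp, pp, "+") * d2) / (sum(s) + eps)
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  out <- c("Coarseness" = coarseness, "Contrast" = contrast,
           "Busyness" = busyness, "Complexity" = complexity,
           "Strength" = strength)
  attr(out, "degenerate") <- Ng <= 1
  out
}
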