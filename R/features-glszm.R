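## Gray-level size zone matrix features (IF_TX-GLSZM) --------------------

#' Gray-level size zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the mask
#' (orientation-free, so there is a single matrix). Entry `(i, s)` is the
#' number of zones of level `i` and size `s` voxels; the matrix entries
#' sum to the number of zones.
#'
#' @param disc a [discretize()] result.
#' @return integer matrix `n_levels x max_zone_size`.
#' @export
glszm_matrix <- function(disc) {
  L <- disc$levels
  d <- dim(L)
  idx <- which(!is.na(L))
  if (!length(idx)) return(matrix(0, disc$n_levels, 1))
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  dirs <- unique_directions_26()
  edges <- list()
  for (r in seq_len(nrow(dirs))) {
    nb <- sweep(ijk, 2, dirs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbl <- nb[ok, , drop = FALSE]
    j <- pos[nbl]
    src <- pos[idx[ok]]
    keep <- j > 0
    if (!any(keep)) next
    same <- L[idx[ok]][keep] == L[cbind(nbl[keep, 1], nbl[keep, 2], nbl[keep, 3])]
    if (any(same))
      edges[[length(edges) + 1]] <- cbind(src[keep][same], j[keep][same])
  }
  if (length(edges)) {
    e <- do.call(rbind, edges)
    gr <- igraph::graph_from_edgelist(e, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, length(idx) - igraph::vcount(gr)))
    comp <- igraph::components(gr)
    memb <- comp$membership
  } else {
    memb <- seq_along(idx)
  }
  lev_per_zone <- tapply(L[idx], memb, function(v) v[1])
  size_per_zone <- as.integer(table(memb))
  ms <- max(size_per_zone)
  M <- matrix(0, disc$n_levels, ms)
  enc <- (size_per_zone - 1L) * disc$n_levels + as.integer(lev_per_zone)
  cnt <- tabulate(enc, nbins = disc$n_levels * ms)
  M[] <- cnt
  M
}

#' GLSZM texture features
#'
#' Thirteen size-zone statistics (same functional forms as the run-length
#' family, applied to zone sizes). Zone percentage (ZP) is the number of
#' zones divided by the number of in-mask voxels: a constant region of N
#' voxels forms one zone, ZP = 1/N.
#'
#' @param disc a [discretize()] result.
#' @return named numeric of length 13 with attribute `degenerate`.
#' @export
glszm_features <- function(disc) {
  M <- glszm_matrix(disc)
  n_vox <- sum(!is.na(disc$levels))
  if (sum(M) == 0) {
    out <- rep(0, 13)
    names(out) <- names(rlm_style_features(matrix(1, 1, 1), 1, zone = TRUE))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- rlm_style_features(M, n_vox, zone = TRUE)
  attr(out, "degenerate") <- n_vox < 2
  out
}
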