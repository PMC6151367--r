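## Gray-level run-length matrix features (IF_TX-GLRLM) -------------------

## maximal runs of equal gray level along direction d (within mask);
## returns a (level, length) count matrix
runs_one_direction <- function(L, d, max_len) {
  dm <- dim(L)
  Lp <- shift_array(L, d)                    # predecessor level
  starts <- which(!is.na(L) & (is.na(Lp) | Lp != L))
  if (length(starts) == 0) return(matrix(0, 0, 0))
  ijk <- arrayInd(starts, dm)
  lev <- L[starts]
  len <- rep(1L, length(starts))
  cur <- ijk
  active <- seq_along(starts)
  while (length(active)) {
    nxt <- sweep(cur[active, , drop = FALSE], 2, d, "+")
    inb <- nxt[, 1] >= 1 & nxt[, 1] <= dm[1] &
      nxt[, 2] >= 1 & nxt[, 2] <= dm[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= dm[3]
    same <- rep(FALSE, length(active))
    if (any(inb)) {
      nl <- L[nxt[inb, , drop = FALSE]]
      same[inb] <- !is.na(nl) & nl == lev[active][inb]
    }
    keep <- active[same]
    len[keep] <- len[keep] + 1L
    cur[keep, ] <- sweep(cur[keep, , drop = FALSE], 2, d, "+")
    active <- keep
  }
  cbind(level = lev, length = len)
}

#' Gray-level run-length matrix
#'
#' Maximal runs of identical gray level extracted along each of the 13
#' unique directions of 26-connectivity and summed into a single
#' `n_levels x max_run_length` matrix (entry = number of runs).
#'
#' @param disc a [discretize()] result.
#' @return integer matrix; `sum(m)` equals the total number of runs.
#' @export
glrlm_matrix <- function(disc) {
  L <- disc$levels
  dirs <- unique_directions_26()
  max_len <- max(dim(L))
  pairs <- list()
  for (r in seq_len(nrow(dirs))) {
    p <- runs_one_direction(L, dirs[r, ], max_len)
    if (nrow(p)) pairs[[length(pairs) + 1]] <- p
  }
  if (!length(pairs)) return(matrix(0, disc$n_levels, 1))
  pr <- do.call(rbind, pairs)
  ml <- max(pr[, "length"])
  M <- matrix(0, disc$n_levels, ml)
  enc <- (pr[, "length"] - 1L) * disc$n_levels + pr[, "level"]
  cnt <- tabulate(enc, nbins = disc$n_levels * ml)
  M[] <- cnt
  M
}

rlm_style_features <- function(M, n_vox, zone = FALSE) {
  Nr <- sum(M)
  i <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  r <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))
  ri <- rowSums(M)   # per gray level
  rj <- colSums(M)   # per run length / zone size
  w <- M / Nr
  mu_i <- sum(i * w)
  mu_r <- sum(r * w)
  f <- c(
    sum(M / r^2) / Nr,                 # short emphasis
    sum(M * r^2) / Nr,                 # long/large emphasis
    sum(ri^2) / Nr,                    # gray-level nonuniformity
    sum(rj^2) / Nr,                    # length/size nonuniformity
    Nr / n_vox,                        # percentage
    sum(M / i^2) / Nr,                 # low gray-level emphasis
    sum(M * i^2) / Nr,                 # high gray-level emphasis
    sum(M / (i^2 * r^2)) / Nr,
    sum(M * i^2 / r^2) / Nr,
    sum(M * r^2 / i^2) / Nr,
    sum(M * i^2 * r^2) / Nr,
    sum(w * (i - mu_i)^2),             # gray-level variance
    sum(w * (r - mu_r)^2))             # run-length / zone-size variance
  names(f) <- if (zone) {
    c("Small zone emphasis (SZE)", "Large zone emphasis (LZE)",
      "Gray-level nonuniformity (GLN)", "Zone-size nonuniformity (ZSN)",
      "Zone percentage (ZP)", "Low gray-level zone emphasis (LGZE)",
      "High gray-level zone emphasis (HGZE)",
      "Small zone low gray-level emphasis (SZLGE)",
      "Small zone high gray-level emphasis (SZHGE)",
      "Large zone low gray-level emphasis (LZLGE)",
      "Large zone high gray-level emphasis (LZHGE)",
      "Gray-level variance (GLV)", "Zone-size variance (ZSV)")
  } else {
    c("Short run emphasis (SRE)", "Long run emphasis (LRE)",
      "Gray-level nonuniformity (GLN)", "Run-length nonuniformity (RLN)",
      "Run percentage (RP)", "Low gray-level run emphasis (LGRE)",
      "High gray-level run emphasis (HGRE)",
      "Short run low gray-level emphasis (SRLGE)",
      "Short run high gray-level emphasis (SRHGE)",
      "Long run low gray-level emphasis (LRLGE)",
      "Long run high gray-level emphasis (LRHGE)",
      "Gray-level variance (GLV)", "Run-length variance (RLV)")
  }
  f
}

#' GLRLM texture features
#'
#' Thirteen run-length statistics on the direction-merged matrix. Run
#' percentage (RP) is total runs / (number of in-mask voxels x number of
#' directions), so an everywhere-fragmented region (all runs length 1)
#' reaches RP = 1. Gray-level and run-length variances are
#' run-probability weighted.
#'
#' @param disc a [discretize()] result.
#' @return named numeric of length 13 with attribute `degenerate`.
#' @export
glrlm_features <- function(disc) {
  M <- glrlm_matrix(disc)
  n_vox <- sum(!is.na(disc$levels))
  if (sum(M) == 0) {
    out <- rep(0, 13)
    names(out) <- names(rlm_style_features(matrix(1, 1, 1), 1))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  n_dir <- nrow(unique_directions_26())
  out <- rlm_style_features(M, n_vox * n_dir)
  attr(out, "degenerate") <- n_vox < 2
  out
}
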