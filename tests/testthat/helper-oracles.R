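# Brute-force oracles for the texture matrices: explicit loops over
# voxels, neighbours and paths, written independently of the package's
# vectorized implementations. Only usable on small volumes.

oracle_dirs26 <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

## symmetric normalized GLCM by enumerating every ordered voxel pair at
## distance-1 under 26-connectivity
oracle_glcm <- function(levels, n_levels) {
  d <- dim(levels)
  dirs <- oracle_dirs26()
  C <- matrix(0, n_levels, n_levels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- levels[i, j, k]
    if (is.na(a)) next
    for (r in seq_len(nrow(dirs))) {
      ii <- i + dirs[r, 1]; jj <- j + dirs[r, 2]; kk <- k + dirs[r, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      b <- levels[ii, jj, kk]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1
    }
  }
  if (sum(C) == 0) return(C)
  C / sum(C)
}

## run-length matrix by walking every line in each of the 13 directions
oracle_glrlm <- function(levels, n_levels) {
  d <- dim(levels)
  dirs <- oracle_dirs26()
  keep <- apply(dirs, 1, function(v) { nz <- v[v != 0]; nz[length(nz)] > 0 })
  dirs <- dirs[keep, , drop = FALSE]
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (r in seq_len(nrow(dirs))) {
    dr <- dirs[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      p <- c(i, j, k)
      a <- levels[i, j, k]
      if (is.na(a)) next
      prev <- p - dr
      if (inb(prev)) {
        b <- levels[prev[1], prev[2], prev[3]]
        if (!is.na(b) && b == a) next  # not a run start
      }
      len <- 1
      q <- p + dr
      while (inb(q) && !is.na(levels[q[1], q[2], q[3]]) &&
             levels[q[1], q[2], q[3]] == a) {
        len <- len + 1
        q <- q + dr
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  if (!length(runs)) return(matrix(0, n_levels, 1))
  rr <- do.call(rbind, runs)
  M <- matrix(0, n_levels, max(rr[, 2]))
  for (x in seq_len(nrow(rr))) M[rr[x, 1], rr[x, 2]] <- M[rr[x, 1], rr[x, 2]] + 1
  M
}

## size-zone matrix by flood fill over equal-level 26-neighbours
oracle_glszm <- function(levels, n_levels) {
  d <- dim(levels)
  dirs <- oracle_dirs26()
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (seen[i, j, k] || is.na(levels[i, j, k])) next
    lev <- levels[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(dirs))) {
        q <- p + dirs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- levels[q[1], q[2], q[3]]
        if (!is.na(b) && b == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  if (!length(zones)) return(matrix(0, n_levels, 1))
  zz <- do.call(rbind, zones)
  M <- matrix(0, n_levels, max(zz[, 2]))
  for (x in seq_len(nrow(zz))) M[zz[x, 1], zz[x, 2]] <- M[zz[x, 1], zz[x, 2]] + 1
  M
}

## NGTDM (level, n_i, s_i) by explicit neighbourhood means
oracle_ngtdm <- function(levels, n_levels) {
  d <- dim(levels)
  dirs <- oracle_dirs26()
  n_i <- numeric(n_levels)
  s_i <- numeric(n_levels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- levels[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(dirs))) {
      q <- c(i, j, k) + dirs[r, ]
      if (any(q < 1) || any(q > d)) next
      b <- levels[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  data.frame(level = seq_len(n_levels), n = n_i, p = n_i / sum(n_i), s = s_i)
}

## random small discretized fixture: levels array with NA outside mask
random_disc_fixture <- function(seed, dim3 = c(5, 5, 5), n_levels = 4,
                                p_mask = 0.8) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dim3), replace = TRUE), dim3)
  msk <- array(runif(prod(dim3)) < p_mask, dim3)
  if (!any(msk)) msk[1] <- TRUE
  lev[!msk] <- NA_integer_
  structure(list(levels = lev, mask = msk, n_levels = as.integer(n_levels),
                 original_range = c(1, n_levels), degenerate = FALSE),
            class = "discretized_volume")
}
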