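# Shared fixtures, built in code at test time.

# digital sphere mask of radius r voxels inside an (2r+pad)^3 array
digital_sphere <- function(r, pad = 5L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  x <- (1:n) - c0
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  array(r2 <= r^2, c(n, n, n))
}

# axis-aligned ellipsoid mask with semi-axes (a, b, c) voxels
digital_ellipsoid <- function(a, b, c, pad = 4L) {
  nx <- 2L * (ceiling(a) + pad) + 1L
  ny <- 2L * (ceiling(b) + pad) + 1L
  nz <- 2L * (ceiling(c) + pad) + 1L
  xs <- ((1:nx) - (ceiling(a) + pad + 1L)) / a
  ys <- ((1:ny) - (ceiling(b) + pad + 1L)) / b
  zs <- ((1:nz) - (ceiling(c) + pad + 1L)) / c
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  array(r2 <= 1, c(nx, ny, nz))
}

# quick uniform-uptake lesion + noiseless acquisition for segmentation tests
noiseless_lesion_image <- function(seed, v_cc = 8, s_target = 0.75, lb = 10,
                                   c1 = 0.06, resolution = 1.5) {
  sh <- shell_for_sphericity(s_target, v_cc, seed = seed,
                             resolution = resolution)
  pl <- phantom_lesion(sh, uptake_config("uniform", c1 = c1),
                       background = c1 / lb)
  img <- suppressWarnings(simulate_acquisition(
    pl, acquisition_settings(noise_scale = 0, seed = seed)))
  list(lesion = pl, image = img)
}

# discretized-volume wrapper around an explicit integer level array
disc_from_levels <- function(lev, n_levels) {
  structure(list(levels = lev, mask = !is.na(lev),
                 n_levels = as.integer(n_levels),
                 original_range = range(lev, na.rm = TRUE),
                 degenerate = FALSE),
            class = "discretized_volume")
}

# lesion-x-feature matrix with the 58 registry column names
registry_matrix <- function(values) {
  reg <- phantomrad::feature_registry()
  m <- matrix(values, nrow = NROW(values), ncol = nrow(reg))
  colnames(m) <- reg$qualified
  m
}
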