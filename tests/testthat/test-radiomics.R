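test_that("isotropic resampling targets the in-plane pixel size", {
  v <- activity_volume(array(rnorm(20 * 20 * 10)^2, c(20, 20, 10)),
                       spacing = c(2, 2, 4))
  m <- array(FALSE, c(20, 20, 10)); m[6:15, 6:15, 3:8] <- TRUE
  rs <- resample_isotropic(v, m)
  expect_equal(rs$image$spacing, c(2, 2, 2))
  ## mask volume approximately conserved
  v0 <- sum(m) * prod(v$spacing)
  v1 <- sum(rs$mask) * prod(rs$image$spacing)
  expect_lt(abs(v1 - v0) / v0, 0.05)
  ## already-isotropic input is returned bitwise unchanged
  iso <- activity_volume(array(1:64, c(4, 4, 4)), spacing = c(2, 2, 2))
  mi <- array(TRUE, c(4, 4, 4))
  rs2 <- resample_isotropic(iso, mi)
  expect_identical(rs2$image$values, iso$values)
  expect_identical(rs2$mask, mi)
  ## unphysical anisotropy rejected
  bad <- activity_volume(array(1, c(4, 4, 4)), spacing = c(1, 1, 20))
  expect_error(resample_isotropic(bad), "anisotropy")
})

test_that("discretization maps the masked range onto 1..64", {
  m <- array(TRUE, c(8, 8, 10))
  ramp <- array(seq(0.5, 4.5, length.out = 640), c(8, 8, 10))
  d <- discretize(ramp, m)
  expect_equal(min(d$levels), 1L)
  expect_equal(max(d$levels), 64L)
  expect_lte(length(unique(as.vector(d$levels))), 64)
  ## oracle binning: same assignment via cut()
  oracle <- as.integer(cut(as.vector(ramp), breaks = seq(0.5, 4.5, length.out = 65),
                           include.lowest = TRUE, right = FALSE))
  oracle[oracle > 64] <- 64L
  expect_true(mean(oracle == as.vector(d$levels)) > 0.99)
  ## a staircase ramp lands exactly 10 voxels on each of the 64 levels
  stair <- array(rep(seq_len(64), each = 10), c(8, 8, 10))
  ds <- discretize(stair, m)
  expect_equal(as.vector(table(ds$levels)), rep(10L, 64))
  ## constant region: single level, degenerate flag
  dc <- discretize(array(3, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  expect_true(dc$degenerate)
  expect_equal(unique(as.vector(dc$levels)), 1L)
  expect_error(discretize(ramp, array(FALSE, c(8, 8, 10))), "empty")
})

test_that("morphological features recover analytic solids", {
  sph <- digital_sphere(20)
  f <- morphological_features(sph, c(1, 1, 1))
  expect_equal(unname(f["Sphericity"]), 1, tolerance = 0.02)
  expect_equal(unname(f["MTV"]), 4 / 3 * pi * 20^3 / 1000, tolerance = 0.01)
  expect_equal(unname(f["Sphericity"] * f["Spherical disproportion"]), 1)
  expect_equal(unname(f["Surface-volume ratio (SV)"]),
               unname(f["Surface"] / f["MTV"]))
  ## 4:1:1 prolate ellipsoid: analytic area oracle
  a <- 24; b <- 6
  ell <- digital_ellipsoid(a, b, b)
  fe <- morphological_features(ell, c(1, 1, 1))
  e <- sqrt(1 - b^2 / a^2)
  s_analytic <- 2 * pi * b^2 * (1 + (a / (b * e)) * asin(e)) / 100
  v_analytic <- 4 / 3 * pi * a * b^2 / 1000
  s_exp <- compute_sphericity_gs(v_analytic, s_analytic)
  expect_equal(unname(fe["Sphericity"]), s_exp, tolerance = 0.04)
  expect_lt(fe["Sphericity"], f["Sphericity"])
  ## intensity independence is structural (mask-only input); single voxel
  ## degenerates but stays finite
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  f1 <- morphological_features(m1, c(2, 2, 2))
  expect_true(attr(f1, "degenerate"))
  expect_true(all(is.finite(f1)))
})

test_that("histogram features match closed forms", {
  m <- array(TRUE, c(4, 4, 4))
  ## constant region sentinels
  fc <- histogram_features(array(7, c(4, 4, 4)), m)
  expect_equal(unname(fc[c("Mean", "Median", "Root mean square (RMS)")]),
               c(7, 7, 7))
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
  expect_equal(unname(fc["Entropy"]), 0)
  expect_equal(unname(fc[c("Kurtosis", "Skewness")]), c(0, 0))
  ## two-value 50/50 region
  ab <- array(rep(c(2, 6), 32), c(4, 4, 4))
  f2 <- histogram_features(ab, m)
  expect_equal(unname(f2["Mean"]), 4)
  expect_equal(unname(f2["Entropy"]), 1)  # 1 bit
  expect_equal(unname(f2["Standard deviation"])^2, unname(f2["Variance"]))
  expect_equal(unname(f2["Energy"]), sum(ab^2))
  ## random region: variance identity and MAD
  set.seed(3)
  x <- array(rlnorm(64), c(4, 4, 4))
  fr <- histogram_features(x, m)
  expect_equal(unname(fr["Variance"]), unname(fr["Standard deviation"])^2)
  expect_equal(unname(fr["Mean absolute deviation (MAD)"]),
               mean(abs(x - mean(x))))
  expect_equal(unname(fr["Maximum"]), max(x))
})

test_that("GLCM features match the exhaustive pair oracle", {
  ## constant region
  dc <- disc_from_levels(array(1L, c(3, 3, 3)), 4)
  fc <- glcm_features(dc)
  expect_equal(unname(fc[c("Energy", "Contrast", "Entropy", "Homogeneity")]),
               c(1, 0, 0, 1))
  ## 2x2x1 checkerboard of levels 1/2
  lev <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  d2 <- disc_from_levels(lev, 2)
  P <- glcm_matrix(d2)
  expect_equal(sum(P), 1)
  expect_equal(P, oracle_glcm(lev, 2))
  f2 <- glcm_features(d2)
  Po <- oracle_glcm(lev, 2)
  i <- matrix(1:2, 2, 2); j <- t(i)
  expect_equal(unname(f2["Contrast"]), sum((i - j)^2 * Po))
  expect_equal(unname(f2["Energy"]), sum(Po^2))
  ## single voxel: sentinel + flag
  d1 <- disc_from_levels(array(1L, c(1, 1, 1)), 4)
  f1 <- glcm_features(d1)
  expect_true(attr(f1, "degenerate"))
  expect_equal(unname(f1["Energy"]), 1)
})

test_that("GLRLM features match hand-enumerated runs", {
  ## constant 4x4x1 slab: 4 runs of length 4 along each in-plane axis
  lev <- array(1L, c(4, 4, 1))
  M <- glrlm_matrix(disc_from_levels(lev, 2))
  Mo <- oracle_glrlm(lev, 2)
  expect_equal(M[, seq_len(ncol(Mo))], Mo)
  ## 4 rows + 4 columns + the two in-plane diagonals of length 4
  expect_equal(M[1, 4], 10)
  ## strictly alternating line: all runs length 1, RP = 1
  lin <- array(rep(c(1L, 2L), 8), c(16, 1, 1))
  fl <- glrlm_features(disc_from_levels(lin, 2))
  expect_equal(unname(fl["Run percentage (RP)"]), 1)
  expect_equal(unname(fl["Short run emphasis (SRE)"]), 1)
  ## conservation: matrix entries sum to the number of runs
  disc <- random_disc_fixture(77, c(5, 4, 3), n_levels = 3)
  M2 <- glrlm_matrix(disc)
  M2o <- oracle_glrlm(disc$levels, 3)
  expect_equal(sum(M2), sum(M2o))
  nc <- max(ncol(M2), ncol(M2o))
  pad <- function(M) cbind(M, matrix(0, nrow(M), nc - ncol(M)))
  expect_equal(pad(M2), pad(M2o))
})

test_that("GLSZM zones match the connected-component oracle", {
  ## constant region of N voxels: one zone, ZP = 1/N
  lev <- array(2L, c(3, 3, 2))
  f <- glszm_features(disc_from_levels(lev, 3))
  expect_equal(unname(f["Zone percentage (ZP)"]), 1 / 18)
  ## two disjoint blobs of the same level -> 2 zones
  lev2 <- array(NA_integer_, c(7, 3, 1))
  lev2[1:2, , 1] <- 1L; lev2[6:7, , 1] <- 1L
  M <- glszm_matrix(disc_from_levels(lev2, 2))
  expect_equal(sum(M), 2)
  expect_equal(M[1, 6], 2)
  ## random fixture equals flood-fill oracle
  disc <- random_disc_fixture(5, c(5, 5, 4), n_levels = 3)
  M1 <- glszm_matrix(disc)
  Mo <- oracle_glszm(disc$levels, 3)
  nc <- max(ncol(M1), ncol(Mo))
  pad <- function(M) cbind(M, matrix(0, nrow(M), nc - ncol(M)))
  expect_equal(pad(M1), pad(Mo))
})

test_that("NGTDM matches hand-computed neighbourhood means", {
  ## single bright voxel amid uniform level on a 3x3x3 toy
  lev <- array(1L, c(3, 3, 3)); lev[2, 2, 2] <- 3L
  tab <- ngtdm_matrix(disc_from_levels(lev, 3))
  oracle <- oracle_ngtdm(lev, 3)
  expect_equal(tab$s, oracle$s)
  expect_equal(tab$n, oracle$n)
  ## centre voxel: 26 neighbours all level 1 -> s_3 = |3 - 1| = 2
  expect_equal(tab$s[3], 2)
  ## constant region: zero contrast, capped coarseness
  fc <- ngtdm_features(disc_from_levels(array(2L, c(3, 3, 3)), 3))
  expect_equal(unname(fc["Contrast"]), 0)
  expect_equal(unname(fc["Coarseness"]), 1e6)
  expect_true(attr(fc, "degenerate"))
})

test_that("texture features are invariant to intensity rescaling and translation", {
  set.seed(10)
  vals <- array(rlnorm(6 * 6 * 6), c(6, 6, 6))
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  v1 <- activity_volume(vals, spacing = c(2, 2, 2))
  v2 <- activity_volume(2 * vals + 0.5, spacing = c(2, 2, 2), clamp = FALSE)
  d1 <- discretize(v1, m); d2 <- discretize(v2, m)
  expect_identical(d1$levels, d2$levels)   # affine map preserves bins
  expect_equal(glcm_features(d1), glcm_features(d2))
  expect_equal(ngtdm_features(d1), ngtdm_features(d2))
  ## translation of the mask+content leaves GLCM unchanged
  vals_t <- array(0, c(8, 8, 8)); vals_t[3:8, 3:8, 3:8] <- vals[1:6, 1:6, 1:6]
  m_t <- array(FALSE, c(8, 8, 8)); m_t[4:7, 4:7, 4:7] <- TRUE
  d_t <- discretize(vals_t, m_t)
  expect_equal(glcm_features(d_t), glcm_features(d1))
  ## axis permutation of an isotropic volume leaves GLCM unchanged
  d_p <- disc_from_levels(aperm(d1$levels, c(2, 3, 1)), d1$n_levels)
  expect_equal(glcm_features(d_p), glcm_features(d1))
})

test_that("extract_all returns the frozen 58-feature registry", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 58)
  expect_equal(as.integer(table(factor(reg$group, levels = unique(reg$group)))),
               c(5L, 13L, 9L, 13L, 13L, 5L))
  expect_false(any(duplicated(reg$qualified)))
  ## golden name check: frozen spot samples across groups
  expect_identical(reg$qualified[c(1, 4, 6, 19, 28, 41, 54, 58)],
                   c("M_MTV", "M_Sphericity", "HIST_Maximum", "GLCM_Energy",
                     "GLRLM_SRE", "GLSZM_SZE", "NGTDM_Coarseness",
                     "NGTDM_Strength"))
  set.seed(4)
  v <- activity_volume(array(rlnorm(16^3), c(16, 16, 16)), spacing = c(2, 2, 3))
  m <- array(FALSE, c(16, 16, 16)); m[5:12, 5:12, 5:12] <- TRUE
  f1 <- extract_all(v, m)
  f2 <- extract_all(v, m)
  expect_identical(f1, f2)                      # bitwise repeatable
  expect_equal(length(f1), 58)
  expect_false(any(is.na(f1)))
  expect_named(f1, reg$qualified)
})
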