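test_that("sphericity index matches Eq.-style closed forms and mesh oracle", {
  r <- 1.7
  expect_equal(compute_sphericity_gs(4 * pi * r^3 / 3, 4 * pi * r^2), 1)
  ## unit cube: V = 1, S = 6 -> (pi/6)^(1/3), evaluated independently
  cube_oracle <- pi^(1 / 3) * 6^(2 / 3) / 6
  expect_equal(compute_sphericity_gs(1, 6), cube_oracle)
  expect_equal(cube_oracle, (pi / 6)^(1 / 3))
  ## 1 x 1 x 4 box: V = 4, S = 18; strictly less spherical than the cube
  box_oracle <- pi^(1 / 3) * (6 * 4)^(2 / 3) / 18
  expect_equal(compute_sphericity_gs(4, 18), box_oracle)
  expect_lt(box_oracle, cube_oracle)
  expect_error(compute_sphericity_gs(0, 6), "positive")
  expect_error(compute_sphericity_gs(1, -1), "positive")
})

test_that("mesh-based sphericity of a rasterized sphere is within 2% of 1", {
  sh <- generate_shell(shell_spec(1, base_radius = 12,
                                  deformation_amplitude = 0, resolution = 1))
  expect_lt(abs(sh$sphericity - 1), 0.02)
  expect_lt(abs(sh$volume_cc - 4 * pi * 12^3 / 3 / 1000) /
              (4 * pi * 12^3 / 3 / 1000), 0.02)
})

test_that("shell generation is deterministic and connected", {
  s1 <- generate_shell(shell_spec(9, 11, 0.4))
  s2 <- generate_shell(shell_spec(9, 11, 0.4))
  expect_identical(s1$labels, s2$labels)
  ## star-shaped by construction; verify a single 26-connected component
  d <- dim(s1$labels)
  idx <- which(s1$labels == 1L)
  comp <- phantomrad:::largest_component(s1$labels == 1L)
  expect_equal(sum(comp), length(idx))
})

test_that("sphericity decreases monotonically along an amplitude sweep", {
  sw <- vapply(seq(0, 0.6, by = 0.1), function(a)
    generate_shell(shell_spec(7, 12, a, resolution = 1.2))$sphericity,
    numeric(1))
  expect_true(all(diff(sw) <= 1e-6))
})

test_that("degenerate shell radius is rejected", {
  expect_error(shell_spec(1, base_radius = 2, resolution = 1.5),
               "unresolvable")
})

test_that("uptake COV matches weighted-moment oracles", {
  ## homogeneous
  expect_equal(compute_cov_gs(uptake_config("uniform", c1 = 0.08)), 0)
  ## 50/50 at C and 5C: mean 3C, population sd 2C -> 200/3 %
  cfg <- uptake_config("d", c1 = 0.05, volume_fractions = c(c1 = 0.5, c2 = 0.5))
  expect_equal(compute_cov_gs(cfg), 200 / 3)
  ## thirds at 0, C, 5C: brute-force voxel enumeration oracle
  vox <- rep(c(0, 0.05, 0.25), each = 1000)
  oracle <- 100 * sqrt(mean((vox - mean(vox))^2)) / mean(vox)
  cfg3 <- uptake_config("f", c1 = 0.05,
                        volume_fractions = c(c0 = 1, c1 = 1, c2 = 1) / 3)
  expect_equal(compute_cov_gs(cfg3), oracle)
  ## all-necrotic mean is an error
  expect_error(
    compute_cov_gs(structure(list(layout = "a", c1 = 1, c2 = 5,
                                  volume_fractions = c(c0 = 1)),
                             class = "uptake_config")),
    "mean")
})

test_that("Gini index has the normalized categorical form", {
  expect_equal(compute_gini_gs(1), 0)
  expect_equal(compute_gini_gs(c(0.5, 0.5)), 1)
  expect_equal(compute_gini_gs(c(0.9, 0.1)), (1 - 0.81 - 0.01) * 2)
  expect_error(compute_gini_gs(c(0.5, 0.2)), "sum to 1")
  ## permutation invariance and maximality at uniform frequencies
  p <- c(0.2, 0.5, 0.3)
  expect_equal(compute_gini_gs(p), compute_gini_gs(sample(p)))
  for (k in 2:4) {
    u <- rep(1 / k, k)
    expect_equal(compute_gini_gs(u), 1)
    set.seed(k)
    q <- as.numeric(stats::rmultinom(1, 500, runif(k)) / 500)
    expect_lte(compute_gini_gs(q[q > 0]), 1 + 1e-12)
  }
})

test_that("total heterogeneity is the COV x Gini product with its bounds", {
  expect_equal(compute_h_gs(0, 0.7), 0)
  expect_equal(compute_h_gs(200 / 3, 1), 200 / 3)
  ## any two-level C/5C configuration stays within [0, 100]
  set.seed(11)
  for (i in 1:50) {
    p <- runif(1, 0.01, 0.99)
    cfg <- uptake_config("d", c1 = 0.05,
                         volume_fractions = c(c1 = p, c2 = 1 - p))
    h <- compute_h_gs(compute_cov_gs(cfg), compute_gini_gs(cfg))
    expect_gte(h, 0); expect_lte(h, 100)
  }
})

test_that("h_gs is zero iff the lesion is homogeneous", {
  cfg_hom <- uptake_config("uniform", c1 = 0.1)
  expect_equal(compute_h_gs(compute_cov_gs(cfg_hom), compute_gini_gs(cfg_hom)), 0)
  cfg_het <- uptake_config("d", c1 = 0.1,
                           volume_fractions = c(c1 = 0.8, c2 = 0.2))
  expect_gt(compute_h_gs(compute_cov_gs(cfg_het), compute_gini_gs(cfg_het)), 0)
})

test_that("uptake configurations validate fractions and the 5x constraint", {
  cfg <- uptake_config("d", c1 = 0.04)
  expect_equal(cfg$c2, 0.2)
  expect_error(uptake_config("d", c1 = 0.05,
                             volume_fractions = c(c1 = 0.5, c2 = 0.4)),
               "sum to 1")
  expect_error(uptake_config("a", c1 = 0.05,
                             volume_fractions = c(c1 = 1)), "needs fractions")
})

test_that("carved lesions report realized fractions in their ground truth", {
  sh <- generate_shell(shell_spec(21, 12, 0.3))
  pl <- phantom_lesion(sh, uptake_config("f", c1 = 0.05,
                                         volume_fractions = c(c0 = 0.15, c1 = 0.6, c2 = 0.25)),
                       background = 0.006)
  g <- pl$ground_truth
  n <- sum(pl$labels > 0)
  expect_equal(sum(pl$labels == 3L) / n, 0.15, tolerance = 0.01)
  expect_equal(g$v_gs_active / g$v_gs, 1 - sum(pl$labels == 3L) / n,
               tolerance = 1e-6)
  expect_gt(g$h_gs, 0)
  ## COV/Gini computed from nominal concentrations, not image values
  expect_equal(g$cov_gs, compute_cov_gs(pl$config))
  expect_equal(g$gini_gs, compute_gini_gs(pl$config))
})
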