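test_that("Friedman stability detects method effects and nothing else", {
  set.seed(21)
  base <- registry_matrix(matrix(rlnorm(20 * 58), 20))
  ## identical values under both methods: no feature flagged
  r0 <- friedman_stability(list(a = base, b = base))
  expect_true(all(r0$p >= 0.05))
  expect_true(all(r0$stable))
  ## one method shifted by 10 sd on every feature: all flagged
  shifted <- base + 10 * matrix(rep(apply(base, 2, sd), each = 20), 20)
  r1 <- friedman_stability(list(a = base, b = shifted))
  expect_true(all(r1$p < 0.05))
  ## consistent lesion permutation leaves p unchanged
  perm <- sample(20)
  r2 <- friedman_stability(list(a = base[perm, ], b = shifted[perm, ]))
  expect_equal(r1$p, r2$p)
  ## mismatched lesion sets rejected
  expect_error(friedman_stability(list(a = base, b = base[1:10, ])),
               "mismatch")
})

test_that("Friedman with three conditions falls back to the chi-square test", {
  set.seed(22)
  m <- registry_matrix(matrix(rnorm(15 * 58), 15))
  r <- friedman_stability(list(a = m, b = m + rnorm(15 * 58, sd = 1e-3),
                               c = m + rnorm(15 * 58, sd = 1e-3)))
  expect_true(all(r$p >= 0 & r$p <= 1))
})

test_that("COV stability classes partition with exact boundaries", {
  ## the partition is gapless, overlap-free and right-closed at 5/10/20
  expect_equal(stability_class_of(c(0, 5, 10, 20)),
               c("stable", "stable", "quite_stable", "poorly_stable"))
  expect_equal(stability_class_of(c(5 + 1e-9, 10 + 1e-9, 20 + 1e-9)),
               c("quite_stable", "poorly_stable", "unstable"))
  expect_false(any(is.na(stability_class_of(seq(0, 50, by = 0.25)))))
  ## crafted 1-lesion, 2-setting data with a target COV per feature:
  ## values (1 - x, 1 + x) give sd = x * sqrt(2), mean 1
  x_for <- function(cov_pct) cov_pct / 100 / sqrt(2)
  covs <- c(4, 7, 15, 25)
  mk <- function(v) { m <- matrix(v, 1); colnames(m) <- paste0("f", seq_along(v)); m }
  out <- cov_stability(list(s1 = mk(1 - x_for(covs)), s2 = mk(1 + x_for(covs))),
                       families = c(s1 = "matrix", s2 = "matrix"))
  expect_equal(out$cov_worst, covs, tolerance = 1e-10)
  expect_equal(out$stability_class,
               c("stable", "quite_stable", "poorly_stable", "unstable"))
  expect_equal(out$quite_stable, covs <= 10)
})

test_that("representative COV is the worst family and near-zero means flag", {
  ## two families with per-feature COVs {3, 9}: representative 9, quite stable
  mk <- function(v) { m <- matrix(v, 1); colnames(m) <- "f1"; m }
  x <- function(cov) cov / 100 / sqrt(2)
  out <- cov_stability(
    list(a1 = mk(1 - x(3)), a2 = mk(1 + x(3)),
         b1 = mk(1 - x(9)), b2 = mk(1 + x(9))),
    families = c(a1 = "fam_a", a2 = "fam_a", b1 = "fam_b", b2 = "fam_b"))
  expect_equal(out$cov_worst, 9, tolerance = 1e-10)
  expect_equal(out$stability_class, "quite_stable")
  expect_true(out$quite_stable)
  ## constant feature across settings: COV 0, class stable
  outc <- cov_stability(list(s1 = mk(2), s2 = mk(2)),
                        families = c(s1 = "m", s2 = "m"))
  expect_equal(outc$cov_worst, 0)
  expect_equal(outc$stability_class, "stable")
  ## negative-mean feature: |mean| used, flagged
  outn <- cov_stability(list(s1 = mk(-1 - x(4)), s2 = mk(-1 + x(4))),
                        families = c(s1 = "m", s2 = "m"))
  expect_true(outn$abs_mean_flag)
  expect_equal(outn$cov_worst, 4, tolerance = 1e-10)
})

test_that("ICC is 1 on duplicated data, ~0 on noise, affine-invariant", {
  set.seed(23)
  m <- registry_matrix(matrix(rlnorm(38 * 58), 38))
  r_dup <- icc_reproducibility(m, m)
  expect_true(all(abs(r_dup$icc_test1 - 1) < 1e-12))
  expect_true(all(r_dup$reproducible))
  ## independent noise: |ICC| small on average
  noise <- registry_matrix(matrix(rnorm(38 * 58), 38))
  noise2 <- registry_matrix(matrix(rnorm(38 * 58), 38))
  r_nil <- icc_reproducibility(noise, noise2)
  expect_lt(mean(abs(r_nil$icc_test1)), 0.3)
  expect_lt(mean(r_nil$reproducible), 0.2)
  ## common affine rescaling of both datasets leaves ICC unchanged
  r_aff <- icc_reproducibility(3 * m + 2, 3 * m + 2)
  expect_equal(r_aff$icc_test1, r_dup$icc_test1, tolerance = 1e-9)
  ## constant shift of the retest: ICC(1,1) penalized, ICC(3,1) unchanged
  sdm <- matrix(rep(apply(m, 2, sd), each = 38), 38)
  r_shift11 <- icc_reproducibility(m, m + 2 * sdm)
  expect_true(all(r_shift11$icc_test1 < r_dup$icc_test1 - 0.1))
  r_shift31 <- icc_reproducibility(m, m + 2 * sdm, form = "ICC31")
  expect_true(all(abs(r_shift31$icc_test1 - 1) < 1e-9))
  ## two pairs: reproducible needs both above the cut
  r_two <- icc_reproducibility(m, m, noise, noise2)
  expect_true(all(r_two$reproducible == (r_two$icc_test2 > 0.6)))
  ## zero between-lesion variance: undefined, non-reproducible
  const <- registry_matrix(matrix(1, 10, 58))
  r_const <- icc_reproducibility(const, const)
  expect_true(all(is.na(r_const$icc_test1)))
  expect_false(any(r_const$reproducible))
})

test_that("Mann-Whitney discrimination is symmetric and powered", {
  set.seed(24)
  hom <- registry_matrix(matrix(rnorm(20 * 58), 20))
  het <- registry_matrix(matrix(rnorm(18 * 58), 18))
  ## strong effect: separated by 5 sd
  het5 <- het + 5
  r <- heterogeneity_discrimination(hom, het5)
  expect_true(all(r$p < 0.05))
  expect_true(all(r$discriminative))
  ## label swap gives identical two-sided p
  r_ab <- heterogeneity_discrimination(hom, het)
  r_ba <- heterogeneity_discrimination(het, hom)
  expect_equal(r_ab$p, r_ba$p)
  ## all-tied values: p = 1
  tied <- registry_matrix(matrix(1, 10, 58))
  r_tie <- heterogeneity_discrimination(tied, tied)
  expect_true(all(r_tie$p == 1))
})

test_that("H_GS correlation recovers exact monotone relations", {
  set.seed(25)
  h <- runif(18, 10, 65)
  m <- registry_matrix(matrix(rnorm(18 * 58), 18))
  m[, 1] <- h          # feature equal to H_GS
  m[, 2] <- -h         # anti-correlated
  m[, 3] <- 7          # constant
  r <- hgs_correlation(m, h)
  expect_equal(r$rho[1], 1)
  expect_equal(r$rho[2], -1)
  expect_true(r$constant[3] && !r$correlated[3])
  expect_true(r$correlated[1] && r$correlated[2])
})

test_that("sphericity agreement flags bias and passes exact agreement", {
  set.seed(26)
  s_gs <- runif(30, 0.5, 0.8)
  exact <- sphericity_agreement(s_gs, s_gs)
  expect_equal(exact$mean_difference, 0)
  biased <- sphericity_agreement(s_gs + 0.2, s_gs)
  expect_lt(biased$p, 0.05)
  expect_equal(biased$mean_difference, 0.2, tolerance = 1e-9)
  expect_error(sphericity_agreement(s_gs[1:2], s_gs[1:2]), "at least 3")
})

test_that("the report joins analyses, counts the funnel, and is pure", {
  set.seed(27)
  n <- 12
  reg <- feature_registry()
  base <- registry_matrix(matrix(rlnorm(n * 58), n))
  retest <- base + registry_matrix(matrix(rnorm(n * 58, sd = 1e-3), n))
  fried <- friedman_stability(list(a = base, b = retest))
  icc <- icc_reproducibility(base, retest)
  mw <- heterogeneity_discrimination(base[1:6, , drop = FALSE],
                                     base[7:12, , drop = FALSE])
  hgs <- hgs_correlation(base[7:12, , drop = FALSE] + 0,
                         seq_len(6), method = "spearman")
  rep1 <- build_report(friedman = fried, icc = icc, mw = mw, hgs = hgs)
  expect_s3_class(rep1, "stability_report")
  expect_equal(nrow(rep1$table), 58)
  expect_equal(rep1$table$feature, reg$qualified)
  ## deterministic copies of lesion properties: everything reproducible
  expect_true(all(rep1$table$reproducible))
  expect_equal(unname(rep1$funnel["reproducible"]), 58)
  expect_lte(rep1$funnel["and_correlated"], rep1$funnel["and_discriminative"])
  ## purity: identical inputs give identical output
  rep2 <- build_report(friedman = fried, icc = icc, mw = mw, hgs = hgs)
  expect_identical(rep1$table, rep2$table)
  ## registry mismatch rejected
  bad <- fried; bad$feature[1] <- "other"
  expect_error(build_report(friedman = bad, icc = icc), "mismatch")
})
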