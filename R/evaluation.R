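## Stability / reproducibility / significance battery --------------------

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, x)
  if (is.null(colnames(x))) stop("feature matrix needs feature column names")
  x
}

#' Feature stability versus segmentation method (Friedman test)
#'
#' Per-feature Friedman test over the same lesions segmented with each
#' method. With exactly two methods the Friedman statistic reduces to a
#' sign test; the exact two-sided sign-test p-value is used there (tied
#' pairs dropped), the chi-square Friedman test for three or more
#' methods. A feature is stable versus segmentation when p >= 0.05.
#'
#' @param features_by_method named list of lesion x feature matrices, one
#'   per segmentation method (same lesions, same order).
#' @param alpha significance level for the stability flag.
#' @return data.frame `feature`, `p`, `stable`.
#' @export
friedman_stability <- function(features_by_method, alpha = 0.05) {
  mats <- lapply(features_by_method, as_feature_matrix)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("mismatched lesion sets across methods")
  if (nrow(mats[[1]]) < 5) stop("need at least 5 lesions")
  feats <- colnames(mats[[1]])
  k <- length(mats)
  p <- vapply(feats, function(f) {
    y <- vapply(mats, function(m) m[, f], numeric(nrow(mats[[1]])))
    if (k == 2) {
      dif <- y[, 1] - y[, 2]
      dif <- dif[dif != 0]
      if (!length(dif)) return(1)
      s <- sum(dif > 0)
      min(1, 2 * min(stats::pbinom(s, length(dif), 0.5),
                     stats::pbinom(length(dif) - s, length(dif), 0.5)))
    } else {
      stats::friedman.test(y)$p.value
    }
  }, numeric(1))
  data.frame(feature = feats, p = unname(p), stable = unname(p) >= alpha,
             stringsAsFactors = FALSE)
}

#' Stability class of a COV value
#'
#' The four classes partition `[0, Inf)` with right-closed boundaries:
#' stable (COV <= 5%), quite stable (5% < COV <= 10%), poorly stable
#' (10% < COV <= 20%), unstable (COV > 20%).
#'
#' @param cov COV values in percent.
#' @return character vector of class labels.
#' @export
stability_class_of <- function(cov) {
  as.character(cut(cov, c(-Inf, 5, 10, 20, Inf),
                   labels = c("stable", "quite_stable", "poorly_stable",
                              "unstable")))
}

#' COV stability classes across reconstruction settings
#'
#' For every one-factor settings family: the COV of the feature across
#' the family's settings is computed per lesion, then averaged over
#' lesions. The representative COV per feature is the worst (highest)
#' family COV; classes: stable (<= 5%), quite stable (5-10%), poorly
#' stable (10-20%), unstable (> 20%), and the quite-stable flag is
#' representative COV <= 10%. Features with near-zero mean use |mean|
#' and are flagged.
#'
#' @param features_by_setting named list of lesion x feature matrices,
#'   one per reconstruction setting.
#' @param families named character: family label per setting (names match
#'   `features_by_setting`); settings of a family must number >= 2.
#' @return data.frame `feature`, one `cov_<family>` column per family,
#'   `cov_worst`, `stability_class`, `quite_stable`, `abs_mean_flag`.
#' @export
cov_stability <- function(features_by_setting, families) {
  mats <- lapply(features_by_setting, as_feature_matrix)
  if (is.null(names(mats)) || !all(names(mats) %in% names(families)))
    stop("settings and family labels must share names")
  feats <- colnames(mats[[1]])
  fam_levels <- unique(unname(families[names(mats)]))
  cov_fam <- matrix(NA_real_, length(feats), length(fam_levels),
                    dimnames = list(feats, fam_levels))
  flag <- setNames(rep(FALSE, length(feats)), feats)
  for (fam in fam_levels) {
    members <- names(mats)[families[names(mats)] == fam]
    if (length(members) < 2) stop("family '", fam, "' has < 2 settings")
    for (f in feats) {
      y <- matrix(unlist(lapply(mats[members], function(m) m[, f])),
                  nrow = nrow(mats[[1]]))
      mns <- rowMeans(y)
      sds <- apply(y, 1, stats::sd)
      near0 <- abs(mns) < 1e-12
      if (any(mns < 0) || any(near0)) flag[f] <- TRUE
      covs <- ifelse(near0, NA_real_, 100 * sds / abs(mns))
      cov_fam[f, fam] <- mean(covs, na.rm = TRUE)
    }
  }
  worst <- apply(cov_fam, 1, max)
  cls <- stability_class_of(worst)
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (fam in fam_levels) out[[paste0("cov_", fam)]] <- unname(cov_fam[, fam])
  out$cov_worst <- unname(worst)
  out$stability_class <- as.character(cls)
  out$quite_stable <- unname(worst) <= 10
  out$abs_mean_flag <- unname(flag)
  out
}

## one-way random single-measure ICC(1,1); x = subjects x raters
icc11 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  row_m <- rowMeans(x)
  msb <- k * sum((row_m - mu)^2) / (n - 1)
  msw <- sum((x - row_m)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw <= 0) return(NA_real_)
  (msb - msw) / (msb + (k - 1) * msw)
}

## two-way mixed consistency ICC(3,1)
icc31 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msb <- k * sum((row_m - mu)^2) / (n - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msb + (k - 1) * mse <= 0) return(NA_real_)
  (msb - mse) / (msb + (k - 1) * mse)
}

#' Test-retest reproducibility (intraclass correlation)
#'
#' Per-feature ICC between paired test and retest feature values. The
#' default form is the one-way random single-measure ICC(1,1), sensitive
#' to systematic shifts; ICC(3,1) (two-way consistency, shift-invariant)
#' is available via `form`. When two test-retest dataset pairs are given
#' the reproducible flag requires ICC > `cut` in both; with one pair, in
#' that pair. Zero between-lesion variance makes the ICC undefined: NA,
#' flagged non-reproducible.
#'
#' @param test,retest lesion x feature matrices of the first pair.
#' @param test2,retest2 optional second pair.
#' @param form `"ICC11"` or `"ICC31"`.
#' @param cut reproducibility cut-off (0.6).
#' @return data.frame `feature`, `icc_test1`, `icc_test2` (NA if absent),
#'   `reproducible`.
#' @export
icc_reproducibility <- function(test, retest, test2 = NULL, retest2 = NULL,
                                form = c("ICC11", "ICC31"), cut = 0.6) {
  form <- match.arg(form)
  fun <- if (form == "ICC11") icc11 else icc31
  t1 <- as_feature_matrix(test); r1 <- as_feature_matrix(retest)
  stopifnot(identical(dim(t1), dim(r1)))
  if (nrow(t1) < 5) stop("need at least 5 paired lesions")
  feats <- colnames(t1)
  i1 <- vapply(feats, function(f) fun(cbind(t1[, f], r1[, f])), numeric(1))
  i2 <- rep(NA_real_, length(feats))
  if (!is.null(test2)) {
    t2 <- as_feature_matrix(test2); r2 <- as_feature_matrix(retest2)
    i2 <- vapply(feats, function(f) fun(cbind(t2[, f], r2[, f])), numeric(1))
  }
  rep_flag <- !is.na(i1) & i1 > cut &
    (if (is.null(test2)) TRUE else !is.na(i2) & i2 > cut)
  data.frame(feature = feats, icc_test1 = unname(i1), icc_test2 = unname(i2),
             reproducible = unname(rep_flag), stringsAsFactors = FALSE)
}

#' Heterogeneous versus homogeneous discrimination (Mann-Whitney)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature between
#' lesions with homogeneous and heterogeneous uptake; discriminative
#' when p < 0.05. All-tied features give p = 1 (tie correction applies).
#'
#' @param features_hom,features_het lesion x feature matrices.
#' @param alpha significance level.
#' @return data.frame `feature`, `p`, `discriminative`.
#' @export
heterogeneity_discrimination <- function(features_hom, features_het,
                                         alpha = 0.05) {
  a <- as_feature_matrix(features_hom); b <- as_feature_matrix(features_het)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be nonempty")
  feats <- colnames(a)
  p <- vapply(feats, function(f) {
    x <- a[, f]; y <- b[, f]
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  data.frame(feature = feats, p = unname(p), discriminative = unname(p) < alpha,
             stringsAsFactors = FALSE)
}

#' Correlation of features with the ground-truth heterogeneity index
#'
#' Spearman rank correlation (default; Pearson via `method`) between each
#' feature and H_GS over the heterogeneous lesions; significantly
#' correlated when p < 0.05. Constant features have undefined correlation
#' and are flagged.
#'
#' @param features_het lesion x feature matrix (heterogeneous lesions).
#' @param h_gs H_GS value per lesion.
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha significance level.
#' @return data.frame `feature`, `rho`, `p`, `correlated`, `constant`.
#' @export
hgs_correlation <- function(features_het, h_gs, method = c("spearman", "pearson"),
                            alpha = 0.05) {
  method <- match.arg(method)
  m <- as_feature_matrix(features_het)
  if (nrow(m) < 5) stop("need at least 5 heterogeneous lesions")
  stopifnot(nrow(m) == length(h_gs))
  feats <- colnames(m)
  res <- lapply(feats, function(f) {
    x <- m[, f]
    if (stats::sd(x) == 0)
      return(data.frame(feature = f, rho = NA_real_, p = NA_real_,
                        correlated = FALSE, constant = TRUE))
    ct <- suppressWarnings(stats::cor.test(x, h_gs, method = method,
                                           exact = FALSE))
    data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value,
               correlated = ct$p.value < alpha, constant = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Agreement of the Sphericity feature with ground truth
#'
#' Two-sided paired t-test between the measured morphological Sphericity
#' and the ground-truth sphericity, plus the mean bias. Necrotic lesions
#' must be excluded upstream (the active-surface ground truth is
#' undefined for them).
#'
#' @param sphericity_feature measured values.
#' @param s_gs paired ground-truth values.
#' @return list `p`, `mean_difference`, `n`.
#' @export
sphericity_agreement <- function(sphericity_feature, s_gs) {
  stopifnot(length(sphericity_feature) == length(s_gs))
  if (length(s_gs) < 3) stop("need at least 3 paired lesions")
  d <- sphericity_feature - s_gs
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    ## degenerate paired data: exact agreement -> no evidence of bias;
    ## constant nonzero shift -> unambiguous bias
    p <- if (abs(mean(d)) < .Machine$double.eps^0.5) 1 else 0
    return(list(p = p, mean_difference = mean(d), n = length(d)))
  }
  tt <- stats::t.test(sphericity_feature, s_gs, paired = TRUE)
  list(p = tt$p.value, mean_difference = unname(tt$estimate), n = length(d))
}

#' Assemble the per-feature stability report
#'
#' Joins the outputs of the battery into one row per feature and a
#' summary block with the fractions of features stable versus
#' segmentation, COV-stable, reproducible, discriminative and
#' H_GS-correlated, plus the intersection funnel (reproducible, also
#' discriminative, also correlated). Benjamini-Hochberg adjusted p-value
#' columns are added for transparency; flags use the raw per-feature
#' p < 0.05 readout. Pure function of its inputs.
#'
#' @param friedman output of [friedman_stability()] (or NULL).
#' @param cov output of [cov_stability()] (or NULL).
#' @param icc output of [icc_reproducibility()] (or NULL).
#' @param mw output of [heterogeneity_discrimination()] (or NULL).
#' @param hgs output of [hgs_correlation()] (or NULL).
#' @return list of class `stability_report`: `table` (one row per
#'   feature), `summary` (named fractions/counts), `funnel` (counts).
#' @export
build_report <- function(friedman = NULL, cov = NULL, icc = NULL, mw = NULL,
                         hgs = NULL) {
  parts <- Filter(Negate(is.null), list(friedman, cov, icc, mw, hgs))
  if (!length(parts)) stop("no analysis outputs supplied")
  feats <- parts[[1]]$feature
  for (p in parts) if (!identical(p$feature, feats))
    stop("feature registry mismatch across analyses")
  tab <- data.frame(feature = feats, stringsAsFactors = FALSE)
  if (!is.null(friedman)) {
    tab$friedman_p <- friedman$p
    tab$friedman_p_bh <- stats::p.adjust(friedman$p, "BH")
    tab$segmentation_stable <- friedman$stable
  }
  if (!is.null(cov)) {
    tab <- cbind(tab, cov[, setdiff(names(cov), "feature"), drop = FALSE])
  }
  if (!is.null(icc)) {
    tab$icc_test1 <- icc$icc_test1
    tab$icc_test2 <- icc$icc_test2
    tab$reproducible <- icc$reproducible
  }
  if (!is.null(mw)) {
    tab$mw_p <- mw$p
    tab$mw_p_bh <- stats::p.adjust(mw$p, "BH")
    tab$discriminative <- mw$discriminative
  }
  if (!is.null(hgs)) {
    tab$hgs_rho <- hgs$rho
    tab$hgs_p <- hgs$p
    tab$hgs_p_bh <- stats::p.adjust(hgs$p, "BH")
    tab$hgs_correlated <- hgs$correlated
  }
  n <- length(feats)
  frac <- function(x) if (is.null(x)) NA_real_ else mean(x)
  summary <- c(
    n_features = n,
    frac_segmentation_stable = frac(tab$segmentation_stable),
    frac_cov_quite_stable = frac(tab$quite_stable),
    frac_reproducible = frac(tab$reproducible),
    frac_discriminative = frac(tab$discriminative),
    frac_hgs_correlated = frac(tab$hgs_correlated))
  funnel <- c(reproducible = NA_integer_, and_discriminative = NA_integer_,
              and_correlated = NA_integer_)
  if (!is.null(icc)) {
    funnel["reproducible"] <- sum(tab$reproducible)
    if (!is.null(mw)) {
      f2 <- tab$reproducible & tab$discriminative
      funnel["and_discriminative"] <- sum(f2)
      if (!is.null(hgs))
        funnel["and_correlated"] <- sum(f2 & tab$hgs_correlated)
    }
  }
  structure(list(table = tab, summary = summary, funnel = funnel),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", nrow(x$table), "features\n")
  s <- x$summary
  for (nm in names(s)) if (!is.na(s[[nm]]))
    cat(sprintf("  %s: %.3g\n", nm, s[[nm]]))
  if (!all(is.na(x$funnel)))
    cat("  funnel:", paste(names(x$funnel), x$funnel, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}
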