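## Feature registry and full extraction ----------------------------------

#' The 58-feature registry
#'
#' One row per radiomic feature in extraction order: 5 morphological
#' (IF_M), 13 histogram (IF_HIST), 9 GLCM, 13 GLRLM, 13 GLSZM and 5
#' NGTDM. `name` is the feature's display name, `group` its family and
#' `qualified` the unique column name (`<group tag>_<short name>`) used
#' in feature vectors and CSV output, since several display names
#' (Energy, Entropy, Variance, GLN, GLV) recur across groups.
#'
#' @return data.frame with columns `group`, `name`, `qualified`.
#' @export
feature_registry <- function() {
  short <- function(x) {
    ## use the parenthesized abbreviation when present
    m <- regexpr("\\(([^)]+)\\)", x)
    hit <- m > 0
    ab <- character(length(x))
    ab[hit] <- substring(x[hit], m[hit] + 1,
                         m[hit] + attr(m, "match.length")[hit] - 2)
    ifelse(hit, ab, gsub("[^A-Za-z]", "", x))
  }
  grp <- function(group, tag, names) {
    data.frame(group = group, name = names,
               qualified = paste0(tag, "_", short(names)),
               stringsAsFactors = FALSE)
  }
  rbind(
    grp("IF_M", "M", c("MTV", "Surface", "Spherical disproportion",
                       "Sphericity", "Surface-volume ratio (SV)")),
    grp("IF_HIST", "HIST",
        c("Maximum", "Minimum", "Mean", "Median",
          "Mean absolute deviation (MAD)", "Root mean square (RMS)",
          "Energy", "Entropy", "Kurtosis", "Skewness",
          "Standard deviation", "Uniformity", "Variance")),
    grp("IF_TX-GLCM", "GLCM",
        c("Energy", "Contrast", "Entropy", "Homogeneity", "Correlation",
          "SumAverage", "Variance", "Dissimilarity", "Autocorrelation")),
    grp("IF_TX-GLRLM", "GLRLM",
        c("Short run emphasis (SRE)", "Long run emphasis (LRE)",
          "Gray-level nonuniformity (GLN)", "Run-length nonuniformity (RLN)",
          "Run percentage (RP)", "Low gray-level run emphasis (LGRE)",
          "High gray-level run emphasis (HGRE)",
          "Short run low gray-level emphasis (SRLGE)",
          "Short run high gray-level emphasis (SRHGE)",
          "Long run low gray-level emphasis (LRLGE)",
          "Long run high gray-level emphasis (LRHGE)",
          "Gray-level variance (GLV)", "Run-length variance (RLV)")),
    grp("IF_TX-GLSZM", "GLSZM",
        c("Small zone emphasis (SZE)", "Large zone emphasis (LZE)",
          "Gray-level nonuniformity (GLN)", "Zone-size nonuniformity (ZSN)",
          "Zone percentage (ZP)", "Low gray-level zone emphasis (LGZE)",
          "High gray-level zone emphasis (HGZE)",
          "Small zone low gray-level emphasis (SZLGE)",
          "Small zone high gray-level emphasis (SZHGE)",
          "Large zone low gray-level emphasis (LZLGE)",
          "Large zone high gray-level emphasis (LZHGE)",
          "Gray-level variance (GLV)", "Zone-size variance (ZSV)")),
    grp("IF_TX-NGTDM", "NGTDM",
        c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")))
}

#' Extract the full 58-feature vector from a segmented lesion
#'
#' Runs the whole preprocessing and extraction chain: isotropic
#' resampling (to the in-plane pixel size), 64-level discretization of
#' the masked content, then the five feature groups. Returns exactly 58
#' named values (names = `feature_registry()$qualified`); degenerate
#' groups yield their documented sentinels and are flagged rather than
#' dropped, so cohort tables stay rectangular.
#'
#' @param image an `activity_volume`.
#' @param mask logical array on the image grid, or a
#'   `segmentation_mask`.
#' @param n_levels gray levels for discretization (64).
#' @return named numeric of length 58; attributes `flags` (named logical
#'   of per-group degeneracy) and `registry`.
#' @export
#' @examples
#' v <- activity_volume(array(rlnorm(8000), c(20, 20, 20)), spacing = c(2, 2, 2))
#' m <- array(FALSE, c(20, 20, 20)); m[5:15, 5:15, 5:15] <- TRUE
#' f <- extract_all(v, m)
#' length(f)  # 58
extract_all <- function(image, mask, n_levels = 64L) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  rs <- resample_isotropic(image, mask)
  img <- rs$image; msk <- rs$mask
  if (!any(msk)) stop("mask vanished under resampling")
  disc <- discretize(img, msk, n_levels = n_levels)
  groups <- list(
    morph = morphological_features(msk, img$spacing),
    hist = histogram_features(img, msk, disc),
    glcm = glcm_features(disc),
    glrlm = glrlm_features(disc),
    glszm = glszm_features(disc),
    ngtdm = ngtdm_features(disc))
  reg <- feature_registry()
  out <- unlist(unname(lapply(groups, as.numeric)))
  stopifnot(length(out) == nrow(reg))
  names(out) <- reg$qualified
  attr(out, "flags") <- vapply(groups, function(g)
    isTRUE(attr(g, "degenerate")), logical(1))
  out
}
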