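## Ground-truth uptake configurations and heterogeneity indices ----------

#' Specify a lesion uptake configuration
#'
#' The seven layouts mirror the compartment strategies used for
#' heterogeneous lesions: `a`-`c` place a zero-uptake (necrotic)
#' compartment inside the active volume (concentric core, eccentric blob,
#' polar cap), `d`-`e` place one or two high-uptake foci (C2 = 5*C1 by
#' default), and `f`-`g` combine a high-uptake focus with a concentric or
#' eccentric necrosis. `uniform` is the homogeneous case.
#'
#' @param layout one of `"uniform"`, `"a"` ... `"g"`.
#' @param c1 base activity concentration, MBq/cc.
#' @param c2 high-uptake concentration, MBq/cc; defaults to `5 * c1`.
#' @param volume_fractions named fractions for the compartments present
#'   (names among `c0`, `c1`, `c2`), summing to 1. Defaults depend on the
#'   layout.
#' @return object of class `uptake_config`.
#' @export
#' @examples
#' uptake_config("d", c1 = 0.05, volume_fractions = c(c1 = 0.7, c2 = 0.3))
uptake_config <- function(layout = "uniform", c1 = 0.05, c2 = 5 * c1,
                          volume_fractions = NULL) {
  layout <- match.arg(layout, c("uniform", letters[1:7]))
  has_necrosis <- layout %in% c("a", "b", "c", "f", "g")
  has_c2 <- layout %in% c("d", "e", "f", "g")
  if (is.null(volume_fractions)) {
    volume_fractions <- switch(layout,
      uniform = c(c1 = 1),
      a = , b = , c = c(c0 = 0.2, c1 = 0.8),
      d = , e = c(c1 = 0.7, c2 = 0.3),
      f = , g = c(c0 = 0.15, c1 = 0.6, c2 = 0.25))
  }
  want <- c(if (has_necrosis) "c0", "c1", if (has_c2) "c2")
  if (!setequal(names(volume_fractions), want))
    stop("layout '", layout, "' needs fractions named: ",
         paste(want, collapse = ", "))
  volume_fractions <- volume_fractions[want]
  if (any(volume_fractions < 0))
    stop("volume fractions must be >= 0")
  if (abs(sum(volume_fractions) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  stopifnot(c1 > 0, c2 > 0)
  structure(list(layout = layout, c1 = c1, c2 = c2,
                 has_necrosis = has_necrosis,
                 volume_fractions = volume_fractions),
            class = "uptake_config")
}

## concentrations (MBq/cc) matching the fraction vector order
config_concentrations <- function(config) {
  cc <- c(c0 = 0, c1 = config$c1, c2 = config$c2)
  unname(cc[names(config$volume_fractions)])
}

#' Ground-truth sphericity index
#'
#' Ratio between the surface of the volume-equivalent sphere and the
#' actual surface: `pi^(1/3) * (6 V)^(2/3) / S`. 1 for a perfect sphere,
#' decreasing towards 0 with increasing shape irregularity.
#'
#' @param volume_cc volume, cc.
#' @param surface_cm2 surface, cm^2 (any length unit works if consistent:
#'   V in u^3 and S in u^2).
#' @return dimensionless sphericity.
#' @export
#' @examples
#' r <- 1.2
#' compute_sphericity_gs(4 * pi * r^3 / 3, 4 * pi * r^2)  # exactly 1
compute_sphericity_gs <- function(volume_cc, surface_cm2) {
  if (any(volume_cc <= 0) || any(surface_cm2 <= 0))
    stop("volume and surface must be positive")
  pi^(1 / 3) * (6 * volume_cc)^(2 / 3) / surface_cm2
}

#' Ground-truth uptake coefficient of variation (percent)
#'
#' Population standard deviation over mean of the activity concentration
#' across the lesion volume, weighted by compartment volume fractions,
#' times 100. Necrotic compartments (zero concentration) participate.
#'
#' @param config an [uptake_config()].
#' @return COV in percent.
#' @export
compute_cov_gs <- function(config) {
  stopifnot(inherits(config, "uptake_config"))
  f <- config$volume_fractions
  cc <- config_concentrations(config)
  m <- sum(f * cc)
  if (m <= 0) stop("all-necrotic lesion: mean concentration is zero")
  v <- sum(f * (cc - m)^2)
  100 * sqrt(v) / m
}

#' Ground-truth Gini heterogeneity index
#'
#' Normalized categorical heterogeneity of the voxelwise distribution of
#' distinct concentration modalities: `(1 - sum(p_i^2)) * k / (k - 1)` for
#' `k >= 2` modalities, 0 for a single modality. Ranges from 0 (minimal)
#' to 1 (maximal heterogeneity, reached at uniform frequencies).
#'
#' @param config an [uptake_config()], or a numeric vector of modality
#'   relative frequencies summing to 1.
#' @return Gini index in `[0, 1]`.
#' @export
#' @examples
#' compute_gini_gs(c(0.5, 0.5))  # 1
#' compute_gini_gs(c(0.9, 0.1))  # 0.36
compute_gini_gs <- function(config) {
  if (inherits(config, "uptake_config")) {
    f <- config$volume_fractions
    cc <- config_concentrations(config)
    ## merge equal concentrations into single modalities
    p <- as.numeric(tapply(f, factor(cc), sum))
  } else {
    p <- as.numeric(config)
  }
  p <- p[p > 0]
  if (length(p) == 0) stop("at least one modality required")
  if (abs(sum(p) - 1) > 1e-9)
    stop("modality frequencies must sum to 1")
  k <- length(p)
  if (k == 1) return(0)
  (1 - sum(p^2)) * k / (k - 1)
}

#' Ground-truth total heterogeneity index
#'
#' Product of the uptake COV (percent) and the Gini index; 0 for
#' homogeneous lesions, up to 100 for two-level C/5C configurations.
#'
#' @param cov COV in percent (>= 0).
#' @param gini Gini index in `[0, 1]`.
#' @return H index.
#' @export
compute_h_gs <- function(cov, gini) {
  stopifnot(cov >= 0, gini >= -1e-12, gini <= 1 + 1e-12)
  cov * gini
}

## Compartment carving ----------------------------------------------------
##
## Assigns compartment labels inside a shell so realized voxel fractions
## match the requested ones exactly (quantile-based region growing keeps
## sub-regions connected: sublevel sets of the radial field are
## star-shaped, balls around interior points are convex).

## labels: 0 outside, 1 C1, 2 C2, 3 necrosis (C0)
carve_compartments <- function(shell, config) {
  lab <- shell$labels
  inside <- which(lab == 1L)
  n <- length(inside)
  phi <- shell$phi
  d <- dim(lab)
  ijk <- arrayInd(inside, d)
  xyz <- sweep(sweep(ijk - 1, 2, shell$spacing, "*"), 2, shell$origin, "+")
  f <- config$volume_fractions
  lay <- config$layout
  pick_deep <- function(frac) {
    ## deepest voxels (most negative phi): concentric core
    k <- round(frac * n)
    if (k == 0) return(integer(0))
    inside[order(phi[inside])[seq_len(k)]]
  }
  pick_ball <- function(frac, centre) {
    k <- round(frac * n)
    if (k == 0) return(integer(0))
    d2 <- rowSums(sweep(xyz, 2, centre, "-")^2)
    inside[order(d2)[seq_len(k)]]
  }
  pick_cap <- function(frac, axis) {
    k <- round(frac * n)
    if (k == 0) return(integer(0))
    proj <- xyz %*% axis
    inside[order(-proj)[seq_len(k)]]
  }
  ## deterministic interior anchors derived from the shape seed
  anchors <- with_seed(child_seed(shell$spec$seed, 7L), {
    a <- matrix(rnorm(9), 3, 3)
    a / sqrt(rowSums(a^2))
  })
  deep_centre <- xyz[which.min(phi[inside]), ]
  off <- function(k, scale = 0.45) deep_centre * 0 + anchors[k, ] * scale * shell$spec$base_radius
  set1 <- function(vox, value) lab[vox] <<- value
  if (lay == "uniform") {
    ## nothing to carve
  } else if (lay == "a") {
    set1(pick_deep(f[["c0"]]), 3L)
  } else if (lay == "b") {
    set1(pick_ball(f[["c0"]], off(1)), 3L)
  } else if (lay == "c") {
    set1(pick_cap(f[["c0"]], anchors[1, ]), 3L)
  } else if (lay == "d") {
    set1(pick_ball(f[["c2"]], off(1)), 2L)
  } else if (lay == "e") {
    set1(pick_ball(f[["c2"]] / 2, off(1)), 2L)
    free <- intersect(inside, which(lab == 1L))
    k <- round(f[["c2"]] * n) - sum(lab == 2L)
    if (k > 0) {
      d2 <- rowSums(sweep(xyz, 2, -off(1), "-")^2)
      ord <- order(d2)
      cand <- inside[ord]
      cand <- cand[lab[cand] == 1L][seq_len(k)]
      set1(cand, 2L)
    }
  } else if (lay == "f") {
    set1(pick_deep(f[["c0"]]), 3L)
    free <- which(lab == 1L)
    k <- round(f[["c2"]] * n)
    d2 <- rowSums(sweep(xyz, 2, off(1), "-")^2)
    cand <- inside[order(d2)]
    cand <- cand[lab[cand] == 1L]
    set1(cand[seq_len(min(k, length(cand)))], 2L)
  } else if (lay == "g") {
    set1(pick_ball(f[["c0"]], off(1)), 3L)
    k <- round(f[["c2"]] * n)
    d2 <- rowSums(sweep(xyz, 2, off(2), "-")^2)
    cand <- inside[order(d2)]
    cand <- cand[lab[cand] == 1L]
    set1(cand[seq_len(min(k, length(cand)))], 2L)
  }
  lab
}

#' Build a phantom lesion with full ground truth
#'
#' Carves the uptake compartments into a shell and computes every
#' ground-truth index: volumes, sphericity, COV, Gini, total
#' heterogeneity and lesion-to-background ratio. Ground-truth COV/Gini
#' use the realized voxel fractions of the carved compartments (the
#' nominal, pre-blur concentrations — not image values).
#'
#' @param shell a `lesion_shell`.
#' @param config an [uptake_config()].
#' @param background background activity concentration, MBq/cc.
#' @return object of class `phantom_lesion` with `shell`, `config`,
#'   `labels` (0 bg / 1 C1 / 2 C2 / 3 necrosis), `background` and
#'   `ground_truth` (a `lesion_ground_truth`).
#' @export
phantom_lesion <- function(shell, config, background = 0.0065) {
  stopifnot(inherits(shell, "lesion_shell"), inherits(config, "uptake_config"),
            background > 0)
  labels <- carve_compartments(shell, config)
  n <- sum(labels > 0L)
  realized <- c(c0 = sum(labels == 3L) / n,
                c1 = sum(labels == 1L) / n,
                c2 = sum(labels == 2L) / n)
  realized <- realized[names(config$volume_fractions)]
  cfg <- uptake_config(config$layout, c1 = config$c1, c2 = config$c2,
                       volume_fractions = realized / sum(realized))
  cov <- compute_cov_gs(cfg)
  gini <- compute_gini_gs(cfg)
  vvox <- prod(shell$spacing) / 1000
  v_gs <- shell$volume_cc
  necro_frac <- if ("c0" %in% names(realized)) realized[["c0"]] else 0
  v_active <- v_gs * (1 - necro_frac)
  conc <- config_concentrations(cfg)
  fr <- cfg$volume_fractions
  active <- conc > 0
  mean_active <- sum(fr[active] * conc[active]) / sum(fr[active])
  gt <- structure(list(
    v_gs = v_gs, v_gs_active = v_active, s_gs = shell$sphericity,
    cov_gs = cov, gini_gs = gini, h_gs = compute_h_gs(cov, gini),
    lb_gs = mean_active / background, layout = cfg$layout,
    seed = shell$spec$seed), class = "lesion_ground_truth")
  structure(list(shell = shell, config = cfg, labels = labels,
                 background = background, ground_truth = gt),
            class = "phantom_lesion")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.phantom_lesion <- function(x, ...) {
  g <- x$ground_truth
  cat(sprintf(
    "<phantom_lesion> layout %s: V = %.2f cc (active %.2f), S = %.3f, COV = %.1f%%, Gini = %.3f, H = %.1f, L/B = %.1f\n",
    g$layout, g$v_gs, g$v_gs_active, g$s_gs, g$cov_gs, g$gini_gs, g$h_gs, g$lb_gs))
  invisible(x)
}
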