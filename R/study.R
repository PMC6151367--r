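## Default study cohort ---------------------------------------------------
##
## The default cohort reproduces the structure of the phantom study: nine
## acquisitions of five irregular shells (A-E, volumes 6.8-32.3 cc,
## sphericities 0.49-0.74), 38 lesions in total, 20 with uniform uptake
## and 18 heterogeneous with printed total-heterogeneity values between
## 12.7 and 62.2 and lesion-to-background ratios between 4 and 27. For
## heterogeneous lesions the necrosis fraction follows from the printed
## active volume, and the high-uptake (5xC1) compartment fraction is
## solved so the generated H_GS matches the printed value.

#' The per-lesion cohort template of the default study
#'
#' @return data.frame with one row per lesion: `acq`, `lesion_id`,
#'   `shell_id`, `v_gs`, `s_gs`, `h_gs`, `v_active`, `lb`.
#' @export
study_cohort_template <- function() {
  shells <- data.frame(
    shell_id = c("A", "B", "C", "D", "E"),
    v_gs = c(6.8, 10.5, 8.5, 12.5, 32.3),
    s_gs = c(0.57, 0.62, 0.49, 0.74, 0.73))
  row <- function(acq, shell, h, v_act, lb) {
    i <- match(shell, shells$shell_id)
    data.frame(acq = acq, shell_id = shell, v_gs = shells$v_gs[i],
               s_gs = shells$s_gs[i], h_gs = h, v_active = v_act, lb = lb)
  }
  tmpl <- rbind(
    row(1, "A", 0, 6.8, 10), row(1, "B", 0, 10.5, 10),
    row(1, "C", 0, 8.5, 10), row(1, "D", 0, 12.5, 10),
    row(2, "A", 0, 6.8, 10), row(2, "B", 0, 10.5, 10),
    row(2, "C", 0, 8.5, 10), row(2, "D", 0, 12.5, 10),
    row(3, "A", 0, 6.8, 10), row(3, "B", 0, 10.5, 10),
    row(3, "C", 0, 8.5, 10), row(3, "D", 0, 12.5, 10),
    row(4, "A", 0, 6.8, 27), row(4, "B", 0, 10.5, 26),
    row(4, "C", 21.1, 7.4, 9), row(4, "D", 12.7, 11.7, 25),
    row(5, "A", 0, 6.8, 27), row(5, "B", 0, 10.5, 26),
    row(5, "C", 21.1, 7.4, 9), row(5, "D", 12.7, 11.7, 25),
    row(6, "A", 0, 6.8, 27), row(6, "B", 0, 10.5, 26),
    row(6, "C", 21.1, 7.4, 9), row(6, "D", 12.7, 11.7, 25),
    row(7, "A", 0, 6.8, 12), row(7, "B", 0, 10.5, 11),
    row(7, "C", 21.1, 7.4, 4), row(7, "D", 12.7, 11.7, 11),
    row(8, "A", 14.9, 6.4, 18), row(8, "B", 26.2, 10.5, 10),
    row(8, "C", 24.8, 7.6, 7), row(8, "D", 62.2, 8.7, 9),
    row(8, "E", 16.3, 29.4, 25),
    row(9, "A", 14.9, 6.4, 12), row(9, "B", 26.2, 10.5, 7),
    row(9, "C", 24.8, 7.6, 5), row(9, "D", 62.2, 8.7, 6),
    row(9, "E", 16.3, 29.4, 16))
  tmpl$lesion_id <- seq_len(nrow(tmpl))
  tmpl[, c("acq", "lesion_id", "shell_id", "v_gs", "s_gs", "h_gs",
           "v_active", "lb")]
}

## H_GS of a (p0, p2) configuration at concentrations (0, C, 5C);
## scale-free in C
h_of_fractions <- function(p0, p2) {
  p1 <- 1 - p0 - p2
  f <- c(p0, p1, p2)
  cc <- c(0, 1, 5)
  keep <- f > 1e-12
  f <- f[keep]; cc <- cc[keep]
  m <- sum(f * cc)
  cov <- 100 * sqrt(sum(f * (cc - m)^2)) / m
  k <- length(f)
  gini <- if (k == 1) 0 else (1 - sum(f^2)) * k / (k - 1)
  cov * gini
}

## pick the high-uptake fraction p2 whose H is closest to the target,
## given the (volume-determined) necrosis fraction p0
solve_c2_fraction <- function(p0, target_h) {
  if (target_h <= 0) return(0)
  grid <- seq(0.002, 1 - p0 - 0.002, length.out = 500)
  h <- vapply(grid, function(p2) h_of_fractions(p0, p2), numeric(1))
  grid[which.min(abs(h - target_h))]
}

#' Build the phantom lesion cohort
#'
#' Generates the five seeded shells (deformation amplitude calibrated to
#' each sphericity target, base radius scaled to each volume) and the 38
#' lesions of the default template, with per-lesion uptake configuration,
#' background level and full ground truth; optionally simulates the
#' default acquisition of every lesion. Deterministic given `seed`.
#'
#' @param seed master seed.
#' @param n_lesions number of lesions (prefix of the template, <= 38).
#' @param resolution ground-truth rasterization step, mm.
#' @param simulate also return a default-settings `activity_volume` per
#'   lesion.
#' @param settings acquisition settings used when `simulate = TRUE`
#'   (per-lesion noise seeds are derived from `seed`).
#' @return list of class `phantom_study`: `lesions` (list of
#'   `phantom_lesion`), `ground_truth` (data.frame, one row per lesion),
#'   `volumes` (list or NULL), `template`, `seed`.
#' @export
build_study <- function(seed = 1L, n_lesions = 38L, resolution = 1.5,
                        simulate = FALSE, settings = acquisition_settings()) {
  tmpl <- utils::head(study_cohort_template(), n_lesions)
  shell_ids <- unique(tmpl$shell_id)
  shells <- list()
  for (sid in shell_ids) {
    i <- match(sid, tmpl$shell_id)
    shells[[sid]] <- shell_for_sphericity(
      tmpl$s_gs[i], tmpl$v_gs[i],
      seed = child_seed(seed, 10L + match(sid, c("A", "B", "C", "D", "E"))),
      resolution = resolution)
  }
  c1_draw <- with_seed(child_seed(seed, 2L),
                       stats::runif(nrow(tmpl), 0.03, 0.16))
  lesions <- vector("list", nrow(tmpl))
  gt_rows <- vector("list", nrow(tmpl))
  for (r in seq_len(nrow(tmpl))) {
    tr <- tmpl[r, ]
    sh <- shells[[tr$shell_id]]
    c1 <- c1_draw[r]
    if (tr$h_gs <= 0) {
      cfg <- uptake_config("uniform", c1 = c1)
      mean_active <- c1
    } else {
      p0 <- max(0, 1 - tr$v_active / tr$v_gs)
      p2 <- solve_c2_fraction(p0, tr$h_gs)
      if (p0 > 1e-6) {
        layout <- if (tr$shell_id %in% c("A", "C")) "f" else "g"
        fr <- c(c0 = p0, c1 = 1 - p0 - p2, c2 = p2)
      } else {
        layout <- if (tr$shell_id %in% c("B", "D")) "d" else "e"
        fr <- c(c1 = 1 - p2, c2 = p2)
      }
      cfg <- uptake_config(layout, c1 = c1, volume_fractions = fr)
      conc <- config_concentrations(cfg)
      act <- conc > 0
      mean_active <- sum(cfg$volume_fractions[act] * conc[act]) /
        sum(cfg$volume_fractions[act])
    }
    background <- mean_active / tr$lb
    pl <- phantom_lesion(sh, cfg, background = background)
    lesions[[r]] <- pl
    g <- pl$ground_truth
    gt_rows[[r]] <- data.frame(
      lesion_id = tr$lesion_id, shell_id = tr$shell_id, acq = tr$acq,
      v_gs_cc = g$v_gs, v_gs_active_cc = g$v_gs_active, s_gs = g$s_gs,
      cov_gs_pct = g$cov_gs, gini_gs = g$gini_gs, h_gs = g$h_gs,
      lb_gs = g$lb_gs, layout = g$layout, seed = g$seed,
      stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, gt_rows)
  volumes <- NULL
  if (simulate) {
    volumes <- lapply(seq_along(lesions), function(r) {
      s <- settings
      s$seed <- child_seed(seed, 1000L + r)
      suppressWarnings(simulate_acquisition(lesions[[r]], s))
    })
  }
  structure(list(lesions = lesions, ground_truth = gt, volumes = volumes,
                 template = tmpl, seed = as.integer(seed)),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<phantom_study> %d lesions (%d homogeneous), V %.1f-%.1f cc, S %.2f-%.2f, L/B %.1f-%.1f\n",
              nrow(gt), sum(gt$h_gs == 0), min(gt$v_gs_cc), max(gt$v_gs_cc),
              min(gt$s_gs), max(gt$s_gs), min(gt$lb_gs), max(gt$lb_gs)))
  invisible(x)
}
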