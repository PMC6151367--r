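## MTV segmentation: fixed 60% and adaptive background-corrected threshold

## largest 26-connected component of a logical array (igraph backend)
largest_component <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1) return(mask)
  d <- dim(mask)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  dirs <- unique_directions_26()
  edges <- list()
  ijk <- arrayInd(idx, d)
  for (r in seq_len(nrow(dirs))) {
    nb <- sweep(ijk, 2, dirs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbl <- nb[ok, , drop = FALSE]
    j <- pos[cbind(nbl[, 1], nbl[, 2], nbl[, 3])]
    keep <- j > 0
    if (any(keep))
      edges[[length(edges) + 1]] <- cbind(pos[idx[ok]][keep], j[keep])
  }
  if (length(edges) == 0) {
    ## isolated voxels only: keep the first
    out <- array(FALSE, d); out[idx[1]] <- TRUE
    return(out)
  }
  e <- do.call(rbind, edges)
  gr <- igraph::graph_from_edgelist(e, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, length(idx) - igraph::vcount(gr)))
  comp <- igraph::components(gr)
  big <- which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[comp$membership == big]] <- TRUE
  out
}

new_segmentation <- function(mask, vol, method, converged = TRUE, threshold = NA) {
  structure(list(mask = mask, method = method,
                 mtv = sum(mask) * voxel_volume_cc(vol),
                 threshold = threshold, converged = converged),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> method %s: MTV = %.2f cc (%d voxels)\n",
              x$method, x$mtv, sum(x$mask)))
  invisible(x)
}

## seed_region: NULL (whole volume) or list(lo=, hi=) voxel index bounds
region_indices <- function(vol, seed_region) {
  d <- dim(vol$values)
  if (is.null(seed_region)) return(array(TRUE, d))
  lo <- pmax(1L, as.integer(seed_region$lo)); hi <- pmin(d, as.integer(seed_region$hi))
  if (any(hi < lo)) stop("empty seed region")
  reg <- array(FALSE, d)
  reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  reg
}

#' Fixed-threshold MTV segmentation (60% of maximum)
#'
#' Keeps voxels at or above `frac` (default 0.60) of the maximum uptake
#' within the seed region, then retains the largest 26-connected
#' component. The comparison is inclusive so the maximum voxel always
#' belongs to the MTV.
#'
#' @param image an `activity_volume`.
#' @param seed_region optional lesion bounding box,
#'   `list(lo = c(i, j, k), hi = c(i, j, k))` in voxel indices; NULL uses
#'   the whole volume.
#' @param frac threshold as a fraction of the regional maximum.
#' @return a `segmentation_mask` (method `"fixed60"`).
#' @export
fixed_threshold_segment <- function(image, seed_region = NULL, frac = 0.60) {
  reg <- region_indices(image, seed_region)
  mx <- max(image$values[reg])
  thr <- frac * mx
  mask <- image$values >= thr & reg
  if (!any(mask)) stop("empty segmentation result")
  new_segmentation(largest_component(mask), image, "fixed60", threshold = thr)
}

#' Calibrate the adaptive threshold coefficient on simulated spheres
#'
#' Simulates noiseless PSF-blurred spheres across diameters and
#' lesion-to-background levels and finds, per cell, the background
#' correction coefficient eps minimizing the MTV volume error when used
#' in the iterative adaptive rule `T = eps * (mean_mask - B) + B`. The
#' fitted table (with the measured lesion-to-background of the converged
#' mask, used as the lookup key at application time) drives
#' [adaptive_threshold_segment()].
#'
#' @param diameters_mm sphere diameters (>= 3 values).
#' @param lb_levels nominal lesion-to-background ratios (>= 3 values).
#' @param settings acquisition settings for the calibration images
#'   (noiseless by default).
#' @param seed base seed (calibration is deterministic given it).
#' @return data.frame of class `adaptive_calibration`: `diameter_mm`,
#'   `v_cc`, `lb_nominal`, `lb_meas`, `eps`, `pct_error`.
#' @export
calibrate_adaptive <- function(diameters_mm = c(12, 16, 20, 24, 28, 36),
                               lb_levels = c(3, 5, 8, 12, 20, 30),
                               settings = acquisition_settings(noise_scale = 0),
                               seed = 1L) {
  stopifnot(length(diameters_mm) >= 3, length(lb_levels) >= 3)
  rows <- list()
  for (dmm in diameters_mm) {
    vox <- settings$fov_mm / settings$matrix_size
    if (dmm / 2 < 2 * vox) {
      warning("sphere of diameter ", dmm, " mm unresolvable at ", vox,
              " mm voxels; skipped")
      next
    }
    v_cc <- pi / 6 * dmm^3 / 1000
    sh <- generate_shell(shell_spec(child_seed(seed, round(dmm)), dmm / 2, 0,
                                    resolution = min(1.5, dmm / 16)))
    for (lb in lb_levels) {
      c1 <- 0.05
      pl <- phantom_lesion(sh, uptake_config("uniform", c1 = c1),
                           background = c1 / lb)
      img <- suppressWarnings(simulate_acquisition(pl, settings))
      B <- pl$background
      vtrue <- pl$ground_truth$v_gs
      err_at <- function(eps) {
        m <- try(adaptive_iterate(img, NULL, B, function(v, l) eps),
                 silent = TRUE)
        if (inherits(m, "try-error")) return(list(err = 1e6))
        list(err = abs(m$mtv - vtrue) / vtrue, m = m)
      }
      ## golden-section search on eps
      lo <- 0.25; hi <- 0.95; gr <- (sqrt(5) - 1) / 2
      x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
      f1 <- err_at(x1)$err; f2 <- err_at(x2)$err
      for (it in 1:18) {
        if (f1 < f2) { hi <- x2; x2 <- x1; f2 <- f1
          x1 <- hi - gr * (hi - lo); f1 <- err_at(x1)$err
        } else { lo <- x1; x1 <- x2; f1 <- f2
          x2 <- lo + gr * (hi - lo); f2 <- err_at(x2)$err }
      }
      eps <- (lo + hi) / 2
      fit <- err_at(eps)
      lb_meas <- mean(img$values[fit$m$mask]) / B
      rows[[length(rows) + 1]] <- data.frame(
        diameter_mm = dmm, v_cc = v_cc, lb_nominal = lb, lb_meas = lb_meas,
        eps = eps, pct_error = 100 * (vtrue - fit$m$mtv) / vtrue)
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("adaptive_calibration", class(tab))
  tab
}

#' Load the calibration table shipped with the package
#' @return an `adaptive_calibration` data.frame.
#' @export
default_calibration <- function() {
  path <- system.file("extdata", "adaptive_calibration.csv",
                      package = "phantomrad", mustWork = TRUE)
  tab <- utils::read.csv(path)
  class(tab) <- c("adaptive_calibration", class(tab))
  tab
}

## interpolate eps at (v_cc, lb_meas): per diameter row interpolate over
## measured L/B, then across volumes (log scales, clamped at the borders)
interp_eps <- function(calib, v_cc, lb) {
  vs <- sort(unique(calib$v_cc))
  eps_v <- sapply(vs, function(v) {
    sub <- calib[calib$v_cc == v, ]
    sub <- sub[order(sub$lb_meas), ]
    if (nrow(sub) == 1) return(sub$eps)
    stats::approx(log(sub$lb_meas), sub$eps, xout = log(max(min(lb, max(sub$lb_meas)),
                                                            min(sub$lb_meas))),
                  rule = 2)$y
  })
  if (length(vs) == 1) return(eps_v[1])
  stats::approx(log(vs), eps_v,
                xout = log(max(min(v_cc, max(vs)), min(vs))), rule = 2)$y
}

## core adaptive iteration; eps_fun(v_cc, lb) supplies the coefficient
adaptive_iterate <- function(image, seed_region, background, eps_fun,
                             tol = 0.005, max_iter = 50) {
  reg <- region_indices(image, seed_region)
  vals <- image$values
  mx <- max(vals[reg])
  if (mx <= background) stop("no uptake above background in seed region")
  ## start from the fixed-50% mask
  mask <- vals >= background + 0.5 * (mx - background) & reg
  mask <- largest_component(mask)
  vcc <- sum(mask) * voxel_volume_cc(image)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m_up <- mean(vals[mask])
    lb <- m_up / background
    eps <- eps_fun(vcc, lb)
    thr <- eps * (m_up - background) + background
    new_mask <- vals >= thr & reg
    if (!any(new_mask)) stop("empty segmentation at threshold ", signif(thr, 4))
    new_mask <- largest_component(new_mask)
    new_v <- sum(new_mask) * voxel_volume_cc(image)
    done <- abs(new_v - vcc) <= tol * max(vcc, 1e-9)
    mask <- new_mask; vcc <- new_v
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    res <- new_segmentation(mask, image, "adaptive", converged = FALSE,
                            threshold = thr)
    cond <- structure(
      list(message = "adaptive segmentation did not converge",
           call = sys.call(-1), last = res),
      class = c("adaptive_nonconvergence", "error", "condition"))
    stop(cond)
  }
  new_segmentation(mask, image, "adaptive", threshold = thr)
}

#' Adaptive background-corrected MTV segmentation
#'
#' Iterative threshold `T_k = eps(V_k, L/B_k) * (mean uptake in current
#' mask - B) + B` with the coefficient looked up in a sphere-calibrated
#' table; iterates until the relative volume change drops below `tol`
#' (0.5%) or `max_iter`. With `background_estimate = 0` and a constant
#' table the rule reduces to a fixed fraction of the mask mean uptake.
#'
#' @param image an `activity_volume`.
#' @param seed_region optional bounding box (see
#'   [fixed_threshold_segment()]).
#' @param background_estimate background activity, MBq/cc; if NULL,
#'   estimated as the median of the volume border shell.
#' @param calibration an `adaptive_calibration` table; default the
#'   shipped one.
#' @param tol relative volume-change convergence tolerance.
#' @param max_iter maximum iterations (error carrying the last iterate in
#'   `condition$last` on non-convergence).
#' @return a `segmentation_mask` (method `"adaptive"`).
#' @export
adaptive_threshold_segment <- function(image, seed_region = NULL,
                                       background_estimate = NULL,
                                       calibration = default_calibration(),
                                       tol = 0.005, max_iter = 50) {
  if (is.null(background_estimate)) {
    d <- dim(image$values)
    border <- array(TRUE, d)
    border[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
    background_estimate <- stats::median(image$values[border])
  }
  if (background_estimate <= 0) {
    ## degenerate limit: fixed fraction of the mask mean
    eps_fun <- function(v, l) 0.5
    background_estimate <- 1e-12
  } else {
    eps_fun <- function(v, l) interp_eps(calibration, v, l)
  }
  adaptive_iterate(image, seed_region, background_estimate, eps_fun,
                   tol = tol, max_iter = max_iter)
}

#' Percent error on the MTV estimate
#'
#' `100 * (V_GS_active - MTV) / V_GS_active` by default: positive for
#' under-segmentation, negative for over-segmentation. The necrotic
#' volume is excluded from the ground truth. The opposite convention is
#' available via `sign = "mtv_minus_gt"` and is applied consistently.
#'
#' @param mask a `segmentation_mask` (or the MTV in cc).
#' @param gt a `lesion_ground_truth` (or the active volume in cc).
#' @param sign sign convention.
#' @return percent error.
#' @export
mtv_percent_error <- function(mask, gt, sign = c("gt_minus_mtv", "mtv_minus_gt")) {
  sign <- match.arg(sign)
  mtv <- if (inherits(mask, "segmentation_mask")) mask$mtv else as.numeric(mask)
  v <- if (inherits(gt, "lesion_ground_truth")) gt$v_gs_active else as.numeric(gt)
  if (v <= 0) stop("active ground-truth volume must be positive")
  e <- 100 * (v - mtv) / v
  if (sign == "mtv_minus_gt") -e else e
}

#' Measured lesion-to-background ratio
#'
#' Ratio of the mean uptake in the lesion mask to the mean uptake in a
#' background region of interest.
#'
#' @param image an `activity_volume`.
#' @param mask lesion mask (logical array or `segmentation_mask`).
#' @param background_roi logical array; if NULL, the volume border shell
#'   is used. Must be disjoint from the lesion mask.
#' @return list with `lb_m`, `lesion_uptake`, `background_uptake`.
#' @export
measure_lb <- function(image, mask, background_roi = NULL) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$mask
  d <- dim(image$values)
  if (is.null(background_roi)) {
    background_roi <- array(TRUE, d)
    background_roi[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  }
  if (any(background_roi & mask)) stop("lesion and background regions overlap")
  bu <- mean(image$values[background_roi])
  if (bu <= 0) stop("zero background uptake")
  lu <- mean(image$values[mask])
  list(lb_m = lu / bu, lesion_uptake = lu, background_uptake = bu)
}
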