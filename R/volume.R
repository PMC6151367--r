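## ActivityVolume: the 3D scalar image every stage consumes ---------------

#' Construct an activity volume
#'
#' A 3D scalar grid of radiotracer activity concentration (MBq/cc) with
#' voxel spacing and origin metadata. This is the carrier object consumed
#' by the acquisition emulator, the segmentation methods and the feature
#' extractor.
#'
#' @param values 3D numeric array, MBq/cc; all values must be >= 0 unless
#'   `allow_negative` (noise can push voxels slightly below zero; such
#'   volumes are clamped at creation by default).
#' @param spacing numeric length-3, voxel size in mm (x, y, z); strictly
#'   positive.
#' @param origin numeric length-3, position of the first voxel centre, mm.
#' @param clamp clamp negative values to zero (default TRUE).
#' @return an object of class `activity_volume`.
#' @export
#' @examples
#' v <- activity_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_cc(v) * length(v$values)  # total volume in cc
activity_volume <- function(values, spacing, origin = c(0, 0, 0), clamp = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  if (clamp) values[values < 0] <- 0
  else if (any(values < 0, na.rm = TRUE)) stop("negative activity values")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "activity_volume"
  )
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<activity_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, range [%.4g, %.4g] MBq/cc\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume in cc
#' @param vol an `activity_volume` (or anything with a `spacing` field in mm).
#' @return voxel volume in cc (= mL).
#' @export
voxel_volume_cc <- function(vol) prod(vol$spacing) / 1000

#' Read / write activity volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 (plain or gzipped) with the voxel spacing
#' in the header; spacing and values round-trip within float32 precision.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an `activity_volume`; `write_volume`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop("3D volume required, got ", length(dim(img)), "D")
  pix <- attr(img, "pixdim")
  if (is.null(pix) || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0))
    stop("missing or invalid voxel spacing in NIfTI header")
  orig <- RNifti::origin(img)
  activity_volume(array(as.numeric(img), dim(img)), spacing = pix[1:3],
                  origin = as.numeric(orig), clamp = FALSE)
}

#' @param vol an `activity_volume`.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## Separable Gaussian smoothing ------------------------------------------

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 1e-8) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

## Convolve along dimension `dimn` with replicate padding, via shifted sums.
convolve_dim <- function(a, kernel, dimn) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(a * kernel)
  d <- dim(a)
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    off <- j - 1L - r
    idx <- seq_len(d[dimn]) + off
    idx[idx < 1L] <- 1L                 # replicate edges
    idx[idx > d[dimn]] <- d[dimn]
    sl <- switch(dimn,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + kernel[j] * sl
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' @param values 3D array.
#' @param fwhm_mm scalar or length-3 FWHM of the Gaussian, mm.
#' @param spacing voxel spacing, mm.
#' @return smoothed array of the same dimensions (replicate-padded edges).
#' @export
gaussian_smooth3d <- function(values, fwhm_mm, spacing) {
  fwhm_mm <- rep_len(fwhm_mm, 3)
  out <- values
  for (k in 1:3) {
    sig <- fwhm_to_sigma(fwhm_mm[k]) / spacing[k]
    if (sig > 1e-8) out <- convolve_dim(out, gauss_kernel(sig), k)
  }
  out
}

## Resampling -------------------------------------------------------------

## Trilinear interpolation of array `a` (spacing `sp`, origin `or`) at world
## coordinates given as three vectors; points outside the grid clamp to the
## border (replicate).
trilinear_sample <- function(a, sp, or, xs, ys, zs) {
  d <- dim(a)
  gx <- (xs - or[1]) / sp[1] + 1
  gy <- (ys - or[2]) / sp[2] + 1
  gz <- (zs - or[3]) / sp[3] + 1
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  gx <- clamp(gx, d[1]); gy <- clamp(gy, d[2]); gz <- clamp(gz, d[3])
  x0 <- pmin(floor(gx), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(gy), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(gz), d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- rep(1, length(gx)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1, length(gy)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1, length(gz)) }
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

nearest_sample <- function(a, sp, or, xs, ys, zs) {
  d <- dim(a)
  gx <- round((xs - or[1]) / sp[1] + 1)
  gy <- round((ys - or[2]) / sp[2] + 1)
  gz <- round((zs - or[3]) / sp[3] + 1)
  gx <- pmin(pmax(gx, 1), d[1]); gy <- pmin(pmax(gy, 1), d[2])
  gz <- pmin(pmax(gz, 1), d[3])
  a[cbind(gx, gy, gz)]
}

#' Resample an image (and optional mask) to an isotropic grid
#'
#' Target spacing is the in-plane (axial) pixel size applied to all three
#' axes. The image is interpolated tri-linearly, the mask with
#' nearest-neighbour so it stays binary. Already-isotropic inputs are
#' returned unchanged (bitwise identity for the mask).
#'
#' @param image an `activity_volume`.
#' @param mask optional 3D logical/0-1 array on the same grid.
#' @return list with elements `image` (activity_volume) and `mask` (array
#'   or NULL).
#' @export
resample_isotropic <- function(image, mask = NULL) {
  sp <- image$spacing
  if (max(sp) / min(sp) > 10)
    stop("anisotropy ratio > 10: unphysical voxel spacing")
  if (!is.null(mask) && !identical(dim(mask), dim(image$values)))
    stop("mask and image dimensions differ")
  target <- sp[1]  # in-plane pixel size
  if (max(abs(sp - target)) < 1e-9)
    return(list(image = image, mask = mask))
  d <- dim(image$values)
  extent <- sp * d
  nd <- pmax(2L, as.integer(round(extent / target)))
  ax <- image$origin[1] + (seq_len(nd[1]) - 1) * target
  ay <- image$origin[2] + (seq_len(nd[2]) - 1) * target
  az <- image$origin[3] + (seq_len(nd[3]) - 1) * target
  g <- expand.grid(x = ax, y = ay, z = az)
  vals <- trilinear_sample(image$values, sp, image$origin, g$x, g$y, g$z)
  out_img <- activity_volume(array(vals, nd), spacing = rep(target, 3),
                             origin = image$origin, clamp = FALSE)
  out_mask <- NULL
  if (!is.null(mask)) {
    mv <- nearest_sample(array(as.numeric(mask), d), sp, image$origin,
                         g$x, g$y, g$z)
    out_mask <- array(mv > 0.5, nd)
  }
  list(image = out_img, mask = out_mask)
}
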