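## Morphological features (IF_M) -----------------------------------------

#' Morphological features of a segmented volume
#'
#' The five shape/size features: MTV (cc), Surface (cm^2, anti-aliased
#' iso-surface mesh), Spherical disproportion (1/Sphericity), Sphericity
#' (`pi^(1/3) (6 MTV)^(2/3) / Surface`) and Surface-volume ratio
#' (Surface / MTV, 1/cm). Intensities play no role. A single-voxel mask
#' is degenerate: the surface falls back to the voxel cuboid area and the
#' vector is flagged.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing, mm.
#' @return named numeric of length 5 (`MTV`, `Surface`,
#'   `Spherical disproportion`, `Sphericity`, `Surface-volume ratio (SV)`)
#'   with attribute `degenerate`.
#' @export
morphological_features <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask")
  nvox <- sum(mask)
  mtv_cc <- nvox * prod(spacing) / 1000
  degenerate <- nvox < 2
  if (degenerate) {
    s_mm2 <- 2 * (spacing[1] * spacing[2] + spacing[1] * spacing[3] +
                    spacing[2] * spacing[3])
  } else {
    s_mm2 <- mask_surface_area(mask, spacing)
  }
  s_cm2 <- s_mm2 / 100
  sph <- compute_sphericity_gs(mtv_cc, s_cm2)
  out <- c("MTV" = mtv_cc, "Surface" = s_cm2,
           "Spherical disproportion" = 1 / sph, "Sphericity" = sph,
           "Surface-volume ratio (SV)" = s_cm2 / mtv_cc)
  attr(out, "degenerate") <- degenerate
  out
}
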