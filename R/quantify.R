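#' Representative axial slice of a VOI
#'
#' The axial (third-index) slice maximising the mean SUV over the VOI
#' voxels it contains; ties are broken toward the inferior-most slice
#' (smallest index; the world z axis is assumed to increase with k, as in
#' RAS-oriented volumes).
#'
#' @param suv A `scalar_volume` (SUV).
#' @param voi A [lesion_voi()] on the SUV grid.
#' @return 0-based slice index.
#' @export
representative_slice <- function(suv, voi) {
  stopifnot(inherits(suv, "scalar_volume"), inherits(voi, "lesion_voi"))
  vals <- suv$data[ijk_to_lin(voi$voxels, dim(suv$data))]
  means <- tapply(vals, voi$voxels[, 3], mean)
  ks <- as.integer(names(means))
  best <- means == max(means)
  min(ks[best])
}

#' Mirrored contralateral background ROI
#'
#' Builds the 2D background region on the representative slice: a disk
#' centred at the reflection of the VOI's in-slice centroid across the
#' mid-sagittal plane `x = midline_world_x`, with area equal to the VOI's
#' cross-sectional area on that slice ("similar size"), clipped to the
#' brain mask. Errors if the VOI straddles the midline, if the clipped ROI
#' overlaps the lesion VOI, or if clipping removes more than
#' `max_lost_fraction` of the nominal area — all of which signal that no
#' valid contralateral background exists.
#'
#' @param vol A `scalar_volume` (the grid the ROI is built on).
#' @param voi The lesion [lesion_voi()] on the same grid.
#' @param slice_index 0-based axial slice (see [representative_slice()]).
#' @param midline_world_x World x of the mid-sagittal plane (default 0).
#' @param brain_mask Logical array on the volume's grid.
#' @param max_lost_fraction Error threshold on area lost to clipping.
#' @return An object of class `background_roi`: fields `voxels` (0-based
#'   n x 3, all on `slice_index`), `slice_index`, `area_mm2`, `center_mm`.
#' @export
mirror_background_roi <- function(vol, voi, slice_index,
                                  midline_world_x = 0, brain_mask,
                                  max_lost_fraction = 0.25) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(voi, "lesion_voi"))
  dims <- dim(vol$data)
  w_all <- voxel_to_world(voi$voxels, vol)
  side <- sign(w_all[, 1] - midline_world_x)
  if (any(side > 0) && any(side < 0))
    stop("lesion VOI straddles the midline plane; no contralateral side exists")
  if (all(side == 0))
    stop("lesion VOI lies on the midline plane")

  insl <- voi$voxels[, 3] == slice_index
  if (!any(insl))
    stop("`slice_index` contains no VOI voxel")
  w <- w_all[insl, , drop = FALSE]
  centroid <- colMeans(w)
  center <- centroid
  center[1] <- 2 * midline_world_x - centroid[1]

  sp <- voxel_spacing(vol)
  n_area <- sum(insl)
  area_mm2 <- n_area * sp[1] * sp[2]
  radius <- sqrt(area_mm2 / pi)

  # in-plane disk on the same axial slice
  cand <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                                k = slice_index))
  cw <- voxel_to_world(cand, vol)
  d2 <- (cw[, 1] - center[1])^2 + (cw[, 2] - center[2])^2
  disk <- d2 <= radius^2
  if (!any(disk)) { # degenerate: take the nearest voxel centre
    disk <- d2 == min(d2)
  }
  vox <- cand[disk, , drop = FALSE]
  n_nominal <- nrow(vox)
  keep <- brain_mask[ijk_to_lin(vox, dims)]
  vox <- vox[keep, , drop = FALSE]
  if (nrow(vox) < (1 - max_lost_fraction) * n_nominal)
    stop(sprintf(
      "background ROI lost %d of %d voxels to the brain mask (> %.0f%%)",
      n_nominal - nrow(vox), n_nominal, 100 * max_lost_fraction))
  voi_lin <- ijk_to_lin(voi$voxels, dims)
  if (any(ijk_to_lin(vox, dims) %in% voi_lin))
    stop("background ROI overlaps the lesion VOI")
  structure(
    list(voxels = vox, grid_id = voi$grid_id, slice_index = slice_index,
         area_mm2 = nrow(vox) * sp[1] * sp[2], center_mm = center),
    class = "background_roi")
}

#' @export
print.background_roi <- function(x, ...) {
  cat(sprintf("<background_roi> %d voxels, slice %d, %.1f mm^2, centred (%.1f, %.1f) mm\n",
              nrow(x$voxels), x$slice_index, x$area_mm2,
              x$center_mm[1], x$center_mm[2]))
  invisible(x)
}

#' Mean voxel value over a region
#'
#' @param vol A `scalar_volume`.
#' @param region A [lesion_voi()], `background_roi`, or bare n x 3 matrix
#'   of 0-based voxel indices.
#' @return Arithmetic mean of the voxel values.
#' @export
roi_mean <- function(vol, region) {
  stopifnot(inherits(vol, "scalar_volume"))
  vox <- if (is.matrix(region)) region else region$voxels
  if (is.null(vox) || nrow(vox) == 0L) stop("`region` is empty")
  if (!all(in_grid(vox, dim(vol$data)))) stop("`region` has out-of-grid voxels")
  mean(vol$data[ijk_to_lin(vox, dim(vol$data))])
}

#' Per-patient biparametric metric set
#'
#' Computes the full quantitative read-out from a lesion VOI pair and the
#' mirrored background regions: SUVmax and SUV80mean over the isocontour
#' VOI, background means, the ratios TBRmax = SUVmax/SUV-BG,
#' TBR80mean = SUV80mean/SUV-BG and rADCmean = ADCmean/ADC-BG, and the VOI
#' volume. Backgrounds must be strictly positive.
#'
#' @param suv,adc The two `scalar_volume`s.
#' @param voi_suv The isocontour [lesion_voi()] on the SUV grid.
#' @param voi_adc The transferred (and margin-adapted) VOI on the ADC grid.
#' @param bg_suv,bg_adc Background regions (`background_roi` or transferred
#'   VOI) on the respective grids.
#' @param patient_id Optional identifier carried into the output.
#' @return An object of class `lesion_metrics` (also a one-row list): see
#'   [as.data.frame.lesion_metrics()].
#' @export
compute_metrics <- function(suv, adc, voi_suv, voi_adc, bg_suv, bg_adc,
                            patient_id = NA_character_) {
  suv_vals <- suv$data[ijk_to_lin(voi_suv$voxels, dim(suv$data))]
  suv_max <- max(suv_vals)
  suv80_mean <- mean(suv_vals)
  suv_bg <- roi_mean(suv, bg_suv)
  adc_mean <- roi_mean(adc, voi_adc)
  adc_bg <- roi_mean(adc, bg_adc)
  if (suv_bg <= 0 || adc_bg <= 0)
    stop("background means must be strictly positive")
  out <- structure(
    list(patient_id = patient_id,
         suv_max = suv_max, suv80_mean = suv80_mean, suv_bg = suv_bg,
         tbr_max = suv_max / suv_bg, tbr80_mean = suv80_mean / suv_bg,
         adc_mean = adc_mean, adc_bg = adc_bg,
         radc_mean = adc_mean / adc_bg,
         voi_volume_mm3 = nrow(voi_suv$voxels) * voxel_volume_mm3(suv)),
    class = "lesion_metrics")
  validate_lesion_metrics(out, voi_suv$threshold_fraction)
  out
}

validate_lesion_metrics <- function(m, fraction = 0.8) {
  if (!is.na(fraction) && m$suv80_mean < fraction * m$suv_max - 1e-9)
    stop("SUV80mean fell below the isocontour pinning bound; inconsistent VOI")
  if (m$suv80_mean > m$suv_max + 1e-9)
    stop("SUV80mean exceeds SUVmax; inconsistent VOI")
  invisible(m)
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("<lesion_metrics>%s\n",
              if (is.na(x$patient_id)) "" else paste0(" ", x$patient_id)))
  cat(sprintf("  SUVmax %.3f  SUV80mean %.3f  SUV-BG %.3f  ->  TBRmax %.2f  TBR80mean %.2f\n",
              x$suv_max, x$suv80_mean, x$suv_bg, x$tbr_max, x$tbr80_mean))
  cat(sprintf("  ADCmean %.0f  ADC-BG %.0f  ->  rADCmean %.2f   (VOI %.0f mm^3)\n",
              x$adc_mean, x$adc_bg, x$radc_mean, x$voi_volume_mm3))
  invisible(x)
}

#' Convert lesion metrics to a one-row data frame
#'
#' Columns (in order): `patient_id, suv_max, suv80_mean, suv_bg, tbr_max,
#' tbr80_mean, adc_mean, adc_bg, radc_mean, voi_volume_mm3` — the same
#' layout the cohort CSV uses.
#'
#' @param x A `lesion_metrics`.
#' @param ... Unused.
#' @export
as.data.frame.lesion_metrics <- function(x, ...) {
  data.frame(patient_id = x$patient_id,
             suv_max = x$suv_max, suv80_mean = x$suv80_mean,
             suv_bg = x$suv_bg, tbr_max = x$tbr_max,
             tbr80_mean = x$tbr80_mean, adc_mean = x$adc_mean,
             adc_bg = x$adc_bg, radc_mean = x$radc_mean,
             voi_volume_mm3 = x$voi_volume_mm3,
             stringsAsFactors = FALSE)
}
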