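#' Scalar 3D volume with world affine
#'
#' Container for a single 3D scalar grid (an SUV PET volume or an ADC map)
#' together with the 4x4 affine mapping 0-based voxel indices to world
#' millimetre coordinates (RAS-oriented; for phantoms the mid-sagittal
#' plane sits at world x = 0).
#'
#' @param data Numeric 3D array of voxel values.
#' @param affine Invertible 4x4 matrix; column vector `c(i, j, k, 1)` of
#'   0-based voxel indices maps to `c(x, y, z, 1)` in mm.
#' @param modality `"SUV"` (dimensionless) or `"ADC"` (10^-6 mm^2/s).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine, modality = c("SUV", "ADC")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("`data` must be finite everywhere")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix")
  structure(
    list(data = data, affine = affine, modality = modality,
         units = if (modality == "SUV") "dimensionless" else "1e-6 mm^2/s"),
    class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<scalar_volume> %s  %dx%dx%d voxels @ %.3gx%.3gx%.3g mm  range [%.3g, %.3g]\n",
              x$modality, d[1], d[2], d[3], sp[1], sp[2], sp[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' Per-axis voxel spacing in mm
#' @param vol A `scalar_volume`.
#' @return Length-3 numeric vector of spacings.
#' @export
voxel_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Voxel volume in mm^3
#' @param vol A `scalar_volume`.
#' @return Scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Map 0-based voxel indices to world mm coordinates
#'
#' @param idx Integer matrix (n x 3) of 0-based voxel indices, or a single
#'   length-3 vector.
#' @param vol A `scalar_volume` (or a bare 4x4 affine).
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(idx, vol) {
  A <- if (inherits(vol, "scalar_volume")) vol$affine else vol
  idx <- rbind_idx(idx)
  t(A %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Map world mm coordinates to (fractional) 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (or length-3 vector).
#' @export
world_to_voxel <- function(xyz, vol) {
  A <- if (inherits(vol, "scalar_volume")) vol$affine else vol
  xyz <- rbind_idx(xyz)
  t(solve(A) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind_idx <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  storage.mode(m) <- "double"
  m
}

# 0-based ijk matrix <-> 1-based linear index into the array
ijk_to_lin <- function(ijk, dims) {
  1L + as.integer(ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]))
}
lin_to_ijk <- function(lin, dims) {
  l0 <- lin - 1L
  i <- l0 %% dims[1]
  j <- (l0 %/% dims[1]) %% dims[2]
  k <- l0 %/% (dims[1] * dims[2])
  cbind(i, j, k)
}

in_grid <- function(ijk, dims) {
  ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
  ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
  ijk[, 3] >= 0 & ijk[, 3] < dims[3]
}

#' Read a NIfTI volume as a `scalar_volume`
#'
#' Loads a NIfTI-1 file and attaches its xform affine. ADC maps stored in
#' SI units (mm^2/s) are rescaled to the conventional 10^-6 mm^2/s.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality `"SUV"` or `"ADC"`.
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path, modality = c("SUV", "ADC")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  data <- array(as.numeric(img), dim = dim(img)[1:3])
  if (modality == "ADC" && max(data) < 1) # SI-unit map: 1e-3 mm^2/s scale
    data <- data * 1e6
  scalar_volume(data, matrix(aff, 4, 4), modality)
}

#' Write a `scalar_volume` to NIfTI-1
#'
#' @param vol A `scalar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  sp <- voxel_spacing(vol)
  img <- RNifti::asNifti(vol$data, list(pixdim = c(-1, sp, 1, 1, 1, 1)))
  aff <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}
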