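#' Specification of a single digital PET/ADC phantom
#'
#' Defines one synthetic patient: an ellipsoidal brain on a regular grid,
#' Gaussian-correlated SUV background noise, CSF spheres (high ADC, low
#' SUV), and a single focal hot lesion with a generalized-Gaussian radial
#' uptake profile `exp(-0.5 (r/sigma)^gamma)` whose hot core (noise-free
#' uptake >= `core_fraction` x peak) carries its own ADC distribution.
#'
#' The phantom emulates the measurement situation of amino-acid PET with a
#' co-registered ADC map: contrast against a quiet background, a
#' contralateral mirror position guaranteed to lie in brain, and CSF
#' structures that margin adaptation must exclude. It makes no claim to
#' anatomical realism (no tissue atlas, no point-spread or partial-volume
#' modelling).
#'
#' @param grid_shape Integer voxel counts per axis (x, y, z).
#' @param voxel_size_mm Per-axis spacing in mm.
#' @param brain_semi_axes_mm Semi-axes of the brain ellipsoid, mm (centred
#'   at the world origin; mid-sagittal plane at world x = 0).
#' @param bg_suv_mean,bg_suv_sd Background SUV level and voxel noise SD
#'   (the SUV noise field is spatially smoothed, see Details).
#' @param bg_adc_mean,bg_adc_sd Background ADC level and white-noise SD
#'   (10^-6 mm^2/s).
#' @param csf_structures List of `list(center_mm=, radius_mm=)` spheres
#'   rendered with ADC `csf_adc` and SUV `csf_suv`.
#' @param lesion_center_mm World lesion centre, mm; must be lateral to the
#'   midline plane. Snapped to the nearest voxel centre when
#'   `snap_center = TRUE` so the noise-free maximum is attained exactly.
#' @param lesion_radius_mm Nominal lesion extent used for the geometric
#'   invariants (inside brain, clear of CSF and midline).
#' @param lesion_peak_suv Noise-free SUV at the lesion centre; must exceed
#'   `bg_suv_mean`.
#' @param lesion_profile_sigma_mm Radial fall-off scale of the uptake
#'   profile.
#' @param lesion_profile_exponent Exponent `gamma` of the generalized
#'   Gaussian profile (2 = Gaussian); see [profile_exponent_for_ratio()].
#' @param core_fraction Fraction of peak uptake delimiting the hot core
#'   (default 0.8, matching IC80 segmentation).
#' @param core_adc_mean,core_adc_sd ADC distribution inside the hot core.
#' @param csf_adc,csf_suv Values rendered inside CSF spheres.
#' @param suv_noise_sigma_vox Smoothing sigma (in voxels) applied to the
#'   SUV noise field, emulating post-reconstruction noise correlation.
#' @param extra_lesions Optional list of secondary hot spots
#'   (`list(center_mm=, peak_suv=, sigma_mm=)`, peaks below
#'   `lesion_peak_suv`), used to exercise prominent-lesion selection.
#' @param seed Integer RNG seed consumed by [render_phantom()].
#' @param snap_center Snap `lesion_center_mm` to the nearest voxel centre
#'   (default TRUE).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 48L),
                         voxel_size_mm = c(2, 2, 2.5),
                         brain_semi_axes_mm = c(55, 60, 50),
                         bg_suv_mean = 1.0, bg_suv_sd = 0.05,
                         bg_adc_mean = 760, bg_adc_sd = 60,
                         csf_structures = list(
                           list(center_mm = c(10, -18, 8), radius_mm = 7),
                           list(center_mm = c(-10, -18, 8), radius_mm = 7)),
                         lesion_center_mm = c(29, 1, 1.25),
                         lesion_radius_mm = 15,
                         lesion_peak_suv = 3.0,
                         lesion_profile_sigma_mm = 6,
                         lesion_profile_exponent = 2,
                         core_fraction = 0.8,
                         core_adc_mean = 1300, core_adc_sd = 100,
                         csf_adc = 3000, csf_suv = 0.2,
                         suv_noise_sigma_vox = 1.5,
                         extra_lesions = list(),
                         seed = 1L,
                         snap_center = TRUE) {
  grid_shape <- as.integer(grid_shape)
  if (any(voxel_size_mm <= 0)) stop("voxel spacings must be > 0")
  if (any(c(bg_suv_sd, bg_adc_sd, core_adc_sd) < 0))
    stop("noise SDs must be >= 0")
  if (lesion_peak_suv <= bg_suv_mean)
    stop("`lesion_peak_suv` must exceed `bg_suv_mean`: the lesion must be a hot spot")
  if (lesion_profile_sigma_mm <= 0 || lesion_profile_exponent <= 0)
    stop("lesion profile parameters must be positive")
  if (core_fraction <= 0 || core_fraction >= 1)
    stop("`core_fraction` must lie in (0, 1)")

  spec <- structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         brain_semi_axes_mm = brain_semi_axes_mm,
         bg_suv_mean = bg_suv_mean, bg_suv_sd = bg_suv_sd,
         bg_adc_mean = bg_adc_mean, bg_adc_sd = bg_adc_sd,
         csf_structures = csf_structures,
         lesion_center_mm = lesion_center_mm,
         lesion_radius_mm = lesion_radius_mm,
         lesion_peak_suv = lesion_peak_suv,
         lesion_profile_sigma_mm = lesion_profile_sigma_mm,
         lesion_profile_exponent = lesion_profile_exponent,
         core_fraction = core_fraction,
         core_adc_mean = core_adc_mean, core_adc_sd = core_adc_sd,
         csf_adc = csf_adc, csf_suv = csf_suv,
         suv_noise_sigma_vox = suv_noise_sigma_vox,
         extra_lesions = extra_lesions,
         seed = as.integer(seed)),
    class = "phantom_spec")
  if (snap_center)
    spec$lesion_center_mm <- snap_to_voxel_center(lesion_center_mm, spec)
  validate_phantom_spec(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> grid %dx%dx%d @ %.3gx%.3gx%.3g mm, seed %d\n",
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3], x$seed))
  cat(sprintf("  lesion @ (%.3g, %.3g, %.3g) mm: peak SUV %.3g (bg %.3g), sigma %.3g mm, gamma %.3g\n",
              x$lesion_center_mm[1], x$lesion_center_mm[2], x$lesion_center_mm[3],
              x$lesion_peak_suv, x$bg_suv_mean,
              x$lesion_profile_sigma_mm, x$lesion_profile_exponent))
  cat(sprintf("  core ADC ~ N(%.4g, %.3g); bg ADC %.4g\n",
              x$core_adc_mean, x$core_adc_sd, x$bg_adc_mean))
  invisible(x)
}

phantom_affine <- function(spec) {
  A <- diag(4)
  A[cbind(1:3, 1:3)] <- spec$voxel_size_mm
  A[1:3, 4] <- -spec$voxel_size_mm * (spec$grid_shape - 1) / 2
  A
}

snap_to_voxel_center <- function(center_mm, spec) {
  A <- phantom_affine(spec)
  idx <- round(world_to_voxel(center_mm, A))
  drop(voxel_to_world(idx, A))
}

validate_phantom_spec <- function(spec) {
  ax <- spec$brain_semi_axes_mm
  ctr <- spec$lesion_center_mm
  r <- spec$lesion_radius_mm
  # conservative containment: inflate each coordinate by the radius
  if (sum(((abs(ctr) + r) / ax)^2) > 1)
    stop("lesion sphere is not fully inside the brain ellipsoid")
  if (abs(ctr[1]) <= r)
    stop("lesion sphere intersects the midline plane x = 0")
  for (csf in spec$csf_structures) {
    if (sqrt(sum((ctr - csf$center_mm)^2)) <= r + csf$radius_mm)
      stop("lesion sphere intersects a CSF structure")
  }
  for (ex in spec$extra_lesions) {
    if (ex$peak_suv >= spec$lesion_peak_suv)
      stop("secondary lesions must be dimmer than the primary lesion")
  }
  invisible(spec)
}

# ---- IC80 profile-shape calibration ----------------------------------------

#' Continuum IC80 mean/max uptake ratio of a generalized-Gaussian lesion
#'
#' For a lesion with radial uptake `bg + (peak - bg) exp(-0.5 (r/sigma)^gamma)`
#' on a flat background, the mean uptake over the isocontour core
#' (uptake >= `fraction` x peak), divided by the peak, has the closed form
#' `(1 + (tbr - 1) m) / tbr` with
#' `m = Gamma(a + 1) P(a, U) / U^a`, `a = 3/gamma`, `U = log(1/c)`,
#' `c = (f tbr - 1)/(tbr - 1)` (P is the regularized incomplete gamma,
#' i.e. `pgamma`). Independent of `sigma` and of the background level.
#'
#' @param gamma Profile exponent (> 0); 2 is Gaussian.
#' @param tbr Peak-to-background ratio of the lesion (> 1/fraction).
#' @param fraction Isocontour fraction (default 0.8).
#' @return The mean/max uptake ratio over the core, in (fraction, 1).
#' @export
ic80_mean_max_ratio <- function(gamma, tbr, fraction = 0.8) {
  if (tbr <= 1 / fraction)
    stop("`tbr` must exceed 1/fraction for the isocontour to close")
  cc <- (fraction * tbr - 1) / (tbr - 1)
  U <- log(1 / cc)
  a <- 3 / gamma
  m <- exp(lgamma(a + 1) + stats::pgamma(U, a, log.p = TRUE) - a * log(U))
  (1 + (tbr - 1) * m) / tbr
}

#' Solve the lesion profile exponent for a target IC80 mean/max ratio
#'
#' Inverts [ic80_mean_max_ratio()] in `gamma`, so a phantom lesion
#' reproduces a prescribed ratio of core-mean to maximum uptake (e.g. a
#' published TBR80mean/TBRmax group ratio).
#'
#' @param target_ratio Desired core mean/max uptake ratio, in (fraction, 1).
#' @inheritParams ic80_mean_max_ratio
#' @return The exponent `gamma`.
#' @export
profile_exponent_for_ratio <- function(target_ratio, tbr, fraction = 0.8) {
  if (target_ratio <= fraction || target_ratio >= 1)
    stop("`target_ratio` must lie strictly between `fraction` and 1")
  stats::uniroot(function(g) ic80_mean_max_ratio(g, tbr, fraction) - target_ratio,
                 lower = 0.05, upper = 100, tol = 1e-9)$root
}

# ---- per-patient sampling ---------------------------------------------------

#' Draw a single patient's phantom specification from a group calibration
#'
#' Samples the patient's target TBRmax from a normal truncated below at
#' the calibration floor (location solved so the truncated mean equals the
#' calibration mean), the hot-core ADCmean from an untruncated normal,
#' sets `lesion_peak_suv = TBRmax x bg_suv_mean`, and solves the lesion
#' profile exponent so the IC80 mean/max ratio matches the calibration's
#' `tbr80_ratio`. The drawn truth values are recorded in `$truth`.
#'
#' @param calibration A [group_calibration()].
#' @param rng_seed Integer seed; identical seeds yield identical specs.
#' @param ... Geometry/noise overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec` with a `truth` element
#'   (`tbrmax`, `core_adc_mean`, `group`).
#' @export
sample_patient_spec <- function(calibration, rng_seed, ...) {
  stopifnot(inherits(calibration, "group_calibration"))
  set.seed(as.integer(rng_seed))
  loc <- truncnorm_location(calibration$tbrmax_mean, calibration$tbrmax_sd,
                            calibration$tbr_truncation_floor)
  tbr <- truncnorm_draw(1, loc, calibration$tbrmax_sd,
                        calibration$tbr_truncation_floor)
  core_adc <- stats::rnorm(1, calibration$core_adc_mean_mean,
                           calibration$core_adc_mean_sd)
  render_seed <- sample.int(.Machine$integer.max, 1)
  gamma <- profile_exponent_for_ratio(calibration$tbr80_ratio, tbr)
  spec <- phantom_spec(
    bg_suv_mean = calibration$bg_suv_mean,
    bg_adc_mean = calibration$bg_adc_mean,
    lesion_peak_suv = tbr * calibration$bg_suv_mean,
    lesion_profile_exponent = gamma,
    core_adc_mean = core_adc,
    seed = render_seed,
    ...)
  spec$truth <- list(tbrmax = tbr, core_adc_mean = core_adc,
                     group = calibration$group)
  spec
}

# ---- rendering --------------------------------------------------------------

# one 26-neighbourhood dilation of a logical 3D mask
dilate26 <- function(mask) {
  dims <- dim(mask)
  lin <- which(mask)
  if (length(lin) == 0L) return(mask)
  ijk <- lin_to_ijk(lin, dims)
  off <- offsets26()
  nb <- ijk[rep(seq_len(nrow(ijk)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(ijk)), , drop = FALSE]
  nb <- nb[in_grid(nb, dims), , drop = FALSE]
  out <- mask
  out[ijk_to_lin(nb, dims)] <- TRUE
  out
}

# separable zero-padded Gaussian smoothing of a 3D array; kernel sigma in voxels
smooth3d_gaussian <- function(arr, sigma_vox) {
  hw <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma_vox)
  k <- k / sum(k)
  for (axis in 1:3) {
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[axis])
    pad <- matrix(0, hw, ncol(m))
    f <- stats::filter(rbind(pad, m, pad), k, sides = 2)
    f <- f[(hw + 1):(hw + d[axis]), , drop = FALSE]
    arr <- aperm(array(f, dim(a)), order(perm))
  }
  attr(arr, "var_factor") <- sum(k^2)^3
  arr
}

#' Render a phantom specification into co-registered SUV and ADC volumes
#'
#' Both volumes share the grid and a diagonal RAS affine centred at the
#' world origin (midline at x = 0). Outside the brain ellipsoid both
#' volumes are zero. The SUV volume is background plus the lesion profile
#' plus smoothed Gaussian noise; the ADC volume is background noise,
#' overwritten by the hot-core ADC distribution inside the region where
#' the noise-free uptake reaches `core_fraction` of the peak — plus a
#' one-voxel partial-volume shell, since tissue at the measurement
#' contour is lesion, not healthy background — and by `csf_adc` inside
#' CSF spheres. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `suv` and `adc` (both [scalar_volume()]).
#' @export
render_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  A <- phantom_affine(spec)
  xs <- spec$voxel_size_mm[1] * (seq_len(d[1]) - 1 - (d[1] - 1) / 2)
  ys <- spec$voxel_size_mm[2] * (seq_len(d[2]) - 1 - (d[2] - 1) / 2)
  zs <- spec$voxel_size_mm[3] * (seq_len(d[3]) - 1 - (d[3] - 1) / 2)

  ax <- spec$brain_semi_axes_mm
  brain <- outer(outer((xs / ax[1])^2, (ys / ax[2])^2, "+"), (zs / ax[3])^2, "+") <= 1

  lesion_field <- function(center, peak, sigma, gamma) {
    r2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                (zs - center[3])^2, "+")
    (peak - spec$bg_suv_mean) * exp(-0.5 * (sqrt(r2) / sigma)^gamma)
  }
  main <- lesion_field(spec$lesion_center_mm, spec$lesion_peak_suv,
                       spec$lesion_profile_sigma_mm, spec$lesion_profile_exponent)
  suv_clean <- spec$bg_suv_mean + main
  for (ex in spec$extra_lesions)
    suv_clean <- suv_clean +
      lesion_field(ex$center_mm, ex$peak_suv,
                   if (is.null(ex$sigma_mm)) spec$lesion_profile_sigma_mm else ex$sigma_mm,
                   if (is.null(ex$gamma)) spec$lesion_profile_exponent else ex$gamma)
  core <- suv_clean >= spec$core_fraction * spec$lesion_peak_suv
  # lesion-ADC region: hot core plus a one-voxel partial-volume shell, so a
  # measurement VOI whose boundary wobbles with reconstruction noise still
  # samples lesion tissue (tissue at the contour is not healthy background)
  adc_region <- dilate26(core)

  csf <- array(FALSE, d)
  for (s in spec$csf_structures) {
    r2 <- outer(outer((xs - s$center_mm[1])^2, (ys - s$center_mm[2])^2, "+"),
                (zs - s$center_mm[3])^2, "+")
    csf <- csf | (r2 <= s$radius_mm^2)
  }
  suv_clean[csf] <- spec$csf_suv

  suv <- suv_clean
  if (spec$bg_suv_sd > 0) {
    noise <- array(stats::rnorm(prod(d)), d)
    sm <- smooth3d_gaussian(noise, spec$suv_noise_sigma_vox)
    suv <- suv + spec$bg_suv_sd * sm / sqrt(attr(sm, "var_factor"))
  }
  suv[!brain] <- 0

  adc <- array(spec$bg_adc_mean, d)
  if (spec$bg_adc_sd > 0)
    adc <- adc + array(stats::rnorm(prod(d), sd = spec$bg_adc_sd), d)
  adc[adc_region] <- stats::rnorm(sum(adc_region), spec$core_adc_mean,
                                  spec$core_adc_sd)
  adc[csf] <- spec$csf_adc
  adc[!brain] <- 0

  # the global hot spot must be the lesion
  amax <- lin_to_ijk(which.max(suv), d)
  wmax <- voxel_to_world(amax, A)
  if (sqrt(sum((wmax - spec$lesion_center_mm)^2)) > spec$lesion_radius_mm)
    stop("rendered SUV maximum fell outside the lesion; check noise levels")

  list(suv = scalar_volume(suv, A, "SUV"),
       adc = scalar_volume(adc, A, "ADC"))
}

# ---- cohort generation ------------------------------------------------------

#' Generate a labelled synthetic cohort on disk
#'
#' Draws `n_rec` + `n_ptre` patient specifications from the two group
#' calibrations, renders each phantom, writes NIfTI pairs under `out_dir`
#' and a manifest CSV (`manifest.csv`) with columns
#' `patient_id,group,suv_path,adc_path,true_core_adc,true_tbrmax`.
#' Fully reproducible from `seed`.
#'
#' @param calibrations Named list with `group_calibration` elements `REC`
#'   and `PTRE` (see [default_calibrations()]).
#' @param n_rec,n_ptre Patients per group (>= 1).
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param ... Geometry/noise overrides forwarded to [sample_patient_spec()].
#' @return The manifest as a data frame (invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_cohort <- function(calibrations, n_rec, n_ptre, seed, out_dir, ...) {
  stopifnot(n_rec >= 1, n_ptre >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_rec + n_ptre)
  ids <- c(sprintf("REC_%03d", seq_len(n_rec)),
           sprintf("PTRE_%03d", seq_len(n_ptre)))
  groups <- rep(c("REC", "PTRE"), c(n_rec, n_ptre))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    spec <- sample_patient_spec(calibrations[[groups[i]]], seeds[i], ...)
    vols <- render_phantom(spec)
    suv_path <- file.path(out_dir, paste0(ids[i], "_suv.nii.gz"))
    adc_path <- file.path(out_dir, paste0(ids[i], "_adc.nii.gz"))
    write_volume(vols$suv, suv_path)
    write_volume(vols$adc, adc_path)
    rows[[i]] <- data.frame(
      patient_id = ids[i], group = groups[i],
      suv_path = suv_path, adc_path = adc_path,
      true_core_adc = spec$truth$core_adc_mean,
      true_tbrmax = spec$truth$tbrmax,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
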