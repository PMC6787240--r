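#' Lesion volume-of-interest on a named grid
#'
#' A set of 0-based voxel index triples on one volume's grid, with the
#' segmentation provenance: the isocontour fraction, the absolute SUV
#' threshold it induced, and the seed voxel (the component maximum). On
#' the SUV grid every member voxel is supra-threshold and the set is
#' 26-connected.
#'
#' @param voxels Integer n x 3 matrix of 0-based voxel indices.
#' @param grid_id Character label of the grid the indices refer to.
#' @param threshold_fraction Isocontour fraction used (e.g. 0.8), or NA
#'   for derived VOIs (transferred / margin-adapted).
#' @param absolute_threshold Absolute threshold in volume units, or NA.
#' @param seed_voxel Length-3 0-based index of the component maximum.
#' @return An object of class `lesion_voi`.
#' @export
lesion_voi <- function(voxels, grid_id,
                       threshold_fraction = NA_real_,
                       absolute_threshold = NA_real_,
                       seed_voxel = NULL) {
  voxels <- rbind_idx(voxels)
  if (nrow(voxels) == 0L) stop("a lesion VOI must be non-empty")
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("i", "j", "k")
  structure(
    list(voxels = voxels, grid_id = grid_id,
         threshold_fraction = threshold_fraction,
         absolute_threshold = absolute_threshold,
         seed_voxel = if (is.null(seed_voxel)) NULL else as.integer(seed_voxel)),
    class = "lesion_voi")
}

#' @export
print.lesion_voi <- function(x, ...) {
  cat(sprintf("<lesion_voi> %d voxels on grid '%s'", nrow(x$voxels), x$grid_id))
  if (!is.na(x$threshold_fraction))
    cat(sprintf(", isocontour %.0f%% (abs %.4g)",
                100 * x$threshold_fraction, x$absolute_threshold))
  cat("\n")
  invisible(x)
}

#' @export
length.lesion_voi <- function(x) nrow(x$voxels)

# 26-neighbourhood offsets (3^3 - 1 rows)
offsets26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# label the TRUE voxels of `mask` into 26-connected components (BFS);
# returns a list of integer matrices of 0-based ijk triples
connected_components26 <- function(mask) {
  dims <- dim(mask)
  lin <- which(mask)
  if (length(lin) == 0L) return(list())
  ijk <- lin_to_ijk(lin, dims)
  inset <- logical(prod(dims)); inset[lin] <- TRUE
  seen <- logical(prod(dims))
  off <- offsets26()
  comps <- list()
  for (start in lin) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0L) {
      members <- c(members, queue)
      cur <- lin_to_ijk(queue, dims)
      nb <- cur[rep(seq_len(nrow(cur)), each = nrow(off)), , drop = FALSE] +
            off[rep(seq_len(nrow(off)), times = nrow(cur)), , drop = FALSE]
      nb <- nb[in_grid(nb, dims), , drop = FALSE]
      nl <- unique(ijk_to_lin(nb, dims))
      nl <- nl[inset[nl] & !seen[nl]]
      seen[nl] <- TRUE
      queue <- nl
    }
    comps[[length(comps) + 1L]] <- lin_to_ijk(sort(members), dims)
  }
  comps
}

#' Find candidate hot components by global isocontour thresholding
#'
#' Thresholds the SUV volume at `fraction` times the global in-mask
#' maximum and splits the supra-threshold voxels into 26-connected
#' components — the candidate lesions. The component containing the
#' global maximum always exists.
#'
#' @param suv A `scalar_volume` (SUV).
#' @param brain_mask Logical array of the volume's shape (non-empty);
#'   voxels outside it are ignored.
#' @param fraction Isocontour fraction in (0, 1); default 0.8 (IC80).
#' @return List of components, each a list with `voxels` (0-based n x 3),
#'   `suv_max`, `max_voxel` (0-based argmax, lexicographic tie-break),
#'   `n_voxels` and `volume_mm3`; sorted by decreasing `suv_max`.
#' @export
find_hot_components <- function(suv, brain_mask, fraction = 0.8) {
  stopifnot(inherits(suv, "scalar_volume"))
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  if (!any(brain_mask)) stop("`brain_mask` is empty")
  if (!identical(dim(brain_mask), dim(suv$data)))
    stop("`brain_mask` shape must match the volume")
  gmax <- max(suv$data[brain_mask])
  thr <- fraction * gmax
  mask <- brain_mask & (suv$data >= thr)
  comps <- connected_components26(mask)
  vv <- voxel_volume_mm3(suv)
  out <- lapply(comps, function(vox) {
    vals <- suv$data[ijk_to_lin(vox, dim(suv$data))]
    mx <- max(vals)
    # lexicographically smallest index triple among ties at the maximum
    cand <- vox[vals == mx, , drop = FALSE]
    ord <- order(cand[, 1], cand[, 2], cand[, 3])
    list(voxels = vox, suv_max = mx,
         max_voxel = cand[ord[1], ],
         n_voxels = nrow(vox), volume_mm3 = nrow(vox) * vv,
         threshold_fraction = fraction)
  })
  out[order(vapply(out, `[[`, numeric(1), "suv_max"), decreasing = TRUE)]
}

#' Select the most prominent lesion among candidate components
#'
#' Ranks candidates by maximum uptake, then by voxel volume, then by
#' smallest distance of the component maximum to an optional reference
#' point (e.g. a resection cavity or prior tumour location). Deterministic.
#'
#' @param components List of components from [find_hot_components()].
#' @param reference_point_mm Optional world point for the distance
#'   tie-break; requires `vol`.
#' @param vol The `scalar_volume` the components live on (needed only for
#'   the distance tie-break).
#' @return The winning component.
#' @export
select_prominent_lesion <- function(components, reference_point_mm = NULL,
                                    vol = NULL) {
  if (length(components) == 0L) stop("no candidate components")
  suvmax <- vapply(components, `[[`, numeric(1), "suv_max")
  nvox <- vapply(components, `[[`, numeric(1), "n_voxels")
  dist <- rep(0, length(components))
  if (!is.null(reference_point_mm)) {
    if (is.null(vol)) stop("`vol` is required with `reference_point_mm`")
    dist <- vapply(components, function(cp) {
      w <- voxel_to_world(cp$max_voxel, vol)
      sqrt(sum((w - reference_point_mm)^2))
    }, numeric(1))
  }
  ord <- order(-suvmax, -nvox, dist)
  components[[ord[1]]]
}

#' Build the local isocontour VOI of a selected component
#'
#' Re-thresholds the component at `fraction` times its own maximum, so a
#' dimmer secondary lesion carries a true isocontour of its own peak, and
#' keeps the 26-connected subcomponent containing the component maximum.
#'
#' @param suv A `scalar_volume` (SUV).
#' @param component A component from [find_hot_components()].
#' @param fraction Isocontour fraction; defaults to the fraction the
#'   component was found with.
#' @param grid_id Grid label recorded on the VOI.
#' @return A [lesion_voi()] on the SUV grid.
#' @export
isocontour_voi <- function(suv, component, fraction = NULL, grid_id = "suv") {
  stopifnot(inherits(suv, "scalar_volume"))
  if (is.null(fraction)) fraction <- component$threshold_fraction
  if (is.null(fraction)) stop("no isocontour fraction available")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  dims <- dim(suv$data)
  thr <- fraction * component$suv_max
  keep_lin <- ijk_to_lin(component$voxels, dims)
  keep_lin <- keep_lin[suv$data[keep_lin] >= thr]
  mask <- array(FALSE, dims)
  mask[keep_lin] <- TRUE
  comps <- connected_components26(mask)
  seed <- component$max_voxel
  holds_seed <- vapply(comps, function(v)
    any(v[, 1] == seed[1] & v[, 2] == seed[2] & v[, 3] == seed[3]), logical(1))
  vox <- comps[[which(holds_seed)[1]]]
  lesion_voi(vox, grid_id = grid_id, threshold_fraction = fraction,
             absolute_threshold = thr, seed_voxel = seed)
}

#' Transfer a VOI between co-registered grids by nearest neighbour
#'
#' Maps each target-grid voxel centre through the target affine and the
#' inverse source affine and includes it when it lands inside a source
#' VOI voxel (nearest-neighbour assignment). The two volumes must share a
#' world frame (co-registered, as on a hybrid scanner); an empty result
#' signals mis-registration and raises an error.
#'
#' @param voi A [lesion_voi()] on `source`'s grid.
#' @param source The `scalar_volume` the VOI lives on.
#' @param target The `scalar_volume` to transfer onto.
#' @param grid_id Grid label for the transferred VOI.
#' @return A [lesion_voi()] on `target`'s grid.
#' @export
transfer_voi <- function(voi, source, target, grid_id = "target") {
  stopifnot(inherits(voi, "lesion_voi"),
            inherits(source, "scalar_volume"),
            inherits(target, "scalar_volume"))
  src_dims <- dim(source$data)
  tgt_dims <- dim(target$data)
  src_mask <- array(FALSE, src_dims)
  src_mask[ijk_to_lin(voi$voxels, src_dims)] <- TRUE

  # candidate target voxels: world bounding box of the source VOI plus one
  # source voxel shell, mapped into target index space
  w <- voxel_to_world(voi$voxels, source)
  sp <- voxel_spacing(source)
  lo <- apply(w, 2, min) - sp
  hi <- apply(w, 2, max) + sp
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  ti <- world_to_voxel(corners, target)
  rng <- function(a, n) max(0L, floor(min(a))):min(n - 1L, ceiling(max(a)))
  ir <- rng(ti[, 1], tgt_dims[1]); jr <- rng(ti[, 2], tgt_dims[2])
  kr <- rng(ti[, 3], tgt_dims[3])
  if (length(ir) == 0L || length(jr) == 0L || length(kr) == 0L)
    stop("VOI transfer produced an empty set: grids do not overlap in world space")
  cand <- as.matrix(expand.grid(i = ir, j = jr, k = kr))
  cw <- voxel_to_world(cand, target)
  si <- round(world_to_voxel(cw, source))
  ok <- in_grid(si, src_dims)
  ok[ok] <- src_mask[ijk_to_lin(si[ok, , drop = FALSE], src_dims)]
  if (!any(ok))
    stop("VOI transfer produced an empty set: grids do not overlap in world space")
  out <- cand[ok, , drop = FALSE]

  seed <- voi$seed_voxel
  if (!is.null(seed)) {
    sw <- voxel_to_world(seed, source)
    seed <- as.integer(round(world_to_voxel(sw, target)))
  }
  lesion_voi(out, grid_id = grid_id,
             threshold_fraction = voi$threshold_fraction,
             absolute_threshold = voi$absolute_threshold,
             seed_voxel = seed)
}

#' Adapt VOI margins to exclude CSF and other excluded regions
#'
#' Removes voxels whose ADC reaches the CSF cutoff or that fall inside an
#' explicit exclusion mask (e.g. a resection cavity). A VOI that loses
#' more than half its voxels — or empties — signals a mis-placed VOI and
#' raises an error rather than returning a misleading measurement.
#'
#' @param voi A [lesion_voi()] on the ADC grid.
#' @param adc The ADC `scalar_volume`.
#' @param csf_cutoff ADC value (10^-6 mm^2/s) at or above which a voxel is
#'   considered CSF/fluid; default 2400.
#' @param exclusion_mask Optional logical array on the ADC grid.
#' @param max_removed_fraction Error threshold on the removed fraction.
#' @return The adapted [lesion_voi()] (a subset of the input).
#' @export
adapt_margins <- function(voi, adc, csf_cutoff = 2400, exclusion_mask = NULL,
                          max_removed_fraction = 0.5) {
  stopifnot(inherits(voi, "lesion_voi"), inherits(adc, "scalar_volume"))
  if (csf_cutoff <= 0) stop("`csf_cutoff` must be positive")
  dims <- dim(adc$data)
  lin <- ijk_to_lin(voi$voxels, dims)
  drop <- adc$data[lin] >= csf_cutoff
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dims))
      stop("`exclusion_mask` shape must match the ADC volume")
    drop <- drop | exclusion_mask[lin]
  }
  n_removed <- sum(drop)
  if (n_removed == nrow(voi$voxels))
    stop("margin adaptation removed the entire VOI; the VOI appears mis-placed")
  if (n_removed > max_removed_fraction * nrow(voi$voxels))
    stop(sprintf(
      "margin adaptation would remove %d of %d voxels (> %.0f%%); the VOI appears mis-placed",
      n_removed, nrow(voi$voxels), 100 * max_removed_fraction))
  out <- voi
  out$voxels <- voi$voxels[!drop, , drop = FALSE]
  out
}

#' Export a VOI as a binary NIfTI mask
#'
#' @param voi A [lesion_voi()].
#' @param vol The `scalar_volume` whose grid the VOI indexes.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_voi_mask <- function(voi, vol, path) {
  dims <- dim(vol$data)
  m <- array(0, dims)
  m[ijk_to_lin(voi$voxels, dims)] <- 1
  write_volume(scalar_volume(m, vol$affine, vol$modality), path)
}
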