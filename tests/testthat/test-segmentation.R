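test_that("a single hot sphere yields one component containing the max", {
  vol <- sphere_vol(spheres = list(list(center = c(10, 0, 0), radius = 8,
                                        value = 10)))
  comps <- find_hot_components(vol, array(TRUE, dim(vol$data)), 0.8)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$suv_max, 10)
  amax <- fetadc:::lin_to_ijk(which.max(vol$data), dim(vol$data))
  expect_true(any(comps[[1]]$voxels[, 1] == amax[1] &
                  comps[[1]]$voxels[, 2] == amax[2] &
                  comps[[1]]$voxels[, 3] == amax[3]))
})

test_that("two disjoint spheres both survive the global 80% threshold", {
  vol <- sphere_vol(spheres = list(
    list(center = c(14, 0, 0), radius = 7, value = 10),
    list(center = c(-14, 0, 0), radius = 7, value = 9)))
  mask <- array(TRUE, dim(vol$data))
  comps <- find_hot_components(vol, mask, 0.8)
  expect_length(comps, 2) # 9 >= 0.8 * 10
  expect_equal(vapply(comps, `[[`, numeric(1), "suv_max"), c(10, 9))
  # brute-force oracle: supra-threshold voxel count matches
  n_brute <- sum(vol$data >= 0.8 * 10)
  expect_equal(sum(vapply(comps, `[[`, numeric(1), "n_voxels")), n_brute)
})

test_that("components shrink monotonically as the fraction rises", {
  vol <- blob_vol(peak = 10, sigma = 9)
  mask <- array(TRUE, dim(vol$data))
  n_prev <- Inf
  for (f in c(0.8, 0.9, 0.99)) {
    comp <- find_hot_components(vol, mask, f)[[1]]
    voi <- isocontour_voi(vol, comp, fraction = f)
    expect_lt(nrow(voi$voxels), n_prev)
    n_prev <- nrow(voi$voxels)
  }
  # at 0.99 only a tight neighbourhood of the max survives
  expect_lt(n_prev, 10)
})

test_that("prominent-lesion selection ranks by peak, volume, distance", {
  comp <- function(peak, n, maxvox = c(0, 0, 0)) {
    list(voxels = matrix(0L, n, 3), suv_max = peak, max_voxel = maxvox,
         n_voxels = n, volume_mm3 = n * 10, threshold_fraction = 0.8)
  }
  # higher peak beats larger volume
  won <- select_prominent_lesion(list(comp(10, 40), comp(9, 400)))
  expect_equal(won$suv_max, 10)
  # equal peaks: tie broken by volume
  won <- select_prominent_lesion(list(comp(9, 40), comp(9, 400)))
  expect_equal(won$n_voxels, 400)
  # equal peaks and volumes: closest to the reference point wins
  vol <- make_vol(array(1, c(16, 16, 8)))
  a <- comp(9, 40, maxvox = c(2L, 2L, 2L))
  b <- comp(9, 40, maxvox = c(12L, 12L, 6L))
  won <- select_prominent_lesion(list(a, b),
                                 reference_point_mm = voxel_to_world(c(12, 12, 6), vol),
                                 vol = vol)
  expect_equal(won$max_voxel, b$max_voxel)
  expect_error(select_prominent_lesion(list()), "no candidate")
})

test_that("isocontour VOIs match brute-force thresholding", {
  # uniform sphere: the VOI is the entire sphere
  vol <- sphere_vol(spheres = list(list(center = c(10, 0, 0), radius = 8,
                                        value = 10)))
  mask <- array(TRUE, dim(vol$data))
  comp <- find_hot_components(vol, mask, 0.8)[[1]]
  voi <- isocontour_voi(vol, comp)
  expect_equal(nrow(voi$voxels), sum(vol$data == 10))
  expect_equal(voi$absolute_threshold, 8)

  # smooth blob: VOI = {value >= 0.8 * peak} exactly
  vol <- blob_vol(peak = 10, sigma = 8)
  comp <- find_hot_components(vol, mask, 0.8)[[1]]
  voi <- isocontour_voi(vol, comp)
  brute <- which(vol$data >= 0.8 * max(vol$data))
  expect_setequal(fetadc:::ijk_to_lin(voi$voxels, dim(vol$data)), brute)

  # fraction 1: the VOI collapses to the argmax
  voi1 <- isocontour_voi(vol, comp, fraction = 1)
  expect_equal(nrow(voi1$voxels), 1)
  expect_equal(voi1$voxels[1, ], voi1$seed_voxel, ignore_attr = TRUE)
})

test_that("a dimmer secondary lesion gets its own local 80% contour", {
  vol <- sphere_vol(dims = c(48, 32, 24), spheres = list(
    list(center = c(20, 0, 0), radius = 7, value = 10),
    list(center = c(-20, 0, 0), radius = 7, value = 9)))
  mask <- array(TRUE, dim(vol$data))
  comps <- find_hot_components(vol, mask, 0.8)
  dim_comp <- comps[[2]]
  voi <- isocontour_voi(vol, dim_comp)
  expect_equal(voi$absolute_threshold, 0.8 * 9)
  expect_equal(nrow(voi$voxels), sum(vol$data == 9))
})

test_that("emitted VOIs satisfy the exhaustive threshold-correctness scan", {
  off <- fetadc:::offsets26()
  for (s in 1:12) {
    spec <- tiny_spec(seed = s)
    vols <- render_phantom(spec)
    mask <- vols$suv$data > 0
    comps <- find_hot_components(vols$suv, mask, 0.8)
    voi <- isocontour_voi(vols$suv, select_prominent_lesion(comps))
    dims <- dim(vols$suv$data)
    lin <- fetadc:::ijk_to_lin(voi$voxels, dims)
    # every member voxel is supra-threshold
    expect_true(all(vols$suv$data[lin] >= voi$absolute_threshold))
    # every non-member 26-neighbour is sub-threshold or outside the mask
    inset <- logical(prod(dims)); inset[lin] <- TRUE
    nb <- voi$voxels[rep(seq_len(nrow(voi$voxels)), each = nrow(off)), ] +
          off[rep(seq_len(nrow(off)), times = nrow(voi$voxels)), ]
    nb <- nb[fetadc:::in_grid(nb, dims), , drop = FALSE]
    nl <- unique(fetadc:::ijk_to_lin(nb, dims))
    outside <- nl[!inset[nl]]
    expect_true(all(vols$suv$data[outside] < voi$absolute_threshold |
                    !mask[outside]))
  }
})

test_that("VOI transfer is exact on identical grids and consistent under shifts", {
  vol <- blob_vol(peak = 10, sigma = 8)
  mask <- array(TRUE, dim(vol$data))
  comp <- find_hot_components(vol, mask, 0.8)[[1]]
  voi <- isocontour_voi(vol, comp)
  # identity transfer
  same <- transfer_voi(voi, vol, vol)
  expect_setequal(fetadc:::ijk_to_lin(same$voxels, dim(vol$data)),
                  fetadc:::ijk_to_lin(voi$voxels, dim(vol$data)))
  # target translated by exactly one source voxel: indices shift by one
  shifted <- vol
  shifted$affine[1, 4] <- shifted$affine[1, 4] - shifted$affine[1, 1]
  tr <- transfer_voi(voi, vol, shifted)
  key <- function(v) sort(fetadc:::ijk_to_lin(v, dim(vol$data)))
  expect_equal(key(cbind(tr$voxels[, 1] - 1L, tr$voxels[, 2:3])), key(voi$voxels))
})

test_that("transfer between resolutions preserves volume up to the surface shell", {
  src <- sphere_vol(dims = c(40, 40, 30), spacing = c(2, 2, 2),
                    spheres = list(list(center = c(0, 0, 0), radius = 12,
                                        value = 10)))
  mask <- array(TRUE, dim(src$data))
  comp <- find_hot_components(src, mask, 0.8)[[1]]
  voi <- isocontour_voi(src, comp)
  tgt <- make_vol(array(1, c(30, 30, 20)), spacing = c(3, 3, 3))
  tr <- transfer_voi(voi, src, tgt)
  # every symmetric-difference voxel lies within one source diagonal of
  # the sphere surface (geometric oracle)
  w <- voxel_to_world(tr$voxels, tgt)
  r <- sqrt(rowSums(w^2))
  shell <- sqrt(sum(c(2, 2, 2)^2))
  expect_true(all(r <= 12 + shell))
  inside <- voxel_to_world(as.matrix(expand.grid(0:29, 0:29, 0:19)), tgt)
  ri <- sqrt(rowSums(inside^2))
  lin_tr <- fetadc:::ijk_to_lin(tr$voxels, c(30, 30, 20))
  deep <- which(ri <= 12 - shell)
  expect_true(all(deep %in% lin_tr))
  # disjoint grids signal mis-registration
  far <- make_vol(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
  far$affine[1, 4] <- far$affine[1, 4] + 500
  expect_error(transfer_voi(voi, src, far), "overlap")
})

test_that("margin adaptation removes CSF voxels and flags mis-placed VOIs", {
  adc <- sphere_vol(background = 1000, modality = "ADC",
                    spheres = list(list(center = c(-14, 0, 0), radius = 6,
                                        value = 3000)))
  # 100-voxel VOI, 10 voxels inside the CSF sphere
  csf_lin <- which(adc$data == 3000)[1:10]
  ok_lin <- which(adc$data == 1000)[1:90]
  voi <- lesion_voi(fetadc:::lin_to_ijk(c(csf_lin, ok_lin), dim(adc$data)),
                    grid_id = "adc")
  out <- adapt_margins(voi, adc, csf_cutoff = 2400)
  expect_equal(nrow(out$voxels), 90)
  # nestedness: output is a subset of input
  expect_true(all(fetadc:::ijk_to_lin(out$voxels, dim(adc$data)) %in%
                  fetadc:::ijk_to_lin(voi$voxels, dim(adc$data))))
  # a VOI fully inside CSF errors
  voi_csf <- lesion_voi(fetadc:::lin_to_ijk(csf_lin, dim(adc$data)), "adc")
  expect_error(adapt_margins(voi_csf, adc), "entire VOI")
  # removing more than half the VOI errors
  voi_bad <- lesion_voi(fetadc:::lin_to_ijk(
    c(which(adc$data == 3000)[1:60], ok_lin[1:40]), dim(adc$data)), "adc")
  expect_error(adapt_margins(voi_bad, adc), "mis-placed")
  # an explicit exclusion mask behaves like CSF
  excl <- array(FALSE, dim(adc$data)); excl[ok_lin[1:5]] <- TRUE
  out2 <- adapt_margins(voi, adc, exclusion_mask = excl)
  expect_equal(nrow(out2$voxels), 85)
})

test_that("VOI masks round-trip through NIfTI export", {
  vol <- blob_vol(peak = 10, sigma = 8)
  comp <- find_hot_components(vol, array(TRUE, dim(vol$data)), 0.8)[[1]]
  voi <- isocontour_voi(vol, comp)
  f <- tempfile(fileext = ".nii.gz")
  write_voi_mask(voi, vol, f)
  back <- read_volume(f, "SUV")
  expect_equal(sum(back$data > 0.5), nrow(voi$voxels))
  unlink(f)
})
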