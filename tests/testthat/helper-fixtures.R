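# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures ship with the package.

# scalar_volume on a diagonal affine grid centred at the world origin
make_vol <- function(data, spacing = c(2, 2, 2.5), modality = "SUV") {
  d <- dim(data)
  A <- diag(4)
  A[cbind(1:3, 1:3)] <- spacing
  A[1:3, 4] <- -spacing * (d - 1) / 2
  scalar_volume(data, A, modality)
}

# volume containing one or more solid spheres on a flat background
# spheres: list of list(center = c(x,y,z) mm, radius = mm, value = v)
sphere_vol <- function(dims = c(32, 32, 24), spacing = c(2, 2, 2.5),
                       background = 1, spheres = list(), modality = "SUV") {
  ax <- spacing[1] * (seq_len(dims[1]) - 1 - (dims[1] - 1) / 2)
  ay <- spacing[2] * (seq_len(dims[2]) - 1 - (dims[2] - 1) / 2)
  az <- spacing[3] * (seq_len(dims[3]) - 1 - (dims[3] - 1) / 2)
  data <- array(background, dims)
  for (s in spheres) {
    r2 <- outer(outer((ax - s$center[1])^2, (ay - s$center[2])^2, "+"),
                (az - s$center[3])^2, "+")
    data[r2 <= s$radius^2] <- s$value
  }
  make_vol(data, spacing, modality)
}

# smooth single-peak blob (generalized Gaussian) for isocontour tests
blob_vol <- function(dims = c(32, 32, 24), spacing = c(2, 2, 2.5),
                     background = 1, center = c(9, 1, 1.25), peak = 10,
                     sigma = 8, gamma = 2, modality = "SUV") {
  ax <- spacing[1] * (seq_len(dims[1]) - 1 - (dims[1] - 1) / 2)
  ay <- spacing[2] * (seq_len(dims[2]) - 1 - (dims[2] - 1) / 2)
  az <- spacing[3] * (seq_len(dims[3]) - 1 - (dims[3] - 1) / 2)
  r2 <- outer(outer((ax - center[1])^2, (ay - center[2])^2, "+"),
              (az - center[3])^2, "+")
  data <- background + (peak - background) * exp(-0.5 * (sqrt(r2) / sigma)^gamma)
  make_vol(data, spacing, modality)
}

# geometry overrides for a small, fast phantom grid (used where the test
# exercises mechanics rather than the default study resolution)
tiny_geom <- function() {
  list(grid_shape = c(32L, 32L, 24L),
       voxel_size_mm = c(2, 2, 2.5),
       brain_semi_axes_mm = c(28, 29, 24),
       csf_structures = list(
         list(center_mm = c(7, -12, 5), radius_mm = 4),
         list(center_mm = c(-7, -12, 5), radius_mm = 4)),
       lesion_center_mm = c(15, 1, 1.25),
       lesion_radius_mm = 8,
       lesion_profile_sigma_mm = 5)
}

tiny_spec <- function(...) {
  args <- utils::modifyList(tiny_geom(), list(...))
  do.call(phantom_spec, args)
}

# brute-force Mann-Whitney AUC by pair counting (ties 1/2)
auc_bruteforce <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# grouped delete-one jackknife variance of the AUC (or of an AUC
# difference when two score sets are supplied)
jackknife_auc_var <- function(x, y, x2 = NULL, y2 = NULL) {
  stat <- function(xs, ys, xs2, ys2) {
    if (is.null(xs2)) auc_bruteforce(xs, ys)
    else auc_bruteforce(xs, ys) - auc_bruteforce(xs2, ys2)
  }
  m <- length(x); n <- length(y)
  vx <- vapply(seq_len(m), function(i)
    stat(x[-i], y, x2[-i], y2), numeric(1))
  vy <- vapply(seq_len(n), function(j)
    stat(x, y[-j], x2, y2[-j]), numeric(1))
  (m - 1) / m * sum((vx - mean(vx))^2) +
  (n - 1) / n * sum((vy - mean(vy))^2)
}

# exhaustive OR-rule envelope AUC: enumerate every threshold pair,
# collect operating points, integrate the staircase
# f(u) = max tpr achievable at fpr <= u on a fine grid of u values
envelope_auc_bruteforce <- function(sa, sb, pos) {
  ta <- c(sort(unique(sa)), Inf)
  tb <- c(sort(unique(sb)), Inf)
  pts <- matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE)
  for (t1 in ta) for (t2 in tb) {
    pred <- sa > t1 | sb > t2
    tpr <- sum(pred & pos) / sum(pos)
    fpr <- sum(pred & !pos) / sum(!pos)
    pts <- rbind(pts, c(fpr, tpr))
  }
  # integrate f over the achievable fpr grid, left heights
  us <- sort(unique(pts[, 1]))
  f <- vapply(us, function(u) max(pts[pts[, 1] <= u, 2]), numeric(1))
  sum(diff(us) * f[-length(us)])
}

# independent Youden oracle: J is piecewise constant in the cutoff, so an
# epsilon-scan around every observed score finds the global maximum
youden_max_J_bruteforce <- function(s, pos) {
  eps <- min(diff(sort(unique(s)))) / 4
  if (!is.finite(eps)) eps <- 0.5 # all scores equal
  cand <- unique(c(s - eps, s + eps))
  J <- vapply(cand, function(t)
    mean(s[pos] > t) + mean(s[!pos] <= t) - 1, numeric(1))
  max(J)
}
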