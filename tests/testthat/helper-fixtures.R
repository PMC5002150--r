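# Shared fixtures, all built in code at test time.

# single-compartment cube phantom: a liver-only block inside an empty grid,
# for exact count-statistics checks (uniform SUV, known voxel count)
cube_phantom <- function(side = 10L, grid = 16L, suv = 1.57,
                         counts = 1e5, voxel = 4) {
  gs <- rep(as.integer(grid), 3)
  spec <- phantom_spec(grid_shape = gs, voxel_size = rep(voxel, 3),
                       liver_suv = suv, lung_suv = 0,
                       total_true_counts = counts, subject_id = "CUBE")
  ph <- build_phantom(spec)
  # overwrite with the cube: air everywhere, liver cube in the center
  lab <- array(0L, gs)
  lo <- (grid - side) %/% 2 + 1L
  idx <- lo:(lo + side - 1L)
  lab[idx, idx, idx] <- 2L
  ph$label_map <- lab
  ph$suv_map <- array(0, gs); ph$suv_map[lab == 2L] <- suv
  ph
}

# small two-lesion thorax spec with high-contrast, easily delineable lesions
two_lesion_spec <- function(counts = 1e5, grid = 32L, subject_id = "S1",
                            volumes = c(2, 10), suv = 4) {
  gs <- rep(as.integer(grid), 3)
  centers <- list(as.integer(c(24, 16, 20)), as.integer(c(10, 22, 20)))
  phantom_spec(grid_shape = gs, voxel_size = c(4, 4, 4),
               liver_suv = 1.57, lung_suv = 0.5,
               lesions = list(
                 list(center = centers[[1]], volume_ml = volumes[1], suv = suv),
                 list(center = centers[[2]], volume_ml = volumes[2], suv = suv)),
               total_true_counts = counts, subject_id = subject_id)
}

# peaked 3D "lesion" profile on a mildly textured background, for the
# threshold-sensitivity checks (no reconstruction involved)
peaked_lesion_image <- function(n = 21L, seed = 11) {
  set.seed(seed)
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  img <- 0.5 + 8 * exp(-d2 / 8)
  img + array(stats::rnorm(n^3, 0, 0.02), rep(n, 3))
}

# expectation of the sample SD of n unit-variance normals (c4 constant)
mean_sd_factor <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# brute-force Euclidean-ball dilation minus the mask (independent oracle for
# background_shell): direct per-voxel distance scan
brute_shell <- function(mask, radius) {
  d <- dim(mask)
  vox <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (i in seq_len(nrow(all_idx))) {
    p <- all_idx[i, ]
    dd <- sweep(vox, 2, p, `-`)
    if (min(rowSums(dd^2)) <= radius^2) out[matrix(p, 1)] <- TRUE
  }
  out & !mask
}

# brute-force minimum-counts scan (independent oracle for case_min_counts):
# walk levels from the largest down while the metric stays below threshold
brute_min_counts <- function(counts, values, threshold) {
  o <- order(counts, decreasing = TRUE)
  counts <- counts[o]; values <- values[o]
  best <- NA_real_
  for (i in seq_along(counts)) {
    if (values[i] <= threshold) best <- counts[i] else break
  }
  best
}

# fine grid search for the saturation-curve coefficients (independent oracle
# for fit_normalized_cnr on noiseless points)
grid_search_cnr <- function(x, y, a_grid = seq(1.5, 3.5, by = 0.01),
                            b_grid = seq(0.5, 1.1, by = 0.01)) {
  best <- c(a = NA, b = NA); best_sse <- Inf
  for (a in a_grid) for (b in b_grid) {
    sse <- sum((y - 1 / (1 + a * x^(-b)))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(a = a, b = b) }
  }
  best
}
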