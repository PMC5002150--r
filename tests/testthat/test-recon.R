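test_that("binning backend is linear and exact", {
  gs <- c(4L, 2L, 2L)
  a <- event_stream(c(1L, 1L, 1L), domain = "image", grid_shape = gs)
  b <- event_stream(c(1L, 5L), domain = "image", grid_shape = gs)
  img_a <- bin_image(a, calibration = 2)
  expect_equal(img_a[1], 6)            # 3 events x calibration 2
  expect_equal(sum(img_a), 6)
  ab <- event_stream(c(a$bin_index, b$bin_index), domain = "image",
                     grid_shape = gs)
  expect_equal(unclass(bin_image(ab)),
               unclass(bin_image(a)) + unclass(bin_image(b)))
  empty <- event_stream(integer(0), domain = "image", grid_shape = gs)
  expect_true(all(bin_image(empty) == 0))
  bad <- event_stream(17L, domain = "image", grid_shape = gs)
  expect_error(bin_image(bad), "out of grid")
})

test_that("liver calibration puts the full-statistics liver mean on target", {
  ph <- cube_phantom(counts = 2e5, suv = 1.57)
  st <- generate_events(ph, seed = 1)
  calib <- liver_calibration(st, ph$label_map == 2L, 1.57)
  img <- bin_image(st, calibration = calib)
  liver_mean <- mean(unclass(img)[ph$label_map == 2L])
  expect_lt(abs(liver_mean - 1.57) / 1.57, 0.01)
})

test_that("forward and back projection are exact adjoints", {
  geom <- projection_geometry(24, pixel_size = 4, n_angles = 21)
  set.seed(2)
  x <- matrix(stats::runif(24^2), 24)
  y <- matrix(stats::runif(geom$n_radial * geom$n_angles), geom$n_radial)
  lhs <- sum(forward_project(x, geom) * y)
  rhs <- sum(x * back_project(y, geom))
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-6)
})

test_that("projection geometry reproduces point and disk profiles", {
  geom <- projection_geometry(32, pixel_size = 4, n_angles = 21)
  expect_true(all(forward_project(matrix(0, 32, 32), geom) == 0))
  hot <- matrix(0, 32, 32); hot[16, 16] <- 1
  sino <- forward_project(hot, geom)
  # one dominant radial bin per angle (a point projects to a point)
  for (a in seq_len(geom$n_angles))
    expect_gte(max(sino[, a]) / sum(sino[, a]), 0.5)
  # uniform disk: profile matches the analytic chord length within 2% RMS
  geom64 <- projection_geometry(64, pixel_size = 4, n_angles = 63)
  coords <- (seq_len(64) - 32.5) * 4
  R <- 80
  disk <- outer(coords, coords, function(x, y) as.numeric(x^2 + y^2 <= R^2))
  sino64 <- forward_project(disk, geom64)
  chord <- outer(coords, geom64$angles,
                 function(s, a) ifelse(abs(s) < R, 2 * sqrt(pmax(R^2 - s^2, 0)), 0))
  expect_lt(sqrt(mean((sino64 - chord)^2)) / max(chord), 0.02)
})

test_that("OSEM recovers a uniform disk at high counts and stays positive", {
  geom <- projection_geometry(48, pixel_size = 4, n_angles = 63)
  coords <- (seq_len(48) - 24.5) * 4
  R <- 60
  disk <- outer(coords, coords, function(x, y) as.numeric(x^2 + y^2 <= R^2))
  st <- sinogram_stream(disk, geom, 2e6, seed = 3)
  calib <- sum(forward_project(disk, geom)) / 2e6
  img <- osem_reconstruct(bin_sinogram(st, geom), geom, calibration = calib)
  expect_true(min(img) >= 0)
  inner <- outer(coords, coords, function(x, y) x^2 + y^2 <= (0.8 * R)^2)
  expect_lt(abs(mean(unclass(img)[inner]) - 1), 0.05)
})

test_that("OSEM degenerate inputs behave as contracted", {
  geom <- projection_geometry(16, pixel_size = 4, n_angles = 21)
  expect_warning(z <- osem_reconstruct(matrix(0, 16, 21), geom),
                 "zero total counts")
  expect_true(all(z == 0))
  expect_true(isTRUE(attr(z, "zero_counts")))
  # 0 iterations: the (smoothed) uniform initialization comes back
  sino <- matrix(5, 16, 21)
  init <- osem_reconstruct(sino, geom, n_iter = 0)
  expect_lt(max(init) - min(init), 1e-10)
  expect_error(osem_reconstruct(matrix(-1, 16, 21), geom), "nonnegative")
})

test_that("the post-filter monotonically reduces ensemble noise", {
  geom <- projection_geometry(32, pixel_size = 4, n_angles = 63)
  coords <- (seq_len(32) - 16.5) * 4
  disk <- outer(coords, coords, function(x, y) as.numeric(x^2 + y^2 <= 50^2))
  recon_sd <- function(fwhm) {
    imgs <- lapply(1:4, function(i) {
      st <- sinogram_stream(disk, geom, 2e4, seed = 100 + i)
      osem_reconstruct(bin_sinogram(st, geom), geom, post_filter_fwhm = fwhm)
    })
    mean(ensemble_stats(imgs)$sd_image)
  }
  expect_lt(recon_sd(5), recon_sd(0))
})

test_that("ensemble reconstruction yields one image per realization", {
  ph <- cube_phantom(side = 8L, counts = 4e4)
  st <- generate_events(ph, seed = 1)
  ens <- make_ensembles(st, fraction_schedule(c(0.5, 0.25),
                                              n_realizations = 3),
                        master_seed = 2)
  rec <- reconstruct_ensemble(st, ens, backend = "bin",
                              liver_mask = ph$label_map == 2L,
                              liver_suv = 1.57)
  expect_length(rec, 2)
  expect_length(rec[[1]]$realizations, 3)
  # distinct realizations give distinct images
  expect_false(identical(unclass(rec[[1]]$realizations[[1]]),
                         unclass(rec[[1]]$realizations[[2]])))
  # at fraction 1 the binned image equals the reference exactly
  ens1 <- make_ensembles(st, fraction_schedule(1, n_realizations = 2),
                         master_seed = 2)
  rec1 <- reconstruct_ensemble(st, ens1, backend = "bin",
                               liver_mask = ph$label_map == 2L,
                               liver_suv = 1.57)
  expect_equal(unclass(rec1[[1]]$realizations[[1]]),
               unclass(rec1[[1]]$reference), ignore_attr = TRUE)
})

test_that("streams of mixed domains are rejected", {
  ph <- cube_phantom(side = 8L, counts = 1e3)
  st <- generate_events(ph, seed = 1)
  ens <- make_ensembles(st, fraction_schedule(0.5, n_realizations = 2), 1)
  ens[[1]]$streams[[1]]$domain <- "sinogram"
  expect_error(reconstruct_ensemble(st, ens, backend = "bin",
                                    liver_mask = ph$label_map == 2L,
                                    liver_suv = 1.57),
               "mixed")
})
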