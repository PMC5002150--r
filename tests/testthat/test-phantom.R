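test_that("cohort sampling reproduces the target count and SUV statistics", {
  specs <- sample_cohort(16, master_seed = 123, scale = 1)
  expect_length(specs, 16)
  counts <- vapply(specs, function(s) s$total_true_counts, numeric(1))
  # mean within 3 standard errors of 1.32e8 (SD 3.91e7, n = 16)
  expect_lt(abs(mean(counts) - 1.32e8), 3 * 3.91e7 / sqrt(16))
  weights <- vapply(specs, function(s) s$weight, numeric(1))
  expect_true(all(weights >= 45 & weights <= 79))
  liver <- vapply(specs, function(s) s$liver_suv, numeric(1))
  expect_true(all(liver > 0))
  vols <- unlist(lapply(specs, function(s)
    vapply(s$lesions, function(l) l$volume_ml, numeric(1))))
  expect_true(all(vols >= 1.2 & vols <= 17.58))
  suvs <- unlist(lapply(specs, function(s)
    vapply(s$lesions, function(l) l$suv, numeric(1))))
  expect_true(all(suvs >= 0.5))
  # attenuation grows with weight
  o <- order(weights)
  att <- vapply(specs, function(s) s$attenuation_factor, numeric(1))
  expect_true(all(diff(att[o]) > 0))
})

test_that("cohort sampling is deterministic in the seed and honors scale", {
  a <- sample_cohort(3, master_seed = 9)
  b <- sample_cohort(3, master_seed = 9)
  expect_identical(a, b)
  small <- sample_cohort(100, master_seed = 5, scale = 0.01)
  counts <- vapply(small, function(s) s$total_true_counts, numeric(1))
  expect_true(all(counts > 0))
  expect_lt(abs(mean(counts) - 1.32e6), 4 * 3.91e5 / sqrt(100))
  expect_error(sample_cohort(0, 1), "n_subjects")
  expect_error(sample_cohort(2, 1, scale = 0), "scale")
})

test_that("lesion rasterization hits the requested volume within a voxel", {
  spec <- phantom_spec(lesions = list(
    list(center = c(46L, 32L, 40L), volume_ml = 1.2, suv = 3)))
  ph <- build_phantom(spec)
  n <- sum(ph$label_map == 3L)
  expect_equal(n, round(1.2 / 0.064))  # 4 mm voxels: 0.064 ml each
  expect_true(all(ph$suv_map[ph$label_map == 3L] == 3))
})

test_that("label map carries exactly the declared compartments", {
  ph0 <- build_phantom(phantom_spec())
  expect_setequal(unique(as.vector(ph0$label_map)), c(0L, 1L, 2L))
  spec2 <- phantom_spec(lesions = list(
    list(center = c(46L, 32L, 40L), volume_ml = 2, suv = 3),
    list(center = c(18L, 32L, 40L), volume_ml = 2, suv = 2)))
  ph2 <- build_phantom(spec2)
  expect_setequal(unique(as.vector(ph2$label_map)), c(0L, 1L, 2L, 3L, 4L))
})

test_that("overlapping lesions are rejected", {
  spec <- phantom_spec(lesions = list(
    list(center = c(46L, 32L, 40L), volume_ml = 10, suv = 3),
    list(center = c(45L, 32L, 40L), volume_ml = 10, suv = 2)))
  expect_error(build_phantom(spec), "overlaps")
})

test_that("event generation follows the fixed-total multinomial convention", {
  ph <- cube_phantom(counts = 1000)
  st <- generate_events(ph, seed = 3)
  expect_s3_class(st, "event_stream")
  expect_equal(st$n_true, 1000)
  expect_equal(st$n_random, 0)
  expect_length(st$bin_index, 1000)
  # all events land in the (only) active compartment
  expect_true(all(ph$label_map[st$bin_index] == 2L))
  # same seed, byte-identical stream
  st2 <- generate_events(ph, seed = 3)
  expect_identical(st$bin_index, st2$bin_index)
})

test_that("per-voxel counts are multinomial over the uniform SUV map", {
  ph <- cube_phantom(side = 8L, counts = 1e6)
  st <- generate_events(ph, seed = 4)
  counts <- tabulate(st$bin_index, nbins = length(ph$suv_map))
  occ <- which(ph$suv_map > 0)
  gof <- stats::chisq.test(counts[occ])
  expect_gt(gof$p.value, 0.001)
})

test_that("randoms are generated at the requested fraction and flagged", {
  gs <- rep(16L, 3)
  spec <- phantom_spec(grid_shape = gs, voxel_size = c(4, 4, 4),
                       total_true_counts = 5000, randoms_fraction = 0.2)
  ph <- build_phantom(spec)
  st <- generate_events(ph, seed = 5)
  expect_equal(st$n_true, 5000)
  expect_equal(st$n_random, round(0.2 * 5000 / 0.8))
  expect_equal(st$n_true + st$n_random, length(st$bin_index))
  expect_equal(sum(!st$is_random), st$n_true)
})

test_that("empirical voxel proportions converge to the SUV proportions", {
  # two-compartment phantom, 1e6 events: liver activity share within 1%
  spec <- phantom_spec(total_true_counts = 1e6)
  ph <- build_phantom(spec)
  st <- generate_events(ph, seed = 6)
  p_liver <- sum(ph$suv_map[ph$label_map == 2L]) / sum(ph$suv_map)
  frac <- mean(ph$label_map[st$bin_index] == 2L)
  expect_lt(abs(frac - p_liver) / p_liver, 0.01)
})

test_that("effective dose applies the ICRP coefficient", {
  expect_equal(effective_dose(370), 7.03)
  expect_equal(effective_dose(0), 0)
  expect_equal(effective_dose(100), 1.9)
  expect_error(effective_dose(-1), ">= 0")
})
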