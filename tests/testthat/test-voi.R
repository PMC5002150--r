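test_that("threshold delineation applies the percent-of-SUVmax rule", {
  profile <- array(c(1, 4, 10, 6, 2), dim = c(5, 1, 1))
  m40 <- threshold_voi(profile, c(1L, 1L, 1L), 40)  # seed climbs to the peak
  expect_equal(which(as.logical(m40)), 2:4)          # values >= 4.0
  m80 <- threshold_voi(profile, c(3L, 1L, 1L), 80)
  expect_equal(which(as.logical(m80)), 3L)           # only the 10
  m100 <- threshold_voi(profile, c(3L, 1L, 1L), 100)
  expect_equal(which(as.logical(m100)), 3L)
})

test_that("threshold masks are restricted to the seed's connected component", {
  img <- array(0.1, c(9, 9, 1))
  img[2:3, 2:3, 1] <- 5     # lesion A
  img[7:8, 7:8, 1] <- 6     # lesion B, brighter, disconnected
  m <- threshold_voi(img, c(2L, 2L, 1L), 40)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] <= 3))
  expect_equal(attr(m, "n_voxels"), 4L)
})

test_that("threshold delineation is monotone in the threshold", {
  set.seed(21)
  for (rep in 1:5) {
    img <- peaked_lesion_image(15L, seed = rep)
    seed_vox <- c(8L, 8L, 8L)
    prev <- NULL
    for (pct in c(20, 40, 60, 80)) {
      m <- threshold_voi(img, seed_vox, pct)
      if (!is.null(prev)) expect_true(all(!(m & !prev)))  # m subset of prev
      prev <- m
    }
  }
})

test_that("spherical VOIs rasterize the inclusive center-distance rule", {
  # diameter of two voxel widths: center plus its six face neighbors
  m <- sphere_voi(c(9L, 9L, 9L), c(5L, 5L, 5L), diameter_mm = 8,
                  voxel_size = c(4, 4, 4))
  expect_equal(attr(m, "n_voxels"), 7L)
  idx <- which(m, arr.ind = TRUE)
  expect_true(all(rowSums(abs(sweep(idx, 2, c(5, 5, 5)))) <= 1))
  # sub-voxel diameter: only the center voxel
  m1 <- sphere_voi(c(9L, 9L, 9L), c(5L, 5L, 5L), diameter_mm = 3,
                   voxel_size = c(4, 4, 4))
  expect_equal(attr(m1, "n_voxels"), 1L)
  # 30 mm sphere on 4 mm voxels: frozen lattice enumeration (251 voxels);
  # the lattice overcount against (pi/6) d^3 = 14.14 ml is real
  m30 <- sphere_voi(c(17L, 17L, 17L), c(9L, 9L, 9L), diameter_mm = 30,
                    voxel_size = c(4, 4, 4))
  expect_equal(attr(m30, "n_voxels"), 251L)
  expect_error(sphere_voi(c(9L, 9L, 9L), c(2L, 5L, 5L), diameter_mm = 30,
                          voxel_size = c(4, 4, 4)), "clipped")
})

test_that("sphere volume converges to the analytic volume as voxels shrink", {
  analytic <- pi / 6 * 30^3 / 1000  # 14.14 ml
  err <- vapply(c(4, 2, 1), function(vs) {
    n <- as.integer(2 * ceiling(15 / vs) + 5)
    c <- as.integer((n + 1) / 2)
    m <- sphere_voi(rep(n, 3), rep(c, 3), 30, rep(vs, 3))
    abs(attr(m, "volume_ml") - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.02)
})

test_that("the background shell is a Euclidean dilation minus the lesion", {
  # single-voxel lesion, radius 2: 33-voxel ball minus the center
  les <- array(FALSE, c(9, 9, 9)); les[5, 5, 5] <- TRUE
  sh <- background_shell(voi_mask(les, "lesion"), 2)
  expect_equal(attr(sh, "n_voxels"), 32L)
  expect_false(any(sh & les))
  # radius 0: empty shell
  sh0 <- background_shell(voi_mask(les, "lesion"), 0)
  expect_equal(attr(sh0, "n_voxels"), 0L)
  # boundary clipping is an error
  edge <- array(FALSE, c(5, 5, 5)); edge[1, 3, 3] <- TRUE
  expect_error(background_shell(voi_mask(edge, "lesion"), 2), "clipped")
})

test_that("shells match the brute-force set difference on random masks", {
  set.seed(31)
  for (rep in 1:5) {
    m <- array(FALSE, c(11, 11, 11))
    vox <- cbind(sample(5:7, 4, TRUE), sample(5:7, 4, TRUE),
                 sample(5:7, 4, TRUE))
    m[vox] <- TRUE
    sh <- background_shell(voi_mask(m, "lesion"), 2)
    expect_identical(array(as.logical(sh), dim(m)), brute_shell(m, 2))
  }
})

test_that("lesion inclusion filtering uses inclusive volume and CNR bounds", {
  rec <- data.frame(id = 1:4, volume_ml = c(5, 25, 5, 20),
                    cnr = c(3, 3, 1.5, 2))
  kept <- filter_lesions(rec)
  expect_equal(kept$id, c(1L, 4L))  # (20 ml, 2.0) boundary case kept
  expect_equal(nrow(filter_lesions(rec[0, ])), 0L)
})

test_that("volume splitting assigns the boundary to the large group", {
  rec <- data.frame(id = 1:3, volume_ml = c(1, 5, 10))
  sp <- split_by_volume(rec, 5)
  expect_equal(sp$small$volume_ml, 1)
  expect_equal(sp$large$volume_ml, c(5, 10))
  all_small <- split_by_volume(data.frame(volume_ml = c(1, 2)), 5)
  expect_equal(nrow(all_small$large), 0L)
})
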