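test_that("ensemble mean and SD images use the sample divisor", {
  a <- array(0, c(2, 2, 1)); b <- array(2, c(2, 2, 1))
  st <- ensemble_stats(list(a, b))
  expect_true(all(st$mean_image == 1))
  expect_true(all(abs(st$sd_image - sqrt(2)) < 1e-12))
  same <- ensemble_stats(list(b, b, b))
  expect_true(all(same$sd_image == 0))
  expect_error(ensemble_stats(list(a)), "at least 2")
  expect_error(ensemble_stats(list(a, array(0, c(3, 2, 1)))), "mismatched")
})

test_that("ensemble SD is calibrated on unit-variance noise", {
  set.seed(5)
  imgs <- lapply(1:10, function(i) array(stats::rnorm(4000), c(20, 20, 10)))
  st <- ensemble_stats(imgs)
  expect_lt(abs(mean(st$sd_image) - mean_sd_factor(10)), 0.1)
})

test_that("VOI statistics follow the population-SD convention", {
  img <- array(c(1, 2, 3, 99), c(4, 1, 1))
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  vs <- voi_stats(img, mask)
  expect_equal(vs$mean, 2)
  expect_equal(vs$sd, sqrt(2 / 3))
  expect_equal(vs$snr, 2 / sqrt(2 / 3))
  expect_equal(vs$suvmax, 3)
  const <- voi_stats(array(5, c(3, 1, 1)), array(TRUE, c(3, 1, 1)))
  expect_true(const$flagged)
  expect_equal(const$snr, Inf)
  single <- voi_stats(img, array(c(TRUE, FALSE, FALSE, FALSE), c(4, 1, 1)))
  expect_equal(single$mean, 1)
  expect_equal(single$sd, 0)
})

test_that("CNR follows the lesion-background contrast formula", {
  img <- array(1, c(6, 1, 1))
  img[1:2] <- 2                       # lesion
  img[3:6] <- c(0.5, 1.5, 0.5, 1.5)   # background, mean 1, SD 0.5
  les <- array(c(TRUE, TRUE, rep(FALSE, 4)), c(6, 1, 1))
  sh <- array(c(FALSE, FALSE, rep(TRUE, 4)), c(6, 1, 1))
  expect_equal(cnr(img, les, sh), 2)
  expect_equal(cnr(img * 2, les, sh), 2)  # scale invariance
  flat <- array(1, c(6, 1, 1))   # zero-SD shell: flagged infinite sentinel
  expect_true(is.infinite(cnr(flat, les, sh)))
  img0 <- img; img0[1:2] <- 1
  expect_equal(cnr(img0, les, sh), 0)
  expect_error(cnr(img, les, les), "overlap")
})

test_that("bias is the percent deviation from full statistics", {
  expect_equal(suv_bias(1, 1), 0)
  expect_equal(suv_bias(0.9, 1), -10)
  expect_equal(suv_bias(1.2, 1), 20)
  expect_error(suv_bias(1, 0), "positive")
})

test_that("ensemble COV is SD over mean in percent", {
  mean_img <- array(2, c(3, 1, 1)); sd_img <- array(0.2, c(3, 1, 1))
  mask <- array(TRUE, c(3, 1, 1))
  expect_equal(ensemble_cov(mean_img, sd_img, mask), 10)
  expect_equal(ensemble_cov(mean_img, sd_img * 0, mask), 0)
  expect_equal(ensemble_cov(mean_img, sd_img, mask, inverse_ratio = TRUE), 1000)
})

test_that("STE is the across-realization coefficient of variation", {
  expect_equal(ste(c(1, 2, 3)), 50)
  expect_equal(ste(c(2, 4, 6)), 50)   # scale invariance
  expect_equal(ste(c(3, 3, 3)), 0)
  expect_error(ste(2), ">= 2")
})

test_that("higher delineation thresholds raise CNR on a peaked lesion", {
  img <- peaked_lesion_image(21L, seed = 11)
  ens <- list(subject = "S1", fraction = 0.5,
              realizations = list(img, img + 0.01),
              mean_image = img, sd_image = array(0, dim(img)),
              reference = img,
              realized_counts = c(100, 100))
  class(ens) <- "recon_ensemble"
  tab <- threshold_sensitivity(ens, c(11L, 11L, 11L))
  expect_equal(tab$threshold_pct, c(20, 40, 60, 80))
  expect_gt(tab$cnr[4], tab$cnr[1])
  expect_true(all(diff(tab$cnr) >= 0))
  expect_true(is.finite(attr(tab, "cov_across_thresholds")))
})

test_that("a constant lesion yields identical masks at all thresholds", {
  # mildly textured background so the shell SD is finite, flat-topped lesion
  img <- array(0.2 + 0.002 * (seq_len(729) %% 7), c(9, 9, 9))
  img[4:6, 4:6, 4:6] <- 2
  ens <- list(subject = "S1", fraction = 1,
              realizations = list(img, img),
              mean_image = img, sd_image = array(0, dim(img)),
              reference = img, realized_counts = c(1, 1))
  class(ens) <- "recon_ensemble"
  tab <- threshold_sensitivity(ens, c(5L, 5L, 5L))
  expect_true(all(abs(tab$cnr - tab$cnr[1]) < 1e-12))
})

test_that("metric tables carry one record per region, metric and fraction", {
  ph <- cube_phantom(side = 8L, counts = 4e4)
  st <- generate_events(ph, seed = 1)
  ens <- make_ensembles(st, fraction_schedule(c(0.5, 0.25),
                                              n_realizations = 3), 2)
  rec <- reconstruct_ensemble(st, ens, backend = "bin",
                              liver_mask = ph$label_map == 2L,
                              liver_suv = 1.57)
  vois <- list(liver = voi_mask(ph$label_map == 2L, "liver",
                                voxel_size = c(4, 4, 4)))
  tab <- do.call(rbind, lapply(rec, ensemble_metrics, vois = vois))
  expect_equal(nrow(tab), 2 * 9)  # 2 fractions x 9 metrics, one region
  expect_false(any(duplicated(tab[c("region", "fraction", "metric")])))
  # bias of the full-statistics ensemble mean is centered near zero
  expect_lt(abs(mean(tab$value[tab$metric == "bias_mean"])), 5)
})
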