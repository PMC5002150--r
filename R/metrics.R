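#' Voxelwise mean and SD images of a realization ensemble
#'
#' @param realizations list of >= 2 images (arrays) on one grid.
#' @return list with `mean_image` and `sd_image` (sample SD, divisor R - 1;
#'   the realization count R is small, so the unbiased divisor is used for
#'   across-realization spread, unlike the spatial SD of [voi_stats()]).
#' @export
ensemble_stats <- function(realizations) {
  R <- length(realizations)
  if (R < 2L) stop("need at least 2 realizations")
  d <- dim(realizations[[1]])
  for (img in realizations)
    if (!identical(dim(img), d)) stop("realizations on mismatched grids")
  acc <- array(0, d); acc2 <- array(0, d)
  for (img in realizations) {
    v <- unclass(img)
    acc <- acc + v
    acc2 <- acc2 + v^2
  }
  mean_img <- acc / R
  var_img <- pmax(0, (acc2 - R * mean_img^2) / (R - 1))
  list(mean_image = mean_img, sd_image = sqrt(var_img))
}

#' VOI statistics: mean, spatial SD, SNR and SUVmax
#'
#' The spatial SD uses the population divisor (the number of VOI voxels),
#' and SNR is the mean-to-SD ratio — both evaluated on whatever image is
#' supplied, conventionally the ensemble mean image. A constant VOI yields
#' `snr = Inf` with `flagged = TRUE`.
#'
#' @param image numeric array.
#' @param mask logical array or [voi_mask()].
#' @return list: `mean`, `sd`, `snr`, `suvmax`, `n_voxels`, `flagged`.
#' @export
voi_stats <- function(image, mask) {
  m <- as_mask_array(mask)
  vals <- unclass(image)[m]
  if (length(vals) == 0L) stop("empty mask")
  n <- length(vals)
  mu <- mean(vals)
  sdv <- sqrt(sum((vals - mu)^2) / n)
  flagged <- sdv == 0
  list(mean = mu, sd = sdv,
       snr = if (flagged) Inf else mu / sdv,
       suvmax = max(vals), n_voxels = n, flagged = flagged)
}

#' Contrast-to-noise ratio of a lesion against its background shell
#'
#' `(mean(lesion) - mean(shell)) / spatial SD(shell)`, evaluated on the
#' ensemble mean image. Scale-invariant; a zero-SD shell yields `Inf` with a
#' `flagged` attribute.
#'
#' @param mean_image ensemble mean image.
#' @param lesion,shell disjoint masks ([voi_mask()] or logical arrays).
#' @return CNR value.
#' @export
cnr <- function(mean_image, lesion, shell) {
  lm <- as_mask_array(lesion); sm <- as_mask_array(shell)
  if (any(lm & sm)) stop("lesion and shell overlap")
  ls <- voi_stats(mean_image, lm)
  bs <- voi_stats(mean_image, sm)
  if (bs$sd == 0)
    return(structure(Inf, flagged = TRUE))
  (ls$mean - bs$mean) / bs$sd
}

#' Percent bias of a reduced-count SUV against full statistics
#'
#' @param mean_frac VOI SUV (mean or max) at the reduced count level.
#' @param mean_full same quantity at full statistics; must be positive.
#' @return percent difference `(frac - full) / full * 100`.
#' @export
suv_bias <- function(mean_frac, mean_full) {
  if (any(mean_full <= 0)) stop("full-statistics reference must be positive")
  (mean_frac - mean_full) / mean_full * 100
}

#' Ensemble coefficient of variation in a VOI
#'
#' Statistical (ensemble) noise: the VOI mean of the across-realization SD
#' image relative to the VOI mean of the mean image, in percent — the
#' universal coefficient-of-variation definition. The inverted orientation
#' (mean over SD), which some formulations of the ensemble-noise metric
#' use, is available with `inverse_ratio = TRUE`.
#'
#' @param mean_image,sd_image ensemble mean and SD images.
#' @param mask VOI mask.
#' @param inverse_ratio return mean/SD x 100 instead of SD/mean x 100.
#' @return COV in percent.
#' @export
ensemble_cov <- function(mean_image, sd_image, mask, inverse_ratio = FALSE) {
  m <- as_mask_array(mask)
  mu <- mean(unclass(mean_image)[m])
  sdv <- mean(unclass(sd_image)[m])
  if (inverse_ratio) {
    if (sdv <= 0) stop("zero SD denominator")
    return(mu / sdv * 100)
  }
  if (mu <= 0) stop("zero mean denominator")
  sdv / mu * 100
}

#' Standard error of a SUV measurement across realizations
#'
#' Reproducibility of a per-realization SUV statistic (SUVmean or SUVmax):
#' sample SD (divisor R - 1) over the realization values relative to their
#' mean, in percent. Scale invariant.
#'
#' @param values one SUV value per realization, R >= 2.
#' @return STE in percent.
#' @export
ste <- function(values) {
  if (length(values) < 2L) stop("need >= 2 realization values")
  mu <- mean(values)
  if (mu == 0) stop("zero mean")
  stats::sd(values) / mu * 100
}

#' CNR sensitivity to the delineation threshold
#'
#' Re-delineates the lesion at each SUVmax percentage, computes CNR on the
#' ensemble mean image per threshold, and summarizes the spread of the
#' per-realization CNR values. The background shell derived from the lowest
#' (20%) threshold mask is reused for all thresholds.
#'
#' @param ensemble a `recon_ensemble` (needs `mean_image`, `realizations`,
#'   `reference`).
#' @param seed_voxel lesion seed on the full-statistics reference image.
#' @param pcts thresholds in percent of SUVmax, default `c(20, 40, 60, 80)`.
#' @param voxel_size mm per axis.
#' @return data frame (threshold_pct, cnr, cnr_cov_realizations) with the
#'   across-threshold COV of the mean-image CNR as attribute
#'   `"cov_across_thresholds"`.
#' @export
threshold_sensitivity <- function(ensemble, seed_voxel,
                                  pcts = c(20, 40, 60, 80),
                                  voxel_size = c(4, 4, 4)) {
  ref <- ensemble$reference
  masks <- lapply(pcts, function(p)
    threshold_voi(ref, seed_voxel, p, voxel_size = voxel_size))
  shell <- background_shell(masks[[which.min(pcts)]])
  rows <- lapply(seq_along(pcts), function(i) {
    cm <- cnr(ensemble$mean_image, masks[[i]], shell)
    per_real <- vapply(ensemble$realizations, function(img)
      as.numeric(cnr(img, masks[[i]], shell)), numeric(1))
    data.frame(threshold_pct = pcts[i], cnr = as.numeric(cm),
               cnr_cov_realizations = if (mean(per_real) != 0)
                 stats::sd(per_real) / mean(per_real) * 100 else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "cov_across_thresholds") <-
    stats::sd(out$cnr) / mean(out$cnr) * 100
  out
}

#' Long-format image-quality metrics for one reconstructed ensemble
#'
#' Computes, per region, the SUVmean/SUVmax of the mean image, SNR, CNR (for
#' lesions), percent bias of SUVmean and SUVmax against the full-statistics
#' reference, ensemble COV, and STE of SUVmean and SUVmax across
#' realizations.
#'
#' @param ensemble a `recon_ensemble`.
#' @param vois named list of region masks; lesions must be named `lesion*`
#'   and have a matching `shell` entry `shell_<name>` for CNR.
#' @param cov_inverse_ratio COV orientation, see [ensemble_cov()].
#' @return data frame: subject, region, fraction, counts (mean realized true
#'   counts), metric, value.
#' @export
ensemble_metrics <- function(ensemble, vois, cov_inverse_ratio = FALSE) {
  mean_img <- ensemble$mean_image
  sd_img <- ensemble$sd_image
  ref <- ensemble$reference
  counts <- mean(ensemble$realized_counts)
  rows <- list()
  add <- function(region, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = ensemble$subject %||% "S1", region = region,
      fraction = ensemble$fraction, counts = counts,
      metric = metric, value = as.numeric(value))
  regions <- names(vois)[!startsWith(names(vois), "shell_")]
  for (rg in regions) {
    mask <- vois[[rg]]
    vs <- voi_stats(mean_img, mask)
    rs <- voi_stats(ref, mask)
    add(rg, "suvmean", vs$mean)
    add(rg, "suvmax", vs$suvmax)
    add(rg, "snr", vs$snr)
    add(rg, "bias_mean", suv_bias(vs$mean, rs$mean))
    add(rg, "bias_max", suv_bias(vs$suvmax, rs$suvmax))
    add(rg, "cov_mean", ensemble_cov(mean_img, sd_img, mask,
                                     inverse_ratio = cov_inverse_ratio))
    m_arr <- as_mask_array(mask)
    add(rg, "cov_max",
        max(unclass(sd_img)[m_arr]) / max(unclass(mean_img)[m_arr]) * 100)
    per_mean <- vapply(ensemble$realizations, function(im)
      voi_stats(im, mask)$mean, numeric(1))
    per_max <- vapply(ensemble$realizations, function(im)
      voi_stats(im, mask)$suvmax, numeric(1))
    add(rg, "ste_mean", ste(per_mean))
    add(rg, "ste_max", ste(per_max))
    shell_name <- paste0("shell_", rg)
    if (shell_name %in% names(vois))
      add(rg, "cnr", cnr(mean_img, mask, vois[[shell_name]]))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
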