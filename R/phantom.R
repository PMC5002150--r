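#' Digital thorax phantom specification
#'
#' A `phantom_spec` describes one synthetic subject: an activity distribution
#' (liver, lung background and spherical lung lesions, in SUV units) together
#' with the acquisition metadata needed downstream (body weight, injected
#' dose, scan time, attenuation factor and the total number of net true
#' coincidences in the full-statistics scan).
#'
#' The composite scanner sensitivity `sensitivity` lumps the proportionality
#' constant, the reconstruction noise-reduction factor and the scanner
#' sensitivity into one number; together with the attenuation factor it ties
#' the detected counts to dose and scan time (counts ~ sensitivity / a(m) x
#' dose x time).
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param voxel_size numeric(3), mm per axis.
#' @param weight body weight in kg.
#' @param injected_dose injected activity in MBq.
#' @param scan_time acquisition time in s.
#' @param liver_suv,lung_suv uniform SUV of liver and lung background.
#' @param lesions list of lesions, each a list with `center` (voxel index
#'   triple), `volume_ml` and `suv`.
#' @param attenuation_factor unitless a(m) >= 1; if `NULL`, computed from the
#'   weight as `exp(0.012 * weight)` (a documented monotone-increasing form;
#'   only monotonicity matters because the per-subject sensitivity is
#'   estimated empirically downstream).
#' @param total_true_counts net true coincidences in the full-statistics scan.
#' @param randoms_fraction fraction of the prompt stream that is random
#'   coincidences, in `[0, 1)`.
#' @param sensitivity composite scanner factor; if `NULL`, derived so that
#'   counts = sensitivity / a(m) x dose x time holds for this subject.
#' @param subject_id identifier carried through provenance.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = c(4, 4, 4),
                         weight = 58.5,
                         injected_dose = 168.6,
                         scan_time = 900,
                         liver_suv = 1.57,
                         lung_suv = 0.5,
                         lesions = list(),
                         attenuation_factor = NULL,
                         total_true_counts = 1.32e6,
                         randoms_fraction = 0,
                         sensitivity = NULL,
                         subject_id = "S1") {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            weight > 0, injected_dose > 0, scan_time > 0,
            liver_suv >= 0, lung_suv >= 0,
            total_true_counts >= 0,
            randoms_fraction >= 0, randoms_fraction < 1)
  if (is.null(attenuation_factor)) attenuation_factor <- exp(0.012 * weight)
  if (attenuation_factor < 1) stop("attenuation_factor must be >= 1")
  for (les in lesions) {
    stopifnot(is.list(les), les$volume_ml > 0, les$suv >= 0,
              length(les$center) == 3L)
    if (any(les$center < 1) || any(les$center > grid_shape))
      stop("lesion center outside grid")
  }
  if (is.null(sensitivity))
    sensitivity <- total_true_counts * attenuation_factor /
      (injected_dose * scan_time)
  structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    weight = weight, injected_dose = injected_dose, scan_time = scan_time,
    liver_suv = liver_suv, lung_suv = lung_suv, lesions = lesions,
    attenuation_factor = attenuation_factor, sensitivity = sensitivity,
    total_true_counts = total_true_counts,
    randoms_fraction = randoms_fraction, subject_id = subject_id
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec %s> %d lesion(s), weight %.1f kg, %.3g true counts\n",
              x$subject_id, length(x$lesions), x$weight, x$total_true_counts))
  invisible(x)
}

#' Sample a synthetic subject cohort
#'
#' Draws subject-level parameters from the cohort distributions: weight
#' uniform on 45-79 kg, liver SUVmean normal(1.57, 0.40) truncated positive,
#' lesion SUVmean normal(1.92, 0.95) truncated at 0.5, lesion volumes uniform
#' on 1.2-17.58 ml, injected dose normal(168.6, 50) truncated to 118-260.5
#' MBq, and full-statistics net true counts normal(1.32e8, 3.91e7) truncated
#' positive, multiplied by `scale` for desk-scale runs. Each subject receives
#' one to three lesions placed at fixed lung positions (a ring in the upper
#' lung field, clear of the liver).
#'
#' @param n_subjects number of subjects, >= 1.
#' @param master_seed integer seed; the cohort is reproducible from it.
#' @param scale count-scaling factor in (0, 1] applied to the full-statistics
#'   counts.
#' @param grid_shape,voxel_size phantom grid passed to each spec.
#' @param randoms_fraction randoms fraction shared by all subjects.
#'
#' @return list of [phantom_spec()] objects.
#' @export
sample_cohort <- function(n_subjects, master_seed = 1L, scale = 1,
                          grid_shape = c(64L, 64L, 64L),
                          voxel_size = c(4, 4, 4),
                          randoms_fraction = 0) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  set.seed(as.integer(master_seed))
  lapply(seq_len(n_subjects), function(i) {
    weight <- stats::runif(1, 45, 79)
    liver_suv <- rnorm_trunc(1, 1.57, 0.40, lower = 1e-6)
    dose <- rnorm_trunc(1, 168.6, 50, lower = 118, upper = 260.5)
    counts <- rnorm_trunc(1, 1.32e8, 3.91e7, lower = 1) * scale
    n_les <- sample.int(3L, 1L)
    centers <- lesion_ring_centers(grid_shape)[seq_len(n_les)]
    lesions <- lapply(seq_len(n_les), function(j) {
      list(center = centers[[j]],
           volume_ml = stats::runif(1, 1.2, 17.58),
           suv = rnorm_trunc(1, 1.92, 0.95, lower = 0.5))
    })
    phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                 weight = weight, injected_dose = dose, scan_time = 900,
                 liver_suv = liver_suv, lesions = lesions,
                 total_true_counts = counts,
                 randoms_fraction = randoms_fraction,
                 subject_id = sprintf("S%02d", i))
  })
}

# truncated-normal draw by rejection; bounds are data-range truncations,
# not tail conditioning, so rejection is cheap
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

# fixed candidate lesion centers: ring in the upper lung field (z = 5/8 of
# the axial extent), radius 14/64 of the transaxial extent off-axis
lesion_ring_centers <- function(grid_shape) {
  cx <- (grid_shape[1] + 1) / 2
  cy <- (grid_shape[2] + 1) / 2
  r <- round(grid_shape[1] * 14 / 64)
  z <- round(grid_shape[3] * 5 / 8)
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  lapply(ang, function(a)
    as.integer(round(c(cx + r * cos(a), cy + r * sin(a), z))))
}

#' Rasterize a phantom specification to voxel maps
#'
#' Builds the labeled SUV volume: a cylindrical body (lung background) along
#' the axial direction, a spherical liver in the lower axial field, and each
#' lesion rasterized as the `n` voxels nearest its center where
#' `n = round(volume_ml / voxel_volume_ml)`, so the realized volume is within
#' one voxel of the request. Labels: 0 air, 1 lung, 2 liver, 3+ lesions.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `activity_phantom` with fields `suv_map`,
#'   `label_map` (arrays of `grid_shape`) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  vox_ml <- prod(vs) / 1000
  ax <- lapply(1:3, function(d) (seq_len(gs[d]) - (gs[d] + 1) / 2) * vs[d])
  X <- array(ax[[1]], gs)
  Y <- array(rep(ax[[2]], each = gs[1]), gs)
  Z <- array(rep(ax[[3]], each = gs[1] * gs[2]), gs)

  label <- array(0L, gs)
  body_r <- 0.42 * gs[1] * vs[1]
  label[X^2 + Y^2 <= body_r^2] <- 1L

  liver_r <- 0.19 * gs[1] * vs[1]
  liver_c <- c(0, 0, ax[[3]][max(1L, round(gs[3] / 4))])
  liver <- (X - liver_c[1])^2 + (Y - liver_c[2])^2 + (Z - liver_c[3])^2 <= liver_r^2
  label[liver] <- 2L

  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    n_vox <- max(1L, as.integer(round(les$volume_ml / vox_ml)))
    cmm <- c(ax[[1]][les$center[1]], ax[[2]][les$center[2]], ax[[3]][les$center[3]])
    d2 <- (X - cmm[1])^2 + (Y - cmm[2])^2 + (Z - cmm[3])^2
    idx <- order(d2)[seq_len(n_vox)]
    if (any(label[idx] != 1L))
      stop(sprintf("lesion %d overlaps liver, air or another lesion", k))
    label[idx] <- 2L + k
  }

  suv <- array(0, gs)
  suv[label == 1L] <- spec$lung_suv
  suv[label == 2L] <- spec$liver_suv
  for (k in seq_along(spec$lesions))
    suv[label == (2L + k)] <- spec$lesions[[k]]$suv

  structure(list(suv_map = suv, label_map = label, spec = spec),
            class = "activity_phantom")
}

#' @export
print.activity_phantom <- function(x, ...) {
  cat(sprintf("<activity_phantom %s> grid %s, labels {%s}\n",
              x$spec$subject_id, paste(dim(x$suv_map), collapse = "x"),
              paste(sort(unique(as.vector(x$label_map))), collapse = ",")))
  invisible(x)
}

#' Generate a full-statistics list-mode event stream
#'
#' Draws exactly `total_true_counts` true events multinomially over voxels
#' with probability proportional to the SUV map (fixed-total convention, so
#' "counts in the scan" is exact), plus
#' `round(randoms_fraction * n_true / (1 - randoms_fraction))` random events
#' distributed uniformly over the occupied field (label > 0). The combined
#' event order is randomized.
#'
#' @param phantom an [build_phantom()] result.
#' @param seed integer seed.
#' @return object of class `event_stream`: integer `bin_index` (voxel linear
#'   index), logical `is_random`, counts `n_true`/`n_random`, `domain`
#'   (`"image"`), `grid_shape`, and a `provenance` list.
#' @export
generate_events <- function(phantom, seed = 1L) {
  stopifnot(inherits(phantom, "activity_phantom"))
  spec <- phantom$spec
  n_true <- as.integer(round(spec$total_true_counts))
  occ <- which(phantom$suv_map > 0)
  if (length(occ) == 0L && n_true > 0L)
    stop("all-zero suv_map with positive requested counts")
  set.seed(as.integer(seed))
  trues <- if (n_true > 0L)
    occ[sample.int(length(occ), n_true, replace = TRUE,
                   prob = phantom$suv_map[occ])]
  else integer(0)
  rf <- spec$randoms_fraction
  n_rand <- as.integer(round(rf * n_true / (1 - rf)))
  body <- which(phantom$label_map > 0L)
  rands <- if (n_rand > 0L)
    body[sample.int(length(body), n_rand, replace = TRUE)]
  else integer(0)
  idx <- c(trues, rands)
  isr <- c(rep(FALSE, n_true), rep(TRUE, n_rand))
  ord <- sample.int(length(idx))
  event_stream(bin_index = idx[ord], is_random = isr[ord],
               domain = "image", grid_shape = spec$grid_shape,
               provenance = list(subject = spec$subject_id, fraction = 1,
                                 realization = 0L, seed = as.integer(seed)))
}

#' Construct an event stream object
#'
#' @param bin_index integer vector of voxel (or sinogram-bin) linear indices.
#' @param is_random logical vector flagging random coincidences.
#' @param domain `"image"` or `"sinogram"`.
#' @param grid_shape dimensions of the index space.
#' @param provenance list with subject, fraction, realization, seed.
#' @return `event_stream` object.
#' @export
event_stream <- function(bin_index, is_random = rep(FALSE, length(bin_index)),
                         domain = c("image", "sinogram"),
                         grid_shape, provenance = list()) {
  domain <- match.arg(domain)
  stopifnot(length(bin_index) == length(is_random))
  structure(list(bin_index = as.integer(bin_index),
                 is_random = as.logical(is_random),
                 n_true = sum(!is_random), n_random = sum(is_random),
                 domain = domain, grid_shape = as.integer(grid_shape),
                 provenance = provenance),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream %s> %d true + %d random events (fraction %.4g)\n",
              x$domain, x$n_true, x$n_random,
              if (is.null(x$provenance$fraction)) NA else x$provenance$fraction))
  invisible(x)
}

#' Effective dose from injected activity
#'
#' Converts an injected FDG activity to effective dose using the ICRP
#' coefficient 0.019 mSv/MBq for an adult.
#'
#' @param activity MBq, >= 0.
#' @return effective dose in mSv.
#' @export
effective_dose <- function(activity) {
  if (any(activity < 0)) stop("activity must be >= 0")
  activity * 0.019
}
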