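#' Construct an SUV image object
#'
#' An `suv_image` is a numeric array (2D slice or 3D volume) of standardized
#' uptake values with voxel size, counts-to-SUV calibration and provenance
#' attached as attributes.
#'
#' @param data nonnegative numeric array.
#' @param voxel_size mm per axis.
#' @param calibration counts-to-SUV scale applied.
#' @param provenance list (subject, fraction, realization, backend).
#' @return `suv_image` object.
#' @export
suv_image <- function(data, voxel_size, calibration = 1, provenance = list()) {
  structure(data, class = c("suv_image", class(data)),
            voxel_size = as.numeric(voxel_size),
            calibration = calibration, provenance = provenance)
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("<suv_image> %s voxels, range [%.3g, %.3g]\n",
              paste(dim(x), collapse = "x"), min(x), max(x)))
  invisible(x)
}

#' Bin an image-domain event stream into an SUV image
#'
#' Linear "binning" backend: each voxel value is the number of true events
#' in that voxel times the calibration factor. Because it is linear in the
#' stream, its statistical properties are exactly predictable, which makes it
#' the oracle backend for the count-response analyses.
#'
#' @param stream `event_stream` with `domain = "image"`.
#' @param grid_shape target grid; defaults to the stream's.
#' @param calibration counts-to-SUV scale (see [liver_calibration()]).
#' @return `suv_image`.
#' @export
bin_image <- function(stream, grid_shape = stream$grid_shape, calibration = 1) {
  stopifnot(inherits(stream, "event_stream"))
  if (stream$domain != "image") stop("bin_image needs an image-domain stream")
  nvox <- prod(grid_shape)
  idx <- stream$bin_index[!stream$is_random]
  if (length(idx) && (min(idx) < 1L || max(idx) > nvox))
    stop(sprintf("event bin index out of grid: %d",
                 idx[which(idx < 1L | idx > nvox)[1]]))
  counts <- tabulate(idx, nbins = nvox)
  suv_image(array(counts * calibration, grid_shape),
            voxel_size = rep(NA_real_, 3), calibration = calibration,
            provenance = stream$provenance)
}

#' Counts-to-SUV calibration from the full-statistics liver
#'
#' Chooses the scale so that the liver VOI mean of the full-statistics binned
#' image equals the phantom's liver SUV. Images at a reduced count fraction
#' are calibrated with this reference scale divided by the nominal fraction
#' (injected dose and detected counts scale together, and SUV normalizes by
#' the injected dose), so SUV level is preserved across fractions and the
#' SUVmean bias at fraction 1 is zero by construction.
#'
#' @param stream full-statistics image-domain `event_stream`.
#' @param liver_mask logical array (or [voi_mask()]) selecting liver voxels.
#' @param liver_suv target liver SUVmean.
#' @return calibration scalar.
#' @export
liver_calibration <- function(stream, liver_mask, liver_suv) {
  m <- as_mask_array(liver_mask)
  counts <- tabulate(stream$bin_index[!stream$is_random], nbins = length(m))
  mu <- mean(counts[m])
  if (mu <= 0) stop("no liver counts; cannot calibrate")
  liver_suv / mu
}

#' Separable Gaussian smoothing of an array
#'
#' FWHM is converted to sigma via `sigma = fwhm / (2 sqrt(2 log 2))`; the
#' kernel is truncated at 3 sigma and renormalized at the array edges so flat
#' regions are preserved.
#'
#' @param arr numeric array (any dimensionality).
#' @param fwhm_mm full width at half maximum, mm.
#' @param voxel_size mm per axis (recycled to the array dimensionality).
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(arr)
  d <- dim(arr); if (is.null(d)) d <- length(arr)
  voxel_size <- rep_len(voxel_size, length(d))
  out <- arr
  for (ax in seq_along(d)) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size[ax]
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution along one axis with edge renormalization
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr); if (is.null(d)) d <- length(arr)
  perm <- c(axis, seq_along(d)[-axis])
  a <- aperm(array(arr, d), perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  res <- matrix(0, n, ncol(m))
  wt <- numeric(n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    res[ok, ] <- res[ok, ] + kernel[j] * m[src[ok], ]
    wt[ok] <- wt[ok] + kernel[j]
  }
  res <- res / wt
  out <- aperm(array(res, d[perm]), order(perm))
  array(out, d)
}

#' Parallel-beam projection geometry
#'
#' Precomputes a sparse system matrix for a 2D pixel-driven parallel-beam
#' projector: each pixel center is mapped to radial coordinate
#' `r = x cos(theta) + y sin(theta)` per angle and linearly split between the
#' two nearest radial bins. The explicit matrix makes the back projector the
#' exact adjoint of the forward projector.
#'
#' @param n_pixels side length of the (square) image slice.
#' @param pixel_size mm.
#' @param n_angles number of projection angles over 180 degrees; the default
#'   63 divides evenly into 21 subsets.
#' @return `projection_geometry` object with the sparse matrix `A`
#'   (`n_radial * n_angles` rows by `n_pixels^2` columns).
#' @export
projection_geometry <- function(n_pixels, pixel_size = 4, n_angles = 63L) {
  n_pixels <- as.integer(n_pixels)
  coords <- (seq_len(n_pixels) - (n_pixels + 1) / 2) * pixel_size
  px <- rep(coords, times = n_pixels)
  py <- rep(coords, each = n_pixels)
  n_rad <- n_pixels
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  npix <- n_pixels^2
  ii <- jj <- integer(0); xx <- numeric(0)
  for (a in seq_len(n_angles)) {
    r <- px * cos(angles[a]) + py * sin(angles[a])
    b <- r / pixel_size + (n_rad + 1) / 2        # fractional radial bin
    b0 <- floor(b); w1 <- b - b0
    for (side in 0:1) {
      bin <- b0 + side
      w <- if (side == 0) 1 - w1 else w1
      ok <- bin >= 1 & bin <= n_rad & w > 0
      ii <- c(ii, (a - 1L) * n_rad + as.integer(bin[ok]))
      jj <- c(jj, which(ok))
      xx <- c(xx, w[ok] * pixel_size)            # weight x ray length step
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_rad * n_angles, npix))
  structure(list(A = A, n_pixels = n_pixels, n_radial = n_rad,
                 n_angles = as.integer(n_angles), pixel_size = pixel_size,
                 angles = angles),
            class = "projection_geometry")
}

#' Forward projection of an image slice
#'
#' @param slice square numeric matrix matching the geometry.
#' @param geom a [projection_geometry()].
#' @return `n_radial x n_angles` sinogram matrix.
#' @export
forward_project <- function(slice, geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (!all(dim(slice) == geom$n_pixels)) stop("slice does not match geometry")
  matrix(as.numeric(geom$A %*% as.vector(slice)), geom$n_radial, geom$n_angles)
}

#' Back projection (adjoint of [forward_project()])
#'
#' @param sino `n_radial x n_angles` matrix.
#' @param geom a [projection_geometry()].
#' @return image slice matrix.
#' @export
back_project <- function(sino, geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (!all(dim(sino) == c(geom$n_radial, geom$n_angles)))
    stop("sinogram does not match geometry")
  matrix(as.numeric(Matrix::crossprod(geom$A, as.vector(sino))),
         geom$n_pixels, geom$n_pixels)
}

#' Generate sinogram-domain events from an activity slice
#'
#' Draws `n_events` coincidences multinomially over sinogram bins with
#' probability proportional to the forward projection of the activity slice.
#' This is the event source for the OSEM surrogate backend: thinning these
#' streams reproduces reduced-dose Poisson-like sinogram statistics.
#'
#' @param slice activity slice (square matrix).
#' @param geom a [projection_geometry()].
#' @param n_events total true events.
#' @param seed integer seed.
#' @param provenance provenance list.
#' @return `event_stream` with `domain = "sinogram"`.
#' @export
sinogram_stream <- function(slice, geom, n_events, seed = 1L,
                            provenance = list()) {
  lam <- as.vector(forward_project(slice, geom))
  if (sum(lam) <= 0 && n_events > 0) stop("all-zero projection")
  set.seed(as.integer(seed))
  idx <- sample.int(length(lam), as.integer(round(n_events)),
                    replace = TRUE, prob = lam)
  event_stream(idx, domain = "sinogram",
               grid_shape = c(geom$n_radial, geom$n_angles, 1L),
               provenance = provenance)
}

#' Bin a sinogram-domain stream into a counts sinogram
#'
#' @param stream `event_stream` with `domain = "sinogram"`.
#' @param geom a [projection_geometry()].
#' @return `n_radial x n_angles` integer count matrix.
#' @export
bin_sinogram <- function(stream, geom) {
  if (stream$domain != "sinogram") stop("bin_sinogram needs a sinogram-domain stream")
  n <- geom$n_radial * geom$n_angles
  idx <- stream$bin_index[!stream$is_random]
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop("sinogram bin index out of range")
  matrix(tabulate(idx, nbins = n), geom$n_radial, geom$n_angles)
}

#' OSEM reconstruction of a counts sinogram (2D surrogate)
#'
#' Ordered-subsets expectation maximization with multiplicative updates,
#' interleaved angular subsets in fixed order, uniform positive
#' initialization, optional Gaussian PSF modeling in the projector, and a
#' Gaussian post-filter applied after the final iteration. Positivity is
#' preserved by construction. This 2D surrogate reproduces the regime
#' behavior of clinical OP-OSEM at low counts (positive bias in cold regions,
#' loss of SNR^2-counts proportionality) without modeling a specific scanner.
#'
#' @param sino counts sinogram (`n_radial x n_angles`).
#' @param geom a [projection_geometry()]; `n_angles` must be divisible by
#'   `n_subsets`.
#' @param n_iter iterations (default 3).
#' @param n_subsets ordered subsets (default 21).
#' @param psf_fwhm optional PSF FWHM in mm (`NULL` disables PSF modeling).
#' @param post_filter_fwhm Gaussian post-filter FWHM in mm (default 5).
#' @param calibration counts-to-SUV scale applied to the final image.
#' @return `suv_image` slice; attribute `zero_counts` flags an all-zero input.
#' @export
osem_reconstruct <- function(sino, geom, n_iter = 3L, n_subsets = 21L,
                             psf_fwhm = NULL, post_filter_fwhm = 5,
                             calibration = 1) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (any(sino < 0)) stop("sinogram counts must be nonnegative")
  if (geom$n_angles %% n_subsets != 0L)
    stop("n_angles must be divisible by n_subsets")
  ps <- geom$pixel_size
  blur <- function(img) if (is.null(psf_fwhm)) img else
    gaussian_smooth(img, psf_fwhm, ps)
  if (sum(sino) == 0) {
    out <- suv_image(matrix(0, geom$n_pixels, geom$n_pixels),
                     voxel_size = c(ps, ps), calibration = calibration)
    attr(out, "zero_counts") <- TRUE
    warning("zero total counts; returning zero image")
    return(out)
  }
  subsets <- lapply(seq_len(n_subsets), function(s)
    seq(s, geom$n_angles, by = n_subsets))
  rows_of <- function(ang) as.vector(outer(seq_len(geom$n_radial),
                                           (ang - 1L) * geom$n_radial, `+`))
  eps <- .Machine$double.eps
  sub <- lapply(subsets, function(ang) {
    rows <- rows_of(ang)
    As <- geom$A[rows, , drop = FALSE]
    sens <- blur(matrix(as.numeric(Matrix::crossprod(
      As, rep(1, length(rows)))), geom$n_pixels, geom$n_pixels))
    list(As = As, ys = as.vector(sino)[rows], sens = sens)
  })
  x <- matrix(1, geom$n_pixels, geom$n_pixels)
  for (it in seq_len(n_iter)) {
    for (s in seq_len(n_subsets)) {
      As <- sub[[s]]$As
      proj <- as.numeric(As %*% as.vector(blur(x)))
      ratio <- sub[[s]]$ys / pmax(proj, eps)
      bp <- blur(matrix(as.numeric(Matrix::crossprod(As, ratio)),
                        geom$n_pixels, geom$n_pixels))
      x <- x * bp / pmax(sub[[s]]$sens, eps)
      x[sub[[s]]$sens <= eps] <- 0
    }
  }
  x <- gaussian_smooth(x, post_filter_fwhm, ps)
  suv_image(x * calibration, voxel_size = c(ps, ps),
            calibration = calibration)
}

#' Reconstruct all realizations of a set of ensembles
#'
#' Produces one SUV image per realization plus a single full-statistics
#' reference image from the parent stream. With the `bin` backend (3D,
#' image-domain streams) calibration is anchored to the full-statistics liver
#' mean (see [liver_calibration()]); each reduced-fraction image uses the
#' reference calibration divided by its nominal fraction.
#'
#' @param parent_stream full-statistics `event_stream`.
#' @param ensembles list of `ensemble_spec` from [make_ensembles()].
#' @param backend `"bin"` or `"osem"`.
#' @param liver_mask,liver_suv calibration anchor (bin backend).
#' @param geom [projection_geometry()] (osem backend).
#' @param ... passed to [osem_reconstruct()].
#' @return list of `recon_ensemble` objects (fields `fraction`,
#'   `realizations` [list of `suv_image`], `mean_image`, `sd_image`,
#'   `realized_counts`, `reference`).
#' @export
reconstruct_ensemble <- function(parent_stream, ensembles,
                                 backend = c("bin", "osem"),
                                 liver_mask = NULL, liver_suv = NULL,
                                 geom = NULL, ...) {
  backend <- match.arg(backend)
  doms <- vapply(ensembles, function(e) e$streams[[1]]$domain, character(1))
  if (length(unique(c(parent_stream$domain, doms))) != 1L)
    stop("mixed stream domains")
  if (backend == "bin") {
    calib <- liver_calibration(parent_stream, liver_mask, liver_suv)
    rec <- function(s, f) bin_image(s, calibration = calib / f)
    reference <- rec(parent_stream, 1)
  } else {
    if (is.null(geom)) stop("osem backend needs a projection geometry")
    ref_sino <- bin_sinogram(parent_stream, geom)
    ref_raw <- osem_reconstruct(ref_sino, geom, calibration = 1, ...)
    calib <- if (!is.null(liver_mask) && !is.null(liver_suv)) {
      mu <- mean(ref_raw[as_mask_array(liver_mask)])
      if (mu > 0) liver_suv / mu else 1
    } else 1
    rec <- function(s, f) {
      img <- osem_reconstruct(bin_sinogram(s, geom), geom,
                              calibration = 1, ...)
      suv_image(unclass(img) * calib / f, voxel_size = attr(img, "voxel_size"),
                calibration = calib / f, provenance = s$provenance)
    }
    reference <- suv_image(unclass(ref_raw) * calib,
                           voxel_size = attr(ref_raw, "voxel_size"),
                           calibration = calib)
  }
  lapply(ensembles, function(ens) {
    imgs <- lapply(ens$streams, function(s) rec(s, ens$fraction))
    st <- ensemble_stats(imgs)
    structure(list(subject = ens$subject, fraction = ens$fraction,
                   realizations = imgs, mean_image = st$mean_image,
                   sd_image = st$sd_image,
                   realized_counts = vapply(ens$streams, function(s)
                     as.numeric(s$n_true), numeric(1)),
                   reference = reference),
              class = "recon_ensemble")
  })
}

#' @export
print.recon_ensemble <- function(x, ...) {
  cat(sprintf("<recon_ensemble> subject %s, fraction %.4g, R = %d, mean counts %.4g\n",
              x$subject, x$fraction, length(x$realizations),
              mean(x$realized_counts)))
  invisible(x)
}
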