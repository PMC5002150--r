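#' Construct a VOI mask object
#'
#' @param mask logical array.
#' @param label one of `"lesion"`, `"background_shell"`, `"liver"`, `"lung"`.
#' @param voxel_size mm per axis.
#' @param threshold_pct percent-of-SUVmax threshold used, if any.
#' @return `voi_mask`: logical array with `label`, `n_voxels`, `volume_ml`
#'   and `threshold_pct` attributes.
#' @export
voi_mask <- function(mask, label = c("lesion", "background_shell",
                                     "liver", "lung"),
                     voxel_size = c(4, 4, 4), threshold_pct = NA_real_) {
  label <- match.arg(label)
  n <- sum(mask)
  if (n == 0L) stop("empty VOI mask")
  voxel_size <- rep_len(as.numeric(voxel_size),
                        max(1L, length(dim(mask))))
  structure(mask, class = c("voi_mask", class(mask)), label = label,
            n_voxels = n, volume_ml = n * prod(voxel_size) / 1000,
            voxel_size = voxel_size, threshold_pct = threshold_pct)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask %s> %d voxels, %.3g ml\n",
              attr(x, "label"), attr(x, "n_voxels"), attr(x, "volume_ml")))
  invisible(x)
}

as_mask_array <- function(m) {
  if (inherits(m, "voi_mask")) array(as.logical(m), dim(m)) else m
}

# neighbor offsets for 26-connectivity (3^d - 1 in d dimensions)
neighbor_offsets <- function(ndim) {
  g <- do.call(expand.grid, rep(list(-1:1), ndim))
  as.matrix(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

# flood fill of the connected component containing `start` within `mask`
connected_component <- function(mask, start) {
  d <- dim(mask); nd <- length(d)
  offs <- neighbor_offsets(nd)
  comp <- array(FALSE, d)
  start <- matrix(as.integer(start), ncol = nd)
  frontier <- start[mask[start], , drop = FALSE]
  comp[frontier] <- TRUE
  while (nrow(frontier) > 0L) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
      sweep(frontier, 2, offs[k, ], `+`)))
    ok <- rep(TRUE, nrow(cand))
    for (j in seq_len(nd))
      ok <- ok & cand[, j] >= 1L & cand[, j] <= d[j]
    cand <- cand[ok, , drop = FALSE]
    keep <- mask[cand] & !comp[cand]
    cand <- unique(cand[keep, , drop = FALSE])
    comp[cand] <- TRUE
    frontier <- cand
  }
  comp
}

# greedy ascent to the local SUV maximum from a seed (26-neighborhood)
hill_climb <- function(image, seed) {
  d <- dim(image); nd <- length(d)
  offs <- neighbor_offsets(nd)
  pos <- as.integer(seed)
  repeat {
    cand <- sweep(offs, 2, pos, `+`)
    ok <- rep(TRUE, nrow(cand))
    for (j in seq_len(nd))
      ok <- ok & cand[, j] >= 1L & cand[, j] <= d[j]
    cand <- cand[ok, , drop = FALSE]
    vals <- image[cand]
    best <- which.max(vals)
    if (length(best) == 0L || vals[best] <= image[matrix(pos, 1)]) break
    pos <- cand[best, ]
  }
  pos
}

#' Threshold-based lesion delineation
#'
#' Segments the lesion containing `seed_voxel` on (typically) the
#' full-statistics image: the seed is climbed to its local maximum, SUVmax is
#' the value there, and the mask is the 26-connected component containing the
#' maximum among voxels at or above `pct`% of SUVmax. The mask is monotone in
#' the threshold: a higher percentage yields a subset of a lower one.
#'
#' @param image SUV array (1D profile, 2D slice or 3D volume).
#' @param seed_voxel index vector inside (or near) the lesion.
#' @param pct percent of SUVmax in (0, 100]; the threshold-sensitivity
#'   protocol uses 20, 40, 60 and 80.
#' @param voxel_size mm per axis.
#' @return `voi_mask` labeled `"lesion"`.
#' @export
threshold_voi <- function(image, seed_voxel, pct = 40,
                          voxel_size = c(4, 4, 4)) {
  if (pct <= 0 || pct > 100) stop("pct must be in (0, 100]")
  img <- as.array(unclass(image))
  if (is.null(dim(img))) dim(img) <- length(img)
  peak <- hill_climb(img, seed_voxel)
  suvmax <- img[matrix(peak, 1)]
  above <- img >= (pct / 100) * suvmax
  comp <- connected_component(above, peak)
  if (!any(comp)) stop("empty thresholded region")
  voi_mask(comp, "lesion", voxel_size = voxel_size, threshold_pct = pct)
}

#' Spherical VOI
#'
#' Selects voxels whose centers lie within `diameter_mm / 2` of the center
#' voxel's center; used for 3 cm background spheres in liver and clear lung.
#'
#' @param grid_shape voxel grid dimensions.
#' @param center_voxel sphere center (voxel indices).
#' @param diameter_mm sphere diameter, default 30 mm.
#' @param voxel_size mm per axis.
#' @param label VOI role, default `"liver"`.
#' @return `voi_mask`. Errors if the sphere is clipped by the grid boundary.
#' @export
sphere_voi <- function(grid_shape, center_voxel, diameter_mm = 30,
                       voxel_size = c(4, 4, 4), label = "liver") {
  nd <- length(grid_shape)
  voxel_size <- rep_len(voxel_size, nd)
  rad <- diameter_mm / 2
  if (any(((center_voxel - 1) * voxel_size) < rad) ||
      any(((grid_shape - center_voxel) * voxel_size) < rad))
    stop("sphere clipped by grid boundary")
  ax <- lapply(seq_len(nd), function(j)
    ((seq_len(grid_shape[j]) - center_voxel[j]) * voxel_size[j])^2)
  d2 <- Reduce(`+`, lapply(seq_len(nd), function(j) {
    rep_each <- prod(grid_shape[seq_len(j - 1)])
    array(rep(ax[[j]], each = rep_each), grid_shape)
  }))
  voi_mask(d2 <= rad^2, label, voxel_size = voxel_size)
}

#' Background shell around a lesion
#'
#' The background mask is the morphological dilation of the lesion mask minus
#' the lesion itself. The structuring element is a Euclidean ball of the
#' given voxel radius (default 2); a Chebyshev cube (two iterated unit
#' dilations equal one radius-2 cube) is available via `method`.
#'
#' @param lesion lesion `voi_mask` (or logical array).
#' @param radius_voxels dilation radius in voxels, default 2.
#' @param method `"ball"` (Euclidean, default) or `"cube"` (Chebyshev).
#' @param voxel_size mm per axis.
#' @return `voi_mask` labeled `"background_shell"`. Errors if the dilation
#'   would be clipped at the grid boundary.
#' @export
background_shell <- function(lesion, radius_voxels = 2L,
                             method = c("ball", "cube"),
                             voxel_size = attr(lesion, "voxel_size")) {
  method <- match.arg(method)
  m <- as_mask_array(lesion)
  if (!any(m)) stop("empty lesion mask")
  if (is.null(voxel_size)) voxel_size <- rep(4, length(dim(m)))
  if (radius_voxels == 0L)
    return(structure(array(FALSE, dim(m)),
                     class = c("voi_mask", "array"),
                     label = "background_shell", n_voxels = 0L,
                     volume_ml = 0, voxel_size = voxel_size,
                     threshold_pct = NA_real_))
  d <- dim(m); nd <- length(d)
  r <- as.integer(radius_voxels)
  g <- as.matrix(do.call(expand.grid, rep(list(-r:r), nd)))
  offs <- if (method == "ball") g[rowSums(g^2) <= r^2, , drop = FALSE] else g
  vox <- which(m, arr.ind = TRUE)
  if (nd == 1L) vox <- matrix(vox, ncol = 1)
  dil <- array(FALSE, d)
  for (k in seq_len(nrow(offs))) {
    sh <- sweep(vox, 2, offs[k, ], `+`)
    if (any(sh < 1L) || any(sweep(sh, 2, d, `>`) ))
      stop("background shell clipped at grid boundary")
    dil[sh] <- TRUE
  }
  voi_mask(dil & !m, "background_shell", voxel_size = voxel_size)
}

#' Filter lesions by volume and contrast
#'
#' Keeps lesions with volume at most `max_volume_ml` and CNR at least
#' `min_cnr` (inclusive bounds), preserving input order. Mirrors the
#' inclusion rule used before the pooled count-response analyses.
#'
#' @param records data frame with columns `volume_ml` and `cnr`.
#' @param max_volume_ml,min_cnr inclusion bounds (defaults 20 ml, 2).
#' @return filtered data frame (possibly empty).
#' @export
filter_lesions <- function(records, max_volume_ml = 20, min_cnr = 2) {
  stopifnot(all(c("volume_ml", "cnr") %in% names(records)))
  records[records$volume_ml <= max_volume_ml & records$cnr >= min_cnr, ,
          drop = FALSE]
}

#' Split lesion records into small and large volume groups
#'
#' Lesions with volume strictly below the threshold form the small group;
#' lesions at or above it the large group (a 5 ml lesion is "large", matching
#' a small-group range that tops out below 5 ml).
#'
#' @param records data frame with a `volume_ml` column.
#' @param threshold_ml split point, default 5 ml.
#' @return list with elements `small` and `large`.
#' @export
split_by_volume <- function(records, threshold_ml = 5) {
  stopifnot("volume_ml" %in% names(records))
  list(small = records[records$volume_ml < threshold_ml, , drop = FALSE],
       large = records[records$volume_ml >= threshold_ml, , drop = FALSE])
}
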