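#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end pipeline (simulate, thin,
#' reconstruct, delineate, metrics, fits, minimum counts) in one
#' serializable object. Every stochastic stage derives its seed from
#' `master_seed`.
#'
#' @param n_subjects cohort size.
#' @param scale count-scaling factor in (0, 1] for desk-scale runs.
#' @param fractions retention fractions (strictly decreasing, in (0, 1]).
#' @param n_realizations realizations per fraction.
#' @param backend `"bin"` (linear, 3D) or `"osem"` (2D surrogate).
#' @param master_seed integer.
#' @param grid_shape,voxel_size phantom grid.
#' @param lesion_pct SUVmax percentage for lesion delineation (default 40).
#' @param shell_radius background-shell dilation radius in voxels.
#' @param max_volume_ml,min_cnr lesion inclusion bounds.
#' @param cov_inverse_ratio COV orientation flag, see [ensemble_cov()].
#' @param ki_range count range (raw counts) for the sensitivity fit.
#' @param percent_levels allowed error levels for the minimum-counts curves.
#' @param out_dir output directory (`NULL` for in-memory only).
#' @param write_nifti also export reference images and masks as NIfTI.
#' @return `run_config` object (a validated named list).
#' @export
run_config <- function(n_subjects = 4L, scale = 0.02,
                       fractions = c(1.67e-2, 5e-3, 3.33e-3, 1.67e-3, 5e-4),
                       n_realizations = 10L,
                       backend = c("bin", "osem"),
                       master_seed = 1L,
                       grid_shape = c(64L, 64L, 64L),
                       voxel_size = c(4, 4, 4),
                       lesion_pct = 40, shell_radius = 2L,
                       max_volume_ml = 20, min_cnr = 2,
                       cov_inverse_ratio = FALSE,
                       ki_range = c(0, 20e6),
                       percent_levels = c(5, 10, 15, 20, 30),
                       out_dir = NULL, write_nifti = FALSE) {
  backend <- match.arg(backend)
  sched <- fraction_schedule(fractions, n_realizations)  # validates
  stopifnot(n_subjects >= 1, scale > 0, scale <= 1,
            lesion_pct > 0, lesion_pct <= 100)
  structure(list(n_subjects = as.integer(n_subjects), scale = scale,
                 fractions = sched$fractions,
                 n_realizations = sched$n_realizations,
                 backend = backend, master_seed = as.integer(master_seed),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 lesion_pct = lesion_pct,
                 shell_radius = as.integer(shell_radius),
                 max_volume_ml = max_volume_ml, min_cnr = min_cnr,
                 cov_inverse_ratio = cov_inverse_ratio,
                 ki_range = ki_range, percent_levels = percent_levels,
                 out_dir = out_dir, write_nifti = write_nifti),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' `load_config(save_config(cfg))` round-trips the configuration.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `save_config`: the path, invisibly; `load_config`: a
#'   `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

# standard VOI set for one phantom: 3 cm liver and clear-lung spheres plus
# threshold-delineated lesions with their background shells. Lesions are
# delineated on a Gaussian-smoothed view of the full-statistics reference
# (the clinical reconstruction is post-filtered at 5 mm; the linear binning
# backend leaves images unsmoothed, so the smoothing is applied here to keep
# threshold segmentation from percolating through voxel noise).
standard_vois <- function(phantom, reference, lesion_pct = 40,
                          shell_radius = 2L, delineation_fwhm = 5) {
  spec <- phantom$spec
  gs <- spec$grid_shape; vs <- spec$voxel_size
  seg_img <- gaussian_smooth(unclass(reference), delineation_fwhm, vs)
  liver_idx <- which(phantom$label_map == 2L, arr.ind = TRUE)
  liver_c <- as.integer(round(colMeans(liver_idx)))
  # the anatomical liver mask is the default liver region: the phantom's
  # ground-truth organ outline is available and a larger homogeneous VOI
  # stabilizes the spatial-SD estimate behind the SNR^2 fits; a 3 cm sphere
  # at the organ centroid is kept alongside as the conventional manual VOI
  vois <- list(liver = voi_mask(phantom$label_map == 2L, "liver",
                                voxel_size = vs),
               liver_sphere = sphere_voi(gs, liver_c, 30, vs,
                                         label = "liver"))
  cx <- (gs[1] + 1) / 2; cy <- (gs[2] + 1) / 2
  r <- round(gs[1] * 14 / 64); z <- round(gs[3] * 5 / 8)
  lung_c <- as.integer(round(c(cx + r * cos(pi), cy + r * sin(pi), z)))
  vois$lung <- sphere_voi(gs, lung_c, 30, vs, label = "lung")
  dropped <- character(0)
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    nm <- paste0("lesion", k)
    ok <- tryCatch({
      mask <- threshold_voi(seg_img, les$center, lesion_pct,
                            voxel_size = vs)
      shell <- background_shell(mask, shell_radius)
      vois[[nm]] <- mask
      vois[[paste0("shell_", nm)]] <- shell
      TRUE
    }, error = function(e) FALSE)
    # a low-contrast lesion can fail delineation (threshold below the lung
    # background floods the field); it is dropped, as in practice, and would
    # not survive the CNR inclusion filter anyway
    if (!ok) dropped <- c(dropped, nm)
  }
  attr(vois, "dropped_lesions") <- dropped
  vois
}

#' Simulate and analyze the count response of one subject
#'
#' Runs the per-subject pipeline: rasterize the phantom, generate the
#' full-statistics stream, thin it over the fraction schedule, reconstruct
#' every realization, delineate the standard VOIs on the full-statistics
#' reference, and compute the long-format metric table.
#'
#' @param spec a [phantom_spec()].
#' @param config a [run_config()] (fractions, realizations, backend, VOI
#'   parameters and seeds are taken from it).
#' @param keep_images retain every realization image in the returned
#'   ensembles (`FALSE` by default: a cohort of full ensembles does not fit
#'   comfortably in memory, and the metric table carries what the
#'   downstream fits need).
#' @return list: `metrics` (long data frame), `vois`, `reference`,
#'   `ensembles` (list of `recon_ensemble`; image-free summaries unless
#'   `keep_images`), `lesion_table` (id, volume_ml, cnr at full
#'   statistics), `phantom`.
#' @export
subject_count_response <- function(spec, config = run_config(),
                                   keep_images = FALSE) {
  phantom <- build_phantom(spec)
  parent <- generate_events(phantom,
                            seed = sub_seed(config$master_seed, 0L,
                                            match_subject_index(spec)))
  sched <- fraction_schedule(config$fractions, config$n_realizations)
  ens <- make_ensembles(parent, sched,
                        master_seed = config$master_seed +
                          match_subject_index(spec))
  liver_mask <- phantom$label_map == 2L
  rec <- reconstruct_ensemble(parent, ens, backend = config$backend,
                              liver_mask = liver_mask,
                              liver_suv = spec$liver_suv)
  reference <- rec[[1]]$reference
  vois <- standard_vois(phantom, reference, config$lesion_pct,
                        config$shell_radius)
  metrics <- do.call(rbind, lapply(rec, ensemble_metrics, vois = vois,
                                   cov_inverse_ratio = config$cov_inverse_ratio %||% FALSE))
  lesion_names <- grep("^lesion", names(vois), value = TRUE)
  lesion_table <- do.call(rbind, lapply(seq_along(lesion_names), function(k) {
    nm <- lesion_names[k]
    data.frame(subject = spec$subject_id, lesion = nm,
               volume_ml = attr(vois[[nm]], "volume_ml"),
               cnr = as.numeric(cnr(reference, vois[[nm]],
                                    vois[[paste0("shell_", nm)]])))
  }))
  if (!keep_images)
    rec <- lapply(rec, function(e) {
      e$realizations <- NULL; e$mean_image <- NULL
      e$sd_image <- NULL; e$reference <- NULL
      e
    })
  list(metrics = metrics, vois = vois, reference = reference,
       ensembles = rec, lesion_table = lesion_table, phantom = phantom)
}

match_subject_index <- function(spec) {
  i <- suppressWarnings(as.integer(sub("^S0*", "", spec$subject_id)))
  if (is.na(i)) 1L else i
}

#' Pooled sensitivity-corrected SNR^2 fit for a cohort
#'
#' Estimates the per-subject composite sensitivity factor from liver SNR^2
#' against realized counts (through-origin fit over `ki_range`), divides
#' each subject's SNR^2 by it, pools the corrected points and fits an
#' ordinary least-squares line (free intercept) against counts in 10^6.
#'
#' @param metrics long metric table pooled over subjects (needs region
#'   `"liver"`, metric `"snr"`).
#' @param ki_range raw-count range for the per-subject fit.
#' @return list: `ki` (data frame subject, ki), `points` (subject, counts,
#'   snr2, snr2_corrected), `fit` (pooled `fit_result`).
#' @export
cohort_snr2_fit <- function(metrics, ki_range = c(0, 20e6)) {
  liv <- metrics[metrics$region == "liver" & metrics$metric == "snr", ]
  if (nrow(liv) == 0L) stop("no liver SNR records")
  liv$snr2 <- liv$value^2
  subjects <- unique(liv$subject)
  kis <- lapply(subjects, function(s) {
    d <- liv[liv$subject == s, ]
    estimate_ki(d$counts, d$snr2, count_range = ki_range, subject = s)
  })
  ki_df <- data.frame(subject = subjects,
                      ki = vapply(kis, function(k) k$ki, numeric(1)))
  pts <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    d <- liv[liv$subject == subjects[i], c("subject", "counts", "snr2")]
    d$snr2_corrected <- correct_snr2(d$snr2, kis[[i]])
    d
  }))
  keep <- pts$counts >= ki_range[1] & pts$counts <= ki_range[2]
  fit <- fit_linear(pts$counts[keep], pts$snr2_corrected[keep])
  list(ki = ki_df, points = pts, fit = fit)
}

#' Pooled normalized-CNR fit for a cohort
#'
#' Normalizes every included lesion's CNR at each count level by its CNR at
#' full statistics and fits the saturation curve `1 / (1 + a x^(-b))`
#' against counts in 10^6. Lesions are included by the volume/CNR rule of
#' [filter_lesions()].
#'
#' @param results list of [subject_count_response()] outputs.
#' @param max_volume_ml,min_cnr inclusion bounds.
#' @return list: `points` (subject, lesion, counts_millions, ncnr), `fit`
#'   (`fit_result`), `lesions` (included lesion table).
#' @export
cohort_cnr_fit <- function(results, max_volume_ml = 20, min_cnr = 2) {
  lesions <- do.call(rbind, lapply(results, function(r) r$lesion_table))
  keep <- filter_lesions(lesions, max_volume_ml, min_cnr)
  if (nrow(keep) == 0L) stop("no lesion passes the inclusion filter")
  pts <- do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    cn <- m[m$metric == "cnr", ]
    if (nrow(cn) == 0L) return(NULL)
    full <- r$lesion_table
    cn$key <- paste(cn$subject, cn$region)
    full$key <- paste(full$subject, full$lesion)
    ok <- full$key[full$key %in% paste(keep$subject, keep$lesion)]
    cn <- cn[cn$key %in% ok, ]
    cn$cnr_full <- full$cnr[match(cn$key, full$key)]
    data.frame(subject = cn$subject, lesion = cn$region,
               counts_millions = cn$counts / 1e6,
               ncnr = cn$value / cn$cnr_full)
  }))
  fit <- fit_normalized_cnr(pts$counts_millions, pts$ncnr)
  list(points = pts, fit = fit, lesions = keep)
}

#' Build minimum-counts case tables from pooled metrics
#'
#' One case is one (subject, region) series across count levels; lesion
#' regions get the lesion volume attached for subgroup analyses. Bias
#' metrics enter by magnitude.
#'
#' @param metrics pooled long metric table.
#' @param metric metric name (`"cov_mean"`, `"ste_max"`, `"bias_mean"`, ...).
#' @param region_type `"lesion"`, `"liver"` or `"lung"`.
#' @param lesion_table lesion volumes (needed for `region_type = "lesion"`).
#' @return data frame (case, counts, value[, volume_ml]).
#' @export
mincounts_cases <- function(metrics, metric, region_type = "lesion",
                            lesion_table = NULL) {
  sel <- if (region_type == "lesion") grepl("^lesion", metrics$region)
         else metrics$region == region_type
  d <- metrics[sel & metrics$metric == metric, ]
  if (nrow(d) == 0L) stop("no records for this metric/region")
  out <- data.frame(case = paste(d$subject, d$region),
                    counts = d$counts, value = abs(d$value))
  if (region_type == "lesion" && !is.null(lesion_table)) {
    key <- paste(lesion_table$subject, lesion_table$lesion)
    out$volume_ml <- lesion_table$volume_ml[match(out$case, key)]
  }
  out
}

#' Run the full pipeline
#'
#' Simulate a cohort, thin and reconstruct all ensembles, compute metrics,
#' fit the sensitivity-corrected SNR^2 and normalized-CNR models, derive
#' minimum-counts curves, and (optionally) write CSV/JSON/NIfTI artifacts
#' plus a manifest with seeds and file hashes. Rerunning with the same
#' configuration reproduces the metric tables bit for bit.
#'
#' @param config a [run_config()].
#' @return run manifest (list) with the in-memory results attached as
#'   `results`; if `config$out_dir` is set, artifacts and
#'   `manifest.json` are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  specs <- sample_cohort(config$n_subjects, config$master_seed,
                         scale = config$scale,
                         grid_shape = config$grid_shape,
                         voxel_size = config$voxel_size)
  per_subject <- lapply(specs, subject_count_response, config = config)
  metrics <- do.call(rbind, lapply(per_subject, function(r) r$metrics))
  lesion_table <- do.call(rbind,
                          lapply(per_subject, function(r) r$lesion_table))
  snr_fit <- cohort_snr2_fit(metrics, config$ki_range)
  cnr_fit <- tryCatch(cohort_cnr_fit(per_subject, config$max_volume_ml,
                                     config$min_cnr),
                      error = function(e) NULL)
  curves <- list()
  for (metric in c("cov_mean", "cov_max", "ste_mean", "ste_max",
                   "bias_mean", "bias_max")) {
    for (rt in c("lesion", "liver", "lung")) {
      cases <- tryCatch(mincounts_cases(metrics, metric, rt, lesion_table),
                        error = function(e) NULL)
      if (is.null(cases)) next
      cv <- tryCatch(min_counts_curve(cases, config$percent_levels,
                                      metric = metric, region = rt),
                     error = function(e) NULL)
      if (!is.null(cv)) curves[[paste(metric, rt, sep = "_")]] <- cv
    }
  }
  results <- list(metrics = metrics, lesion_table = lesion_table,
                  snr_fit = snr_fit, cnr_fit = cnr_fit, curves = curves,
                  per_subject = per_subject)
  manifest <- list(package = "petiq",
                   config = unclass(config)[setdiff(names(config),
                                                    "out_dir")],
                   n_streams = config$n_subjects *
                     (1 + length(config$fractions) * config$n_realizations),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   artifacts = character(0))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    wr <- function(obj, name, writer) {
      p <- file.path(config$out_dir, name)
      writer(obj, p)
      paths <<- c(paths, p)
    }
    wr(metrics, "metrics.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(lesion_table, "lesions.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    fits <- list(snr2_pooled = unclass(snr_fit$fit),
                 ki = snr_fit$ki,
                 normalized_cnr = if (!is.null(cnr_fit))
                   unclass(cnr_fit$fit))
    wr(fits, "fits.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = NA))
    for (nm in names(curves))
      wr(as.data.frame(curves[[nm]]), paste0("mincounts_", nm, ".csv"),
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    if (isTRUE(config$write_nifti)) {
      for (i in seq_along(per_subject)) {
        pr <- file.path(config$out_dir, sprintf("subject%02d", i))
        export_phantom(per_subject[[i]]$phantom, pr)
        paths <- c(paths, paste0(pr, c("_suv.nii.gz", "_labels.nii.gz",
                                       "_spec.json")))
        p <- paste0(pr, "_reference.nii.gz")
        write_volume_nifti(per_subject[[i]]$reference, p,
                           config$voxel_size)
        paths <- c(paths, p)
      }
    }
    manifest$artifacts <- data.frame(
      path = basename(paths),
      md5 = unname(tools::md5sum(paths)))
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest$results <- results
  invisible(manifest)
}
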