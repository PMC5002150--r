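#' Minimum count level keeping one case's metric below a threshold
#'
#' For one case (one subject-region-statistic series across count levels),
#' returns the smallest count level at which the metric is at or below the
#' threshold *and stays at or below it at every available higher level* — a
#' guard against non-monotone noise in the series.
#'
#' @param counts count levels (any order).
#' @param values metric values (percent) matching `counts`.
#' @param threshold allowed percent level.
#' @return the required counts, or `NA` if the threshold is never met (the
#'   case is censored above the maximum available level).
#' @export
case_min_counts <- function(counts, values, threshold) {
  stopifnot(length(counts) == length(values))
  if (length(unique(counts)) < 3L) stop("need records at >= 3 count levels")
  o <- order(counts)
  counts <- counts[o]; values <- values[o]
  ok_above <- rev(cumprod(rev(values <= threshold))) == 1
  if (!any(ok_above)) return(NA_real_)
  counts[which(ok_above)[1]]
}

#' Exceedance histogram of per-case required counts
#'
#' Histograms the per-case required counts on fixed-width bins (default
#' 1 x 10^6) and reports the mean and maximum of the distribution (computed
#' on the required-count values themselves; the binning is for display).
#' Censored cases (`NA`) are excluded from mean/max and counted separately.
#'
#' @param nstar per-case required counts, e.g. from [case_min_counts()].
#' @param metric,threshold,region labels carried through.
#' @param bin bin width in counts, default 1e6.
#' @return `exceedance_histogram` object: `breaks`, `mids`, `frequency`,
#'   `mean_counts`, `max_counts`, `n_cases`, `n_censored`.
#' @export
exceedance_histogram <- function(nstar, metric = "cov_mean", threshold = 10,
                                 region = "lesion", bin = 1e6) {
  if (length(nstar) == 0L) stop("empty case pool")
  cen <- sum(is.na(nstar))
  v <- nstar[!is.na(nstar)]
  if (length(v) == 0L) stop("all cases censored")
  breaks <- seq(0, bin * ceiling(max(v) / bin + 1e-12), by = bin)
  if (length(breaks) < 2L) breaks <- c(0, bin)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
  structure(list(metric = metric, threshold = threshold, region = region,
                 breaks = breaks, mids = h$mids, frequency = h$counts,
                 mean_counts = mean(v), max_counts = max(v),
                 n_cases = length(nstar), n_censored = cen),
            class = "exceedance_histogram")
}

#' @export
print.exceedance_histogram <- function(x, ...) {
  cat(sprintf("<exceedance_histogram %s <= %g%% (%s)> mean %.3g, max %.3g, %d case(s), %d censored\n",
              x$metric, x$threshold, x$region, x$mean_counts, x$max_counts,
              x$n_cases, x$n_censored))
  invisible(x)
}

#' Minimum-counts curve across allowed error levels
#'
#' For each allowed percent level, computes every case's required counts and
#' summarizes the distribution by its mean, median ("half of the cases") and
#' maximum. Summaries are taken over the cases that meet every requested
#' level (the common uncensored set), so each summary curve is non-increasing
#' in the allowed percent by construction; the per-level number of censored
#' cases is reported alongside.
#'
#' @param cases data frame with columns `case` (case id), `counts`, `value`
#'   (metric in percent); one row per (case, count level).
#' @param percent_levels allowed error levels, >= 2 values.
#' @param metric,region,statistic labels carried into the result.
#' @return `min_counts_curve`: data frame (percent, n_cases, n_censored,
#'   counts_mean, counts_median, counts_max) with the labels as attributes.
#' @export
min_counts_curve <- function(cases, percent_levels,
                             metric = "cov_mean", region = "lesion",
                             statistic = "suvmean") {
  stopifnot(all(c("case", "counts", "value") %in% names(cases)))
  if (length(percent_levels) < 2L) stop("need >= 2 percent levels")
  percent_levels <- sort(percent_levels)
  ids <- unique(cases$case)
  nstar <- sapply(percent_levels, function(p)
    vapply(ids, function(id) {
      rec <- cases[cases$case == id, ]
      case_min_counts(rec$counts, rec$value, p)
    }, numeric(1)))
  nstar <- matrix(nstar, nrow = length(ids))
  common <- rowSums(is.na(nstar)) == 0L
  if (!any(common)) stop("no case meets every requested level")
  out <- data.frame(
    percent = percent_levels,
    n_cases = sum(common),
    n_censored = colSums(is.na(nstar)),
    counts_mean = colMeans(nstar[common, , drop = FALSE]),
    counts_median = apply(nstar[common, , drop = FALSE], 2, stats::median),
    counts_max = apply(nstar[common, , drop = FALSE], 2, max))
  structure(out, class = c("min_counts_curve", "data.frame"),
            metric = metric, region = region, statistic = statistic)
}

#' Minimum-counts curves for small and large lesion subgroups
#'
#' Splits lesion cases at a volume threshold (default 5 ml; a lesion exactly
#' at the threshold goes to the large group) and computes one minimum-counts
#' curve per subgroup, plus a pointwise direction comparison (smaller lesions
#' are expected to require at least as many counts).
#'
#' @param cases data frame as in [min_counts_curve()] with an additional
#'   `volume_ml` column (constant within a case).
#' @param percent_levels allowed error levels.
#' @param volume_threshold_ml split point, default 5.
#' @param ... passed to [min_counts_curve()].
#' @return list: `small`, `large` (curves) and `small_requires_more`
#'   (logical vector per percent level, mean-summary comparison).
#' @export
subgroup_curves <- function(cases, percent_levels, volume_threshold_ml = 5,
                            ...) {
  stopifnot("volume_ml" %in% names(cases))
  grp <- split_by_volume(cases, volume_threshold_ml)
  if (nrow(grp$small) == 0L) stop("small-lesion subgroup is empty")
  if (nrow(grp$large) == 0L) stop("large-lesion subgroup is empty")
  small <- min_counts_curve(grp$small, percent_levels, ...)
  large <- min_counts_curve(grp$large, percent_levels, ...)
  list(small = small, large = large,
       small_requires_more = small$counts_mean >= large$counts_mean)
}
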