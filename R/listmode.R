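#' Count-fraction schedule for reduced-dose simulation
#'
#' The default is the ten predefined retention fractions used for the
#' reduced-dose study (5e-1 down to 5e-4) with ten independent realizations
#' per fraction.
#'
#' @param fractions strictly decreasing retention probabilities in (0, 1].
#' @param n_realizations realizations per fraction.
#' @return `fraction_schedule` object.
#' @export
fraction_schedule <- function(fractions = c(5e-1, 2.5e-1, 1.25e-1, 6.25e-2,
                                            3.33e-2, 1.67e-2, 5e-3, 3.33e-3,
                                            1.67e-3, 5e-4),
                              n_realizations = 10L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) == 0L) stop("schedule must contain at least one fraction")
  if (any(fractions <= 0) || any(fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.unsorted(rev(fractions), strictly = TRUE))
    stop("fractions must be strictly decreasing")
  if (n_realizations < 1L) stop("n_realizations must be >= 1")
  structure(list(fractions = fractions,
                 n_realizations = as.integer(n_realizations)),
            class = "fraction_schedule")
}

# deterministic sub-seed for (master, fraction index, realization index);
# unique within fi <= 2000, ri <= 1e5 and bounded below 2^31
sub_seed <- function(master_seed, fraction_index, realization_index) {
  as.integer((as.numeric(master_seed) %% 9973L) * 100003 +
               fraction_index * 1000003 + realization_index * 101) %% 2147483647L
}

#' Thin an event stream by random event discarding
#'
#' Simulates a reduced injected dose: every event (true or random alike) is
#' independently retained with probability `fraction`, so the retained true
#' count is Binomial(n_true, fraction).
#'
#' @param stream an [event_stream()].
#' @param fraction retention probability in `[0, 1]`.
#' @param seed integer seed.
#' @return thinned `event_stream`; provenance records `fraction` and `seed`.
#' @export
thin_stream <- function(stream, fraction, seed = 1L) {
  stopifnot(inherits(stream, "event_stream"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- length(stream$bin_index)
  keep <- if (fraction >= 1) rep(TRUE, n)
          else if (fraction <= 0) rep(FALSE, n)
          else { set.seed(as.integer(seed)); stats::runif(n) < fraction }
  prov <- stream$provenance
  prov$fraction <- fraction * if (is.null(prov$fraction)) 1 else prov$fraction
  prov$seed <- as.integer(seed)
  prov$method <- "thin"
  event_stream(stream$bin_index[keep], stream$is_random[keep],
               domain = stream$domain, grid_shape = stream$grid_shape,
               provenance = prov)
}

#' Resample an event stream with replacement (bootstrap)
#'
#' Alternative reduced-dose resampler: draws `round(fraction * n)` events
#' with replacement from the parent stream. Offered for comparison with
#' binomial thinning; the fitted count-response coefficients are very close
#' under either resampler.
#'
#' @inheritParams thin_stream
#' @return resampled `event_stream`.
#' @export
bootstrap_stream <- function(stream, fraction, seed = 1L) {
  stopifnot(inherits(stream, "event_stream"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- length(stream$bin_index)
  m <- as.integer(round(fraction * n))
  idx <- if (m == 0L) integer(0) else {
    set.seed(as.integer(seed))
    sample.int(n, m, replace = TRUE)
  }
  prov <- stream$provenance
  prov$fraction <- fraction * if (is.null(prov$fraction)) 1 else prov$fraction
  prov$seed <- as.integer(seed)
  prov$method <- "bootstrap"
  event_stream(stream$bin_index[idx], stream$is_random[idx],
               domain = stream$domain, grid_shape = stream$grid_shape,
               provenance = prov)
}

#' Build multi-realization ensembles over a fraction schedule
#'
#' For each fraction in the schedule, generates `n_realizations` independent
#' resampled streams from the parent stream. Sub-seeds are derived
#' deterministically from `(master_seed, fraction index, realization index)`
#' so any single realization is reproducible in isolation.
#'
#' @param stream non-empty parent `event_stream`.
#' @param schedule a [fraction_schedule()].
#' @param master_seed integer master seed.
#' @param method `"thin"` (default, event discarding) or `"bootstrap"`.
#' @return list of `ensemble_spec` objects, one per fraction, each holding
#'   the realization streams and the seeds used.
#' @export
make_ensembles <- function(stream, schedule, master_seed = 1L,
                           method = c("thin", "bootstrap")) {
  stopifnot(inherits(stream, "event_stream"),
            inherits(schedule, "fraction_schedule"))
  method <- match.arg(method)
  if (length(stream$bin_index) == 0L) stop("parent stream is empty")
  resample <- if (method == "thin") thin_stream else bootstrap_stream
  lapply(seq_along(schedule$fractions), function(fi) {
    f <- schedule$fractions[fi]
    seeds <- vapply(seq_len(schedule$n_realizations), function(ri)
      sub_seed(master_seed, fi, ri), integer(1))
    streams <- lapply(seq_len(schedule$n_realizations), function(ri) {
      s <- resample(stream, f, seeds[ri])
      s$provenance$realization <- ri
      s
    })
    structure(list(subject = stream$provenance$subject, fraction = f,
                   streams = streams, seeds = seeds, method = method),
              class = "ensemble_spec")
  })
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> subject %s, fraction %.4g, %d realizations (%s)\n",
              x$subject, x$fraction, length(x$streams), x$method))
  invisible(x)
}
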