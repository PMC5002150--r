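#' Fit-result container
#'
#' @param form `"linear"`, `"power"` or `"cnr_saturation"`.
#' @param coefficients named numeric vector.
#' @param r_squared coefficient of determination, `1 - SS_res / SS_tot`
#'   (SS_tot about the mean of y; the same definition is used for linear and
#'   nonlinear fits).
#' @param count_range range of counts used, in raw counts.
#' @param x_units description of the abscissa units.
#' @return `fit_result` object.
#' @export
fit_result <- function(form, coefficients, r_squared,
                       count_range = c(NA_real_, NA_real_),
                       x_units = "counts in 1e6") {
  stopifnot(all(is.finite(coefficients)))
  if (is.finite(r_squared)) stopifnot(r_squared <= 1 + 1e-12)
  structure(list(form = form, coefficients = coefficients,
                 r_squared = r_squared, count_range = count_range,
                 x_units = x_units),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> %s; R^2 = %.4g\n", x$form,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$r_squared))
  invisible(x)
}

r_squared_of <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

#' Ordinary least-squares fit of SNR^2 against counts
#'
#' Counts are rescaled to units of 10^6 before fitting, so a slope of 1
#' means one SNR^2 unit per million detected counts.
#'
#' @param counts detected true counts (raw, > 0).
#' @param snr2 squared SNR values.
#' @param through_origin force a zero intercept.
#' @return `fit_result` with coefficients `slope` (and `intercept` unless
#'   through origin).
#' @export
fit_linear <- function(counts, snr2, through_origin = FALSE) {
  stopifnot(length(counts) == length(snr2))
  if (length(counts) < 3L) stop("need at least 3 points")
  if (any(counts <= 0)) stop("counts must be positive")
  x <- counts / 1e6
  if (stats::sd(x) == 0) stop("degenerate fit: constant counts")
  if (through_origin) {
    fit <- stats::lm(snr2 ~ 0 + x)
    co <- c(slope = unname(stats::coef(fit)[1]))
  } else {
    fit <- stats::lm(snr2 ~ x)
    co <- c(intercept = unname(stats::coef(fit)[1]),
            slope = unname(stats::coef(fit)[2]))
  }
  fit_result("linear", co, r_squared_of(snr2, stats::fitted(fit)),
             count_range = range(counts))
}

#' Estimate the per-subject composite sensitivity factor
#'
#' The sensitivity factor is the through-origin slope of liver SNR^2 on
#' detected counts (in 10^6 units), fitted over a count range where the
#' Poisson proportionality holds (default up to 20 x 10^6 counts). Dividing
#' a subject's SNR^2 values by this factor removes the subject-specific
#' scanner-sensitivity/attenuation scaling.
#'
#' @param counts detected true counts per ensemble.
#' @param snr2 liver SNR^2 per ensemble.
#' @param count_range inclusive range of raw counts used in the fit.
#' @param subject subject id carried through.
#' @param weight subject weight (kg), optional descriptive field.
#' @return `subject_sensitivity` object with fields `subject`, `ki`,
#'   `weight`, `n_points`.
#' @export
estimate_ki <- function(counts, snr2, count_range = c(0, 20e6),
                        subject = "S1", weight = NA_real_) {
  keep <- counts >= count_range[1] & counts <= count_range[2]
  if (sum(keep) < 2L) stop("fewer than 2 points in the count range")
  x <- counts[keep] / 1e6
  y <- snr2[keep]
  ki <- sum(x * y) / sum(x^2)
  if (!is.finite(ki) || ki <= 0) stop("non-positive sensitivity estimate")
  structure(list(subject = subject, ki = ki, weight = weight,
                 n_points = sum(keep)),
            class = "subject_sensitivity")
}

#' @export
print.subject_sensitivity <- function(x, ...) {
  cat(sprintf("<subject_sensitivity %s> Ki = %.4g (%d points)\n",
              x$subject, x$ki, x$n_points))
  invisible(x)
}

#' Correct SNR^2 by the subject sensitivity factor
#'
#' @param snr2 SNR^2 values for one subject.
#' @param ki a `subject_sensitivity` or a positive scalar.
#' @return corrected SNR^2 values (`snr2 / ki`); pooled over subjects these
#'   fall on a common line of slope ~1 against counts in 10^6.
#' @export
correct_snr2 <- function(snr2, ki) {
  k <- if (inherits(ki, "subject_sensitivity")) ki$ki else ki
  if (!is.finite(k) || k <= 0) stop("ki must be positive")
  snr2 / k
}

#' Fit the normalized CNR saturation curve
#'
#' Fits `y = 1 / (1 + a * x^(-b))` with `a, b > 0` to normalized CNR
#' (CNR relative to full statistics) against counts in units of 10^6, by
#' Levenberg-Marquardt nonlinear least squares started from the best point
#' of a small (a, b) grid. The form is heuristic — a saturating curve chosen
#' for prediction, not a physical model.
#'
#' @param counts_millions counts in units of 10^6.
#' @param ncnr normalized CNR values.
#' @return `fit_result` with coefficients `a` and `b`.
#' @export
fit_normalized_cnr <- function(counts_millions, ncnr) {
  stopifnot(length(counts_millions) == length(ncnr))
  if (length(ncnr) < 4L) stop("need at least 4 points")
  if (any(counts_millions <= 0)) stop("counts must be positive")
  if (stats::sd(ncnr) == 0) stop("degenerate fit: constant normalized CNR")
  x <- counts_millions; y <- ncnr
  grid <- expand.grid(a = c(0.5, 1, 2.5, 5, 10), b = c(0.3, 0.6, 0.8, 1, 1.5))
  sse <- apply(grid, 1, function(p)
    sum((y - 1 / (1 + p[1] * x^(-p[2])))^2))
  st <- grid[which.min(sse), ]
  fit <- minpack.lm::nlsLM(y ~ 1 / (1 + a * x^(-b)),
                           start = list(a = st$a, b = st$b),
                           lower = c(a = 1e-8, b = 1e-8),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  fit_result("cnr_saturation", c(a = unname(co["a"]), b = unname(co["b"])),
             r_squared_of(y, stats::fitted(fit)),
             count_range = range(counts_millions * 1e6))
}

#' Predict normalized CNR at a count level
#'
#' Evaluates the fitted saturation curve `y = 1 / (1 + a x^(-b))` at counts
#' expressed in 10^6; for the coefficients reported for the clinical cohort
#' (a = 2.41, b = 0.8) this gives 0.60 at x = 5, i.e. CNR reduced to 60% of
#' its full-statistics value at 5 million counts.
#'
#' @param fit `fit_result` from [fit_normalized_cnr()] (or any object with
#'   coefficients `a`, `b`).
#' @param counts_millions counts in units of 10^6, > 0.
#' @return normalized CNR in (0, 1).
#' @export
predict_normalized_cnr <- function(fit, counts_millions) {
  co <- if (inherits(fit, "fit_result")) fit$coefficients else fit
  if (any(counts_millions <= 0)) stop("counts must be positive")
  1 / (1 + co[["a"]] * counts_millions^(-co[["b"]]))
}

#' Counts required for a target normalized CNR
#'
#' Closed-form inversion of the saturation curve:
#' `x = (a / (1/y - 1))^(1/b)`, counts in 10^6. The curve saturates at 1, so
#' targets at or above 1 are rejected.
#'
#' @param fit as in [predict_normalized_cnr()].
#' @param target_ncnr desired normalized CNR in (0, 1).
#' @return required counts in units of 10^6.
#' @export
invert_normalized_cnr <- function(fit, target_ncnr) {
  co <- if (inherits(fit, "fit_result")) fit$coefficients else fit
  if (any(target_ncnr >= 1)) stop("normalized CNR saturates below 1")
  if (any(target_ncnr <= 0)) stop("target must be positive")
  (co[["a"]] / (1 / target_ncnr - 1))^(1 / co[["b"]])
}

#' Descriptive power-law fit
#'
#' Log-log least squares of `y = c * x^p`; offered as a descriptive summary
#' (for example, per-subject sensitivity against weight); no mechanistic
#' claim attaches to it.
#'
#' @param x,y positive vectors.
#' @return `fit_result` (form `"power"`) with coefficients `c` and `p`;
#'   R^2 is computed on the original scale.
#' @export
fit_power <- function(x, y) {
  if (any(x <= 0) || any(y <= 0)) stop("power fit needs positive data")
  if (length(x) < 3L) stop("need at least 3 points")
  fit <- stats::lm(log(y) ~ log(x))
  co <- stats::coef(fit)
  cc <- exp(unname(co[1])); p <- unname(co[2])
  fit_result("power", c(c = cc, p = p),
             r_squared_of(y, cc * x^p), count_range = range(x),
             x_units = "raw")
}
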