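# Straight-line calibration of a response (QI, log counts, TVB-N, TBARS)
# against storage days, plus inverse prediction of days-in-ice.

#' Construct a linear calibration fit
#'
#' Mostly used internally; [fit_line()] is the estimator. Exposed so that
#' published slope/intercept pairs can be wrapped as `linear_fit` objects for
#' prediction without the underlying raw data (in which case `r_squared`,
#' `residual_sd` and `n` may be `NA`).
#'
#' @param slope slope (response units per day).
#' @param intercept intercept (response units).
#' @param r_squared coefficient of determination in `[0, 1]`.
#' @param residual_sd residual standard deviation (response units).
#' @param n number of points the line was fitted to.
#' @return An object of class `linear_fit`.
#' @export
linear_fit <- function(slope, intercept, r_squared = NA_real_,
                       residual_sd = NA_real_, n = NA_integer_) {
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12))
    stop("r_squared must lie in [0, 1]")
  if (!is.na(residual_sd) && residual_sd < 0)
    stop("residual_sd must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, residual_sd = residual_sd,
                 n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: y = %.4f * day + %.4f  (R2 = %s, n = %s)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$n))
  invisible(x)
}

#' Ordinary least-squares straight-line fit
#'
#' Fits `y = slope * x + intercept` by OLS (via [stats::lm()]) and returns the
#' quantities the calibration work needs: slope, intercept,
#' `R2 = 1 - SSres/SStot`, residual SD and n.
#'
#' @param x numeric predictor (storage days).
#' @param y numeric response.
#' @return A [linear_fit].
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2) stop("need at least 2 points to fit a line")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("degenerate x: zero variance, calibration line undefined")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 1 else 1 - ssres / sstot
  n <- length(x)
  linear_fit(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = max(0, min(1, r2)),
             residual_sd = if (n > 2) sqrt(ssres / (n - 2)) else 0,
             n = as.integer(n))
}

#' Evaluate a calibration line
#'
#' @param fit a [linear_fit].
#' @param day storage day(s).
#' @return numeric response on the calibration scale (not rounded).
#' @export
predict_line <- function(fit, day) fit$slope * day + fit$intercept

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Predict an integer quality index from a calibration line
#'
#' Evaluates `slope * day + intercept`, rounds half away from zero and clamps
#' to the protocol's demerit range `[0, protocol_max]`.
#'
#' @param fit a [linear_fit] on the QI scale.
#' @param day storage day(s), `>= 0`.
#' @param protocol_max protocol maximum QI (e.g. `max_qi(protocol)`).
#' @return integer QI value(s).
#' @export
predict_qi <- function(fit, day, protocol_max) {
  if (any(day < 0)) stop("day must be >= 0")
  q <- round_half_away(predict_line(fit, day))
  as.integer(pmin(pmax(q, 0), protocol_max))
}

#' Inverse prediction: days in ice from an observed quality index
#'
#' Inverts the calibration line, `day = (qi - intercept)/slope`, and attaches
#' an approximate confidence interval by first-order (delta-method)
#' propagation of the calibration's residual SD through the inverse map:
#' `se(day) ~ residual_sd / |slope|`. Bounds are clipped at 0 days. The
#' interval is approximate and adequate when the slope is many standard
#' errors away from zero, as is the case for all calibrations here.
#'
#' @param fit a [linear_fit] with nonzero slope.
#' @param qi observed quality index (need not be integer).
#' @param confidence interval coverage as a fraction (default 0.95).
#' @return A list of class `day_estimate` with `point`, `lower`, `upper`
#'   (days) and `confidence`.
#' @export
inverse_predict <- function(fit, qi, confidence = 0.95) {
  if (fit$slope == 0) stop("calibration uninformative: slope is zero")
  point <- (qi - fit$intercept) / fit$slope
  se <- if (is.na(fit$residual_sd)) NA_real_ else fit$residual_sd / abs(fit$slope)
  z <- stats::qnorm((1 + confidence) / 2)
  lo <- if (is.na(se)) NA_real_ else max(0, point - z * se)
  hi <- if (is.na(se)) NA_real_ else max(0, point + z * se)
  structure(list(point = point, lower = lo, upper = hi,
                 confidence = confidence),
            class = "day_estimate")
}

#' @export
print.day_estimate <- function(x, ...) {
  cat(sprintf("estimated storage: %.2f days (%.0f%% CI %.2f-%.2f)\n",
              x$point, 100 * x$confidence, x$lower, x$upper))
  invisible(x)
}

#' Remaining shelf-life given an observed quality index
#'
#' `max(0, shelf_life_days - estimated days already in ice)`, with the days
#' in ice from [inverse_predict()].
#'
#' @param fit a [linear_fit] with positive slope (quality degrades over time).
#' @param qi observed quality index.
#' @param shelf_life_days established shelf-life of the species (days).
#' @return remaining days, clamped at 0.
#' @export
remaining_shelf_life <- function(fit, qi, shelf_life_days) {
  if (fit$slope <= 0) stop("remaining shelf-life needs a positive slope")
  est <- inverse_predict(fit, qi)
  max(0, shelf_life_days - est$point)
}

#' Prediction-error summaries (SEP family)
#'
#' Reports the three conventions in use for the "standard error of
#' performance" of a calibration: the root-mean-square error of prediction,
#' the mean bias, and the bias-corrected SEP.
#' With errors `e = predicted - observed`:
#' `bias = mean(e)`, `rmsep = sqrt(mean(e^2))`,
#' `sep_corrected = sqrt(sum((e - mean(e))^2)/(n - 1))`. They satisfy
#' `rmsep^2 = bias^2 + sep_corrected^2 * (n-1)/n`.
#'
#' @param observed numeric vector of observations.
#' @param predicted numeric vector of predictions, same length.
#' @return list with `rmsep`, `bias`, `sep_corrected` (response units).
#' @export
sep <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 2) stop("need at least 2 pairs")
  e <- predicted - observed
  list(rmsep = sqrt(mean(e^2)),
       bias = mean(e),
       sep_corrected = sqrt(sum((e - mean(e))^2) / (length(e) - 1)))
}
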