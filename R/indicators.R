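# Spoilage-indicator engine: named time series with units, acceptability
# limit rules, limit-crossing detection (discrete on observations and
# continuous on fitted lines), biogenic-amine quality classes, and
# correlation of indicators with the panel quality index.

#' Indicator time series
#'
#' @param name indicator name (e.g. `"psychrotrophic"`, `"tvbn"`).
#' @param units measurement units, non-empty (e.g. `"log CFU/g"`).
#' @param day strictly increasing storage days.
#' @param value finite values, same length as `day`.
#' @return object of class `indicator_series`.
#' @export
indicator_series <- function(name, units, day, value) {
  if (!nzchar(units)) stop("units must be non-empty")
  if (length(day) != length(value)) stop("day and value lengths differ")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(!is.finite(value))) stop("values must be finite")
  structure(list(name = name, units = units,
                 observations = data.frame(day = day, value = value)),
            class = "indicator_series")
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("indicator '%s' (%s), %d observations over days %g-%g\n",
              x$name, x$units, nrow(x$observations),
              min(x$observations$day), max(x$observations$day)))
  invisible(x)
}

#' Acceptability limit rule for a spoilage indicator
#'
#' @param indicator indicator name the rule applies to.
#' @param threshold finite limit value, in the indicator's units.
#' @param direction one of `"at_or_above"`, `"above"`, `"at_or_below"`:
#'   the condition under which the sample is unacceptable.
#' @param units units the threshold is expressed in; checked against the
#'   series when the rule is applied.
#' @param source free-text provenance of the limit.
#' @return object of class `limit_rule`.
#' @export
limit_rule <- function(indicator, threshold,
                       direction = c("at_or_above", "above", "at_or_below"),
                       units = NULL, source = "") {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(list(indicator = indicator, threshold = threshold,
                 direction = direction, units = units, source = source),
            class = "limit_rule")
}

rule_satisfied <- function(value, rule) {
  switch(rule$direction,
         at_or_above = value >= rule$threshold,
         above = value > rule$threshold,
         at_or_below = value <= rule$threshold)
}

#' First sampling day on which a limit rule fires
#'
#' Scans the observed series in day order and returns the smallest day whose
#' observation satisfies the rule, or `NA` if the limit is never reached
#' within the series.
#'
#' @param series an [indicator_series].
#' @param rule a [limit_rule]; its units (when set) must match the series.
#' @return day (numeric) or `NA_real_`.
#' @export
first_crossing_day <- function(series, rule) {
  if (nrow(series$observations) == 0) stop("empty indicator series")
  if (!is.null(rule$units) && !identical(rule$units, series$units))
    stop("units mismatch for '", series$name, "': series in '", series$units,
         "', rule in '", rule$units, "'")
  hit <- which(rule_satisfied(series$observations$value, rule))
  if (length(hit) == 0) return(NA_real_)
  series$observations$day[min(hit)]
}

#' Continuous limit-crossing day from a fitted line
#'
#' Solves `slope * day + intercept = threshold` for the day at which a fitted
#' indicator trend reaches its limit. Returns `NA` (with a warning for a zero
#' slope) when the line never reaches the limit for non-negative days or
#' moves away from it; returns 0 when the line already satisfies the rule at
#' day 0.
#'
#' @param fit a [linear_fit] for the indicator against storage day.
#' @param rule a [limit_rule].
#' @return crossing day (numeric, possibly fractional) or `NA_real_`.
#' @export
crossing_day_continuous <- function(fit, rule) {
  if (fit$slope == 0) {
    warning("zero slope: no crossing day")
    return(NA_real_)
  }
  if (rule_satisfied(predict_line(fit, 0), rule)) return(0)
  d <- (rule$threshold - fit$intercept) / fit$slope
  towards <- switch(rule$direction,
                    at_or_above = , above = fit$slope > 0,
                    at_or_below = fit$slope < 0)
  if (!towards || d < 0) return(NA_real_)
  d
}

#' Biogenic-amine quality class
#'
#' Classifies a putrescine concentration into the customary freshness bands:
#' below 10 mg/kg indicates high-quality fresh fish, above 20 mg/kg low
#' quality, with the closed interval `[10, 20]` (boundaries included) taken
#' as intermediate since the bands are defined by strict inequalities.
#'
#' @param value concentration in mg/kg, `>= 0`.
#' @param kind amine; only `"putrescine"` has published class limits here.
#' @return one of `"fresh"`, `"intermediate"`, `"low_quality"` (vectorised).
#' @export
classify_amine <- function(value, kind = "putrescine") {
  kind <- match.arg(kind)
  if (any(value < 0)) stop("amine concentration must be >= 0")
  ifelse(value < 10, "fresh", ifelse(value > 20, "low_quality", "intermediate"))
}

#' Pearson correlation with domain validation
#'
#' Sample Pearson correlation (via [stats::cor()]) with explicit rejection of
#' the degenerate cases: unequal lengths, fewer than 3 pairs, or a constant
#' argument (undefined correlation).
#'
#' @param a,b numeric vectors of equal length `>= 3`.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant input")
  stats::cor(a, b, method = "pearson")
}

#' Correlation matrix of the panel QI with spoilage indicators
#'
#' Aligns the per-day panel quality index with each indicator series by exact
#' inner join on day (no interpolation; all series in a study share the
#' sampling grid) and returns the Pearson correlation matrix.
#'
#' @param panel a `panel_qi` object from [aggregate_panel()], or a data.frame
#'   with columns `storage_day` and `qi_mean`.
#' @param indicators list of [indicator_series].
#' @return symmetric correlation matrix with unit diagonal; rows/columns
#'   `qi` plus the indicator names.
#' @export
correlation_matrix <- function(panel, indicators) {
  qi <- if (inherits(panel, "panel_qi")) panel$summary else panel
  days <- qi$storage_day
  for (s in indicators) days <- intersect(days, s$observations$day)
  days <- sort(days)
  if (length(days) < 3)
    stop("fewer than 3 common days across series; cannot correlate")
  m <- cbind(qi = qi$qi_mean[match(days, qi$storage_day)])
  for (s in indicators) {
    v <- s$observations$value[match(days, s$observations$day)]
    m <- cbind(m, v)
    colnames(m)[ncol(m)] <- s$name
  }
  consts <- apply(m, 2, stats::sd) == 0
  if (any(consts))
    stop("undefined correlation: constant series ",
         paste(colnames(m)[consts], collapse = ", "))
  stats::cor(m, method = "pearson")
}
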