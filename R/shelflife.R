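# Shelf-life decision logic: sensory rejection at the protocol maximum,
# indicator limit crossings, and their integration into a single shelf-life
# estimate on the sampling grid, plus a machine-readable study report.

#' Rejection finding
#'
#' @param criterion `"sensory_qi_max"` or an indicator name.
#' @param rejection_day day the criterion fired, or `NA` if it never did.
#' @param evidence human-readable justification.
#' @return object of class `rejection_finding`.
#' @export
rejection_finding <- function(criterion, rejection_day, evidence = "") {
  structure(list(criterion = criterion,
                 rejection_day = rejection_day,
                 evidence = evidence),
            class = "rejection_finding")
}

#' Sensory rejection day of a panel
#'
#' The panel is taken to have rejected the fish on the first storage day
#' whose rounded mean quality index reaches the protocol maximum (the
#' maximum demerit score means every attribute was scored at its worst).
#' With `any_referee = TRUE`, a single sheet at the protocol maximum
#' triggers rejection instead of the panel mean.
#'
#' @param panel a `panel_qi` from [aggregate_panel()].
#' @param protocol the [qim_protocol] the panel scored against.
#' @param any_referee use the stricter single-sheet rule.
#' @param assessments long-format assessments; required when
#'   `any_referee = TRUE`.
#' @return a [rejection_finding] with criterion `"sensory_qi_max"`.
#' @export
sensory_rejection_day <- function(panel, protocol, any_referee = FALSE,
                                  assessments = NULL) {
  m <- max_qi(protocol)
  if (any_referee) {
    if (is.null(assessments))
      stop("any_referee = TRUE needs the raw assessments")
    key <- interaction(assessments$lot, assessments$fish_id,
                       assessments$referee_id, assessments$storage_day,
                       drop = TRUE)
    qi <- vapply(split(assessments, key),
                 function(s) as.numeric(score_assessment(s, protocol)),
                 numeric(1))
    day <- vapply(split(assessments, key),
                  function(s) s$storage_day[1], numeric(1))
    hit <- day[qi >= m]
    rd <- if (length(hit)) min(hit) else NA_real_
    return(rejection_finding("sensory_qi_max", rd,
                             if (is.na(rd)) "no sheet reached the protocol maximum"
                             else sprintf("a sheet reached QI %d on day %g", m, rd)))
  }
  hit <- panel$summary$storage_day[round_half_away(panel$summary$qi_mean) >= m]
  rd <- if (length(hit)) min(hit) else NA_real_
  rejection_finding("sensory_qi_max", rd,
                    if (is.na(rd))
                      sprintf("panel mean QI never reached the maximum (%d)", m)
                    else
                      sprintf("panel mean QI reached the maximum (%d) on day %g",
                              m, rd))
}

#' Integrate rejection findings into a shelf-life estimate
#'
#' The shelf-life is the greatest sampling day strictly before the first
#' rejection: a rejection observed on day 14 of the grid
#' `{1, 4, 8, 11, 14, 18}` gives a shelf-life of 11 days. If no criterion
#' fired, the shelf-life is undetermined within the study
#' (`status = "not reached within study"`); if the first sampling day is
#' already rejected there is no acceptable observation to fall back on
#' (`status = "rejected at first observation"`).
#'
#' @param findings list of [rejection_finding] objects.
#' @param sampling_days strictly increasing sampling grid.
#' @return object of class `shelf_life_result`: list with `sampling_days`,
#'   `findings`, `first_rejection_day` (day or `NA`), `shelf_life_days`
#'   (day or `NA`) and `status`.
#' @export
integrate_shelf_life <- function(findings, sampling_days) {
  if (any(diff(sampling_days) <= 0))
    stop("sampling_days must be strictly increasing")
  days <- vapply(findings, function(f) as.numeric(f$rejection_day), numeric(1))
  days <- days[!is.na(days)]
  if (length(days) == 0) {
    return(structure(list(sampling_days = sampling_days, findings = findings,
                          first_rejection_day = NA_real_,
                          shelf_life_days = NA_real_,
                          status = "not reached within study"),
                     class = "shelf_life_result"))
  }
  first <- min(days)
  before <- sampling_days[sampling_days < first]
  if (length(before) == 0) {
    return(structure(list(sampling_days = sampling_days, findings = findings,
                          first_rejection_day = first,
                          shelf_life_days = NA_real_,
                          status = "rejected at first observation"),
                     class = "shelf_life_result"))
  }
  structure(list(sampling_days = sampling_days, findings = findings,
                 first_rejection_day = first,
                 shelf_life_days = max(before),
                 status = "ok"),
            class = "shelf_life_result")
}

#' @export
print.shelf_life_result <- function(x, ...) {
  cat("shelf-life result:", x$status, "\n")
  cat("  first rejection day:", x$first_rejection_day, "\n")
  cat("  shelf-life (days):", x$shelf_life_days, "\n")
  invisible(x)
}

#' Build an integrated study report
#'
#' Runs the whole pipeline over a (simulated or observed) study: panel
#' aggregation, QI-vs-day calibration, PLS/VIP attribute importance,
#' indicator limit crossings (discrete and continuous), the correlation
#' matrix, and the integrated shelf-life decision. Stages that cannot run
#' (e.g. PLS skipped, too few common days to correlate) are marked skipped
#' rather than aborting the report. Output is a plain nested list,
#' serialisable to JSON, and is deterministic given identical inputs.
#'
#' @param assessments long-format panel assessments.
#' @param indicators list of [indicator_series].
#' @param protocol the [qim_protocol].
#' @param limits named list of [limit_rule]; defaults to [kw_limit_rules()]
#'   plus the putrescine low-quality band (`> 20` mg/kg) when a putrescine
#'   series is present. Amine crossings are reported as informational only
#'   (`informational` in the crossings section) and do not enter the
#'   shelf-life decision: the amine bands grade quality, while rejection here
#'   follows the sensory and microbial/chemical acceptability criteria.
#' @param run_pls run the PLS/VIP stage.
#' @return nested list of class `qim_report`.
#' @export
build_report <- function(assessments, indicators, protocol,
                         limits = NULL, run_pls = TRUE) {
  panel <- aggregate_panel(assessments, protocol)
  pm <- max_qi(protocol)

  cal <- fit_line(panel$summary$storage_day, panel$summary$qi_mean)
  calibration <- list(slope = cal$slope, intercept = cal$intercept,
                      r_squared = cal$r_squared,
                      residual_sd = cal$residual_sd, n = cal$n)

  pls_section <- list(skipped = TRUE)
  if (run_pls) {
    X <- as.matrix(panel$parameter_means[, -1, drop = FALSE])
    y <- panel$parameter_means$storage_day
    cv <- loo_cv_pls(X, y, ncomp_max = min(3, nrow(X) - 2, ncol(X)))
    m <- fit_pls1(X, y, ncomp = cv$chosen_ncomp)
    vip <- vip_scores(m)
    sep_train <- sep(y, predict(m, X))
    pls_section <- list(skipped = FALSE,
                        chosen_ncomp = cv$chosen_ncomp,
                        rmsecv = as.list(stats::setNames(
                          cv$rmsecv, paste0("ncomp", seq_along(cv$rmsecv)))),
                        sep = sep_train,
                        vip = as.list(vip$vip),
                        selected = vip$selected)
  }

  if (is.null(limits)) {
    limits <- kw_limit_rules()
    if ("putrescine" %in% names(indicators))
      limits$putrescine <- limit_rule("putrescine", 20, "above",
                                      units = "mg/kg",
                                      source = "putrescine low-quality band")
  }
  amine_names <- unique(kw_amine_series()$amine)
  crossings <- list()
  findings <- list(sensory_rejection_day(panel, protocol))
  for (nm in names(limits)) {
    if (!nm %in% names(indicators)) next
    s <- indicators[[nm]]
    r <- limits[[nm]]
    d_obs <- first_crossing_day(s, r)
    lf <- fit_line(s$observations$day, s$observations$value)
    d_cont <- crossing_day_continuous(lf, r)
    informational <- nm %in% amine_names
    crossings[[nm]] <- list(threshold = r$threshold, direction = r$direction,
                            units = r$units,
                            observed_crossing_day = d_obs,
                            fitted_crossing_day = d_cont,
                            informational = informational)
    if (!informational)
      findings <- c(findings, list(rejection_finding(
        nm, d_obs,
        sprintf("%s %s %g %s", nm, r$direction, r$threshold,
                if (is.null(r$units)) "" else r$units))))
  }

  correlations <- tryCatch(
    correlation_matrix(panel, indicators),
    error = function(e) NULL)

  shelf <- integrate_shelf_life(findings,
                                sort(unique(panel$summary$storage_day)))

  structure(list(
    protocol = list(name = protocol$name,
                    n_parameters = nrow(protocol_parameters(protocol)),
                    max_qi = pm),
    panel = panel$summary,
    calibration = calibration,
    pls = pls_section,
    crossings = crossings,
    correlations = if (is.null(correlations)) list(skipped = TRUE)
                   else as.data.frame(correlations),
    shelf_life = list(
      first_rejection_day = shelf$first_rejection_day,
      shelf_life_days = shelf$shelf_life_days,
      status = shelf$status,
      findings = lapply(shelf$findings, unclass))
  ), class = "qim_report")
}

#' Write a study report as JSON and markdown
#'
#' JSON is written with stable key order (`auto_unbox`, full precision); the
#' markdown rendering is a short human-readable digest of the same content.
#'
#' @param report a `qim_report` from [build_report()].
#' @param json_path output JSON path (`NULL` to skip).
#' @param md_path output markdown path (`NULL` to skip).
#' @return the report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  if (!is.null(md_path)) {
    lines <- c(
      paste0("# QIM shelf-life report: ", report$protocol$name),
      "",
      sprintf("- protocol: %d parameters, QI range 0-%d",
              report$protocol$n_parameters, report$protocol$max_qi),
      sprintf("- QI calibration: QI = %.4f x day + %.4f (R2 = %.4f, n = %d)",
              report$calibration$slope, report$calibration$intercept,
              report$calibration$r_squared, report$calibration$n),
      if (isTRUE(report$pls$skipped)) "- PLS/VIP stage: skipped"
      else sprintf("- PLS: %d component(s); attributes with VIP > 1: %s",
                   report$pls$chosen_ncomp,
                   paste(report$pls$selected, collapse = ", ")),
      "",
      "## Limit crossings",
      vapply(names(report$crossings), function(nm) {
        cr <- report$crossings[[nm]]
        sprintf("- %s: %s %g %s; observed day %s, fitted day %s", nm,
                cr$direction, cr$threshold, cr$units,
                format(cr$observed_crossing_day),
                format(round(cr$fitted_crossing_day, 2)))
      }, character(1)),
      "",
      sprintf("## Shelf-life: %s days (first rejection day %s; %s)",
              format(report$shelf_life$shelf_life_days),
              format(report$shelf_life$first_rejection_day),
              report$shelf_life$status))
    writeLines(unlist(lines), md_path)
  }
  invisible(report)
}
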