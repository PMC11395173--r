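#' QIM demerit protocol
#'
#' A Quality Index Method (QIM) protocol is an ordered list of attribute
#' groups (e.g. overall aspect, gills, eyes, anal area), each holding sensory
#' parameters with ordered descriptors and integer demerit points. The sum of
#' the demerits awarded on one score sheet is the quality index (QI); the
#' protocol maximum is the rejection score.
#'
#' Within each parameter the demerit points must be consecutive integers
#' starting at 0 (typically 0--1 or 0--2), and parameter names must be unique
#' across the whole protocol.
#'
#' @param name protocol name.
#' @param groups list of groups, each `list(group_name =, parameters = list(...))`
#'   where every parameter is
#'   `list(parameter_name =, descriptors = list(list(description =, demerit =), ...))`.
#' @param version schema version string.
#' @return An object of class `qim_protocol`.
#' @seealso [read_protocol()], [max_qi()], [score_assessment()]
#' @export
qim_protocol <- function(name, groups, version = "1") {
  p <- structure(list(name = name, version = version, groups = groups),
                 class = "qim_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(is.list(p$groups))
  seen <- character(0)
  for (g in p$groups) {
    if (is.null(g$group_name) || !nzchar(g$group_name))
      stop("protocol group without a group_name")
    for (par in g$parameters) {
      nm <- par$parameter_name
      if (is.null(nm) || !nzchar(nm))
        stop("parameter without a name in group '", g$group_name, "'")
      if (nm %in% seen)
        stop("duplicate parameter name in protocol: '", nm, "'")
      seen <- c(seen, nm)
      d <- vapply(par$descriptors, function(x) as.numeric(x$demerit), numeric(1))
      if (length(d) < 1 || any(d != round(d)) || any(d < 0))
        stop("parameter '", nm, "': demerit points must be non-negative integers")
      if (!identical(as.integer(sort(d)), seq(0L, length(d) - 1L)))
        stop("parameter '", nm, "': demerit points must be consecutive integers ",
             "starting at 0 (got ", paste(sort(d), collapse = ","), ")")
    }
  }
  invisible(p)
}

#' Read a QIM protocol from JSON
#'
#' Expects a UTF-8 JSON document
#' `{name, version, groups:[{group_name, parameters:[{parameter_name,
#' descriptors:[{description, demerit}]}]}]}`. The bundled transcription of
#' the king weakfish scheme is at
#' `system.file("extdata", "king_weakfish_protocol.json", package = "qimshelf")`.
#'
#' @param path path to a protocol JSON file.
#' @return A validated [qim_protocol] object.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$name) || is.null(raw$groups))
    stop("protocol file missing required fields 'name'/'groups': ", path)
  qim_protocol(name = raw$name, groups = raw$groups,
               version = if (is.null(raw$version)) "1" else raw$version)
}

#' Write a QIM protocol to JSON
#'
#' Serialisation uses a fixed key order so that a read/write round trip is
#' content-identical.
#'
#' @param p a [qim_protocol].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(p, path) {
  out <- list(
    name = p$name, version = p$version,
    groups = lapply(p$groups, function(g) list(
      group_name = g$group_name,
      parameters = lapply(g$parameters, function(par) list(
        parameter_name = par$parameter_name,
        descriptors = lapply(par$descriptors, function(d) list(
          description = d$description, demerit = as.integer(d$demerit)))))))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Parameter table of a protocol
#'
#' @param p a [qim_protocol].
#' @return data.frame with columns `group`, `parameter`, `max_demerit`, in
#'   protocol order.
#' @export
protocol_parameters <- function(p) {
  rows <- do.call(rbind, lapply(p$groups, function(g) {
    do.call(rbind, lapply(g$parameters, function(par) {
      data.frame(group = g$group_name, parameter = par$parameter_name,
                 max_demerit = max(vapply(par$descriptors,
                                          function(d) as.integer(d$demerit),
                                          integer(1))),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Protocol maximum quality index
#'
#' The rejection score: the sum over parameters of each parameter's maximum
#' demerit. For the bundled king weakfish protocol this is 21.
#'
#' @param p a [qim_protocol].
#' @return integer maximum QI.
#' @export
max_qi <- function(p) {
  pars <- protocol_parameters(p)
  if (is.null(pars) || nrow(pars) == 0) return(0L)
  as.integer(sum(pars$max_demerit))
}

#' @export
print.qim_protocol <- function(x, ...) {
  pars <- protocol_parameters(x)
  cat("QIM protocol:", x$name, "\n")
  cat("  ", length(x$groups), " groups, ", nrow(pars),
      " parameters, QI range 0-", max_qi(x), "\n", sep = "")
  invisible(x)
}

#' Score one assessment sheet
#'
#' The quality index of a sheet is the sum of the per-parameter demerits. The
#' sheet must be complete (every protocol parameter scored exactly once) and
#' in range; partial sheets are rejected rather than imputed, because a QIM
#' sum is meaningless with missing parameters.
#'
#' @param scores named integer vector or single-sheet data.frame with columns
#'   `parameter`, `demerit`.
#' @param p a [qim_protocol].
#' @return integer QI in `[0, max_qi(p)]`.
#' @export
score_assessment <- function(scores, p) {
  if (is.data.frame(scores)) {
    v <- scores$demerit
    names(v) <- scores$parameter
    scores <- v
  }
  pars <- protocol_parameters(p)
  miss <- setdiff(pars$parameter, names(scores))
  if (length(miss))
    stop("incomplete assessment: missing parameter(s) ",
         paste(sQuote(miss), collapse = ", "))
  extra <- setdiff(names(scores), pars$parameter)
  if (length(extra))
    stop("unknown parameter(s) in assessment: ",
         paste(sQuote(extra), collapse = ", "))
  if (anyDuplicated(names(scores)))
    stop("duplicated parameter in assessment sheet")
  d <- scores[pars$parameter]
  if (any(d != round(d))) stop("demerits must be integers")
  bad <- which(d < 0 | d > pars$max_demerit)
  if (length(bad))
    stop("demerit out of range for parameter ",
         sQuote(pars$parameter[bad[1]]), ": ", d[bad[1]],
         " (allowed 0..", pars$max_demerit[bad[1]], ")")
  as.integer(sum(d))
}

#' Read panel score sheets from CSV
#'
#' Long format, header `lot,fish_id,referee_id,storage_day,parameter,demerit`.
#'
#' @param path CSV path.
#' @return data.frame of assessments in long format.
#' @export
read_scoresheets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lot", "fish_id", "referee_id", "storage_day", "parameter", "demerit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("score-sheet CSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write panel score sheets to CSV
#'
#' @param assessments long-format assessment data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scoresheets <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate panel score sheets into per-day quality indices
#'
#' Each sheet (one referee scoring one fish on one day) is summed to a QI;
#' per storage day the panel QI is the arithmetic mean over all sheets, with
#' its sample standard deviation (0 when a single sheet), alongside the mean
#' demerit of every parameter. This keeps the panel QI on the demerit scale.
#'
#' @param assessments long-format data.frame with columns `lot`, `fish_id`,
#'   `referee_id`, `storage_day`, `parameter`, `demerit`.
#' @param p a [qim_protocol]; every sheet is validated against it.
#' @return An object of class `panel_qi`: a list with
#'   \describe{
#'     \item{summary}{data.frame `storage_day`, `qi_mean`, `qi_sd`, `n_assessments`}
#'     \item{parameter_means}{data.frame `storage_day` plus one column per parameter}
#'   }
#' @export
aggregate_panel <- function(assessments, p) {
  pars <- protocol_parameters(p)
  key <- interaction(assessments$lot, assessments$fish_id,
                     assessments$referee_id, assessments$storage_day,
                     drop = TRUE)
  sheets <- split(assessments, key)
  qi <- vapply(sheets, function(s) as.numeric(score_assessment(s, p)), numeric(1))
  day <- vapply(sheets, function(s) s$storage_day[1], numeric(1))

  days <- sort(unique(day))
  summ <- data.frame(
    storage_day = days,
    qi_mean = vapply(days, function(d) mean(qi[day == d]), numeric(1)),
    qi_sd = vapply(days, function(d) {
      x <- qi[day == d]
      if (length(x) < 2) 0 else stats::sd(x)
    }, numeric(1)),
    n_assessments = vapply(days, function(d) sum(day == d), integer(1))
  )

  pm <- vapply(days, function(d) {
    sub <- assessments[assessments$storage_day == d, ]
    vapply(pars$parameter,
           function(par) mean(sub$demerit[sub$parameter == par]), numeric(1))
  }, numeric(nrow(pars)))
  parameter_means <- data.frame(storage_day = days, t(pm), check.names = FALSE)

  structure(list(summary = summ, parameter_means = parameter_means),
            class = "panel_qi")
}

#' @export
print.panel_qi <- function(x, ...) {
  cat("Panel quality index (", nrow(x$summary), " storage days)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
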