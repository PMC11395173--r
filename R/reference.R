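#' Bundled king weakfish protocol
#'
#' Convenience loader for the demerit scheme shipped with the package
#' (4 attribute groups, 13 parameters, QI range 0--21).
#'
#' @return A [qim_protocol].
#' @export
king_weakfish_protocol <- function() {
  read_protocol(system.file("extdata", "king_weakfish_protocol.json",
                            package = "qimshelf", mustWork = TRUE))
}

#' Reference calibration lines for ice-stored king weakfish
#'
#' Published straight-line calibrations for whole king weakfish stored in ice,
#' used as simulator defaults and as anchors in the examples: quality index vs
#' storage day for two application lots, log-linear mesophilic and
#' psychrotrophic plate counts, TVB-N and TBARS trends.
#'
#' The microbial and TVB-N intercepts are stored with positive sign. The
#' originally typeset negative intercepts are inconsistent with the same
#' study's point values (mesophilic 5.7 log CFU/g at day 18, psychrotrophic
#' 7.02 log CFU/g at day 14, TVB-N 11.06 rising to 28.4 mg N/100 g), all of
#' which the positive intercepts reproduce; `intercept_as_printed` keeps the
#' original value.
#'
#' @return A named list of lists with elements `slope`, `intercept`, `units`,
#'   `r_squared` (as published) and, where the sign was corrected,
#'   `intercept_as_printed`.
#' @export
kw_reference_lines <- function() {
  list(
    qi_lot3 = list(slope = 0.767, intercept = 8.3361,
                   units = "demerit points", r_squared = 0.9661),
    qi_lot4 = list(slope = 0.9281, intercept = 1.3378,
                   units = "demerit points", r_squared = 0.9868),
    mesophilic = list(slope = 0.1229, intercept = 3.4642,
                      intercept_as_printed = -3.4642,
                      units = "log CFU/g", r_squared = 0.9399),
    psychrotrophic = list(slope = 0.1593, intercept = 4.5679,
                          intercept_as_printed = -4.5679,
                          units = "log CFU/g", r_squared = 0.9747),
    tvbn = list(slope = 0.9577, intercept = 8.0379,
                intercept_as_printed = -8.0379,
                units = "mg N/100 g", r_squared = 0.8488),
    tbars = list(slope = 0.0034, intercept = 0.2253,
                 units = "mg MDA/kg", r_squared = 0.8849)
  )
}

#' Reference biogenic-amine series for ice-stored king weakfish
#'
#' Putrescine, cadaverine and spermidine concentrations (mg/kg) measured over
#' ice storage; putrescine accumulates near-exponentially and drives the
#' amine-based quality classification.
#'
#' @return data.frame with columns `day`, `amine`, `value_mg_kg`.
#' @export
kw_amine_series <- function() {
  data.frame(
    day = c(1, 4, 8, 11, 14,   4, 14,   4, 14),
    amine = c(rep("putrescine", 5), rep("cadaverine", 2), rep("spermidine", 2)),
    value_mg_kg = c(3.28, 13.74, 24.41, 65.84, 409.97, 15.22, 55.54, 0.69, 1.71)
  )
}

#' Default spoilage-indicator limit rules
#'
#' The acceptability limits used throughout: 7 log CFU/g for mesophilic and
#' psychrotrophic plate counts in refrigerated fish (reaching the limit counts
#' as rejection), 30 mg N/100 g for TVB-N (the stricter of the two customary
#' limits 30 and 35), and 5 mg MDA/kg for TBARS (lower bound of the customary
#' 5--8 band).
#'
#' @return A named list of [limit_rule] objects.
#' @export
kw_limit_rules <- function() {
  list(
    mesophilic = limit_rule("mesophilic", 7, "at_or_above", units = "log CFU/g",
                            source = "ICMSF limit for refrigerated fish"),
    psychrotrophic = limit_rule("psychrotrophic", 7, "at_or_above",
                                units = "log CFU/g",
                                source = "ICMSF limit for refrigerated fish"),
    tvbn = limit_rule("tvbn", 30, "at_or_above", units = "mg N/100 g",
                      source = "customary TVB-N acceptability limit"),
    tbars = limit_rule("tbars", 5, "at_or_above", units = "mg MDA/kg",
                       source = "lower bound of customary 5-8 mg MDA/kg band")
  )
}
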