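# Shared fixtures, built in code.

kw_protocol <- king_weakfish_protocol()

# minimal two-parameter protocol (maxima 1 and 2)
tiny_protocol <- function() {
  qim_protocol("tiny", list(
    list(group_name = "g", parameters = list(
      list(parameter_name = "a", descriptors = list(
        list(description = "ok", demerit = 0),
        list(description = "bad", demerit = 1))),
      list(parameter_name = "b", descriptors = list(
        list(description = "ok", demerit = 0),
        list(description = "worse", demerit = 1),
        list(description = "bad", demerit = 2)))))))
}

# one complete sheet for a protocol, all demerits equal to `value` clamped to
# each parameter's maximum
flat_sheet <- function(protocol, value = 0) {
  pars <- protocol_parameters(protocol)
  stats::setNames(pmin(value, pars$max_demerit), pars$parameter)
}

# long-format assessments from a list of named score vectors
as_assessments <- function(sheets, day, lot = "L", fish = "f1") {
  do.call(rbind, lapply(seq_along(sheets), function(i) {
    data.frame(lot = lot, fish_id = fish, referee_id = paste0("r", i),
               storage_day = day, parameter = names(sheets[[i]]),
               demerit = unname(sheets[[i]]), stringsAsFactors = FALSE)
  }))
}

# panel whose mean QI follows given per-day values exactly (single sheet/day,
# demerits apportioned like the simulator)
panel_from_qi <- function(qi_by_day, protocol) {
  pars <- protocol_parameters(protocol)
  do.call(rbind, lapply(names(qi_by_day), function(d) {
    dem <- qimshelf:::apportion_demerits(qi_by_day[[d]], pars$max_demerit)
    data.frame(lot = "L", fish_id = "f1", referee_id = "r1",
               storage_day = as.numeric(d), parameter = pars$parameter,
               demerit = dem, stringsAsFactors = FALSE)
  }))
}

# reference lot-4 quality index calibration line
lot4_fit <- function() {
  ref <- kw_reference_lines()$qi_lot4
  linear_fit(ref$slope, ref$intercept, r_squared = ref$r_squared,
             residual_sd = 0.5, n = 6L)
}
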