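# Synthetic spoilage-study generator: panel score sheets with referee-level
# ordinal noise and spoilage-indicator time series, anchored to the reference
# king weakfish trajectories so every downstream stage can be exercised at
# desk scale.

#' Simulation configuration
#'
#' Defaults reproduce the reference study design: sampling on days
#' 1, 4, 8, 11, 14 and 18; a panel of 4 referees each scoring 3 fish per day;
#' quality index following the lot-4 calibration line
#' (0.9281 demerit/day + 1.3378); log-linear mesophilic and psychrotrophic
#' growth; linear TVB-N and TBARS trends; near-exponential putrescine
#' accumulation (log-linear kinetics fitted to the reference amine series).
#'
#' @param sampling_days strictly increasing storage days.
#' @param n_referees panel size per fish.
#' @param n_fish_per_day fish scored per sampling day.
#' @param qi_line list with `slope` (demerit/day) and `intercept` (demerit).
#' @param referee_noise_sd SD of the latent freshness noise, demerit units.
#'   0.5 keeps the simulated QI-vs-day R-squared near the reference 0.9868.
#' @param indicator_models named list; each element is a list with `kind`
#'   (`"linear"`, `"loglinear"` or `"exponential"`), `slope`, `intercept`,
#'   `noise_sd` and `units`. Linear and log-linear kinds evaluate
#'   `slope*day + intercept` plus Gaussian noise; the exponential kind
#'   evaluates `exp(slope*day + intercept)` with multiplicative log-normal
#'   noise (so `slope`/`intercept`/`noise_sd` live on the log scale).
#' @param seed root seed; panel and indicator noise use child streams derived
#'   deterministically from it, so the two are independent but jointly
#'   reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_days = c(1, 4, 8, 11, 14, 18),
                       n_referees = 4,
                       n_fish_per_day = 3,
                       qi_line = list(slope = 0.9281, intercept = 1.3378),
                       referee_noise_sd = 0.5,
                       indicator_models = default_indicator_models(),
                       seed = 1L) {
  if (any(diff(sampling_days) <= 0) || any(sampling_days < 0))
    stop("sampling_days must be strictly increasing and >= 0")
  if (n_referees < 1 || n_fish_per_day < 1)
    stop("n_referees and n_fish_per_day must be >= 1")
  if (referee_noise_sd < 0) stop("referee_noise_sd must be >= 0")
  for (nm in names(indicator_models)) {
    m <- indicator_models[[nm]]
    if (!m$kind %in% c("linear", "loglinear", "exponential"))
      stop("unknown indicator model kind for '", nm, "': ", m$kind)
    if (m$noise_sd < 0) stop("noise_sd must be >= 0 for indicator '", nm, "'")
  }
  structure(list(sampling_days = sampling_days,
                 n_referees = as.integer(n_referees),
                 n_fish_per_day = as.integer(n_fish_per_day),
                 qi_line = qi_line,
                 referee_noise_sd = referee_noise_sd,
                 indicator_models = indicator_models,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default indicator models
#'
#' Microbial, TVB-N and TBARS models use the reference calibration lines
#' ([kw_reference_lines()], sign-corrected intercepts); putrescine kinetics
#' are obtained at call time by log-linear regression on the bundled amine
#' series ([kw_amine_series()]), since no kinetic model is published.
#' Noise SDs reflect typical assay repeatability: 0.15 log CFU/g for plate
#' counts, 1 mg N/100 g for TVB-N, 0.01 mg MDA/kg for TBARS, 0.2 on the log
#' scale for putrescine.
#'
#' @return named list of indicator model specifications (see [sim_config()]).
#' @export
default_indicator_models <- function() {
  ref <- kw_reference_lines()
  am <- kw_amine_series()
  put <- am[am$amine == "putrescine", ]
  pfit <- fit_line(put$day, log(put$value_mg_kg))
  list(
    mesophilic = list(kind = "loglinear", slope = ref$mesophilic$slope,
                      intercept = ref$mesophilic$intercept,
                      noise_sd = 0.15, units = "log CFU/g"),
    psychrotrophic = list(kind = "loglinear", slope = ref$psychrotrophic$slope,
                          intercept = ref$psychrotrophic$intercept,
                          noise_sd = 0.15, units = "log CFU/g"),
    tvbn = list(kind = "linear", slope = ref$tvbn$slope,
                intercept = ref$tvbn$intercept,
                noise_sd = 1.0, units = "mg N/100 g"),
    tbars = list(kind = "linear", slope = ref$tbars$slope,
                 intercept = ref$tbars$intercept,
                 noise_sd = 0.01, units = "mg MDA/kg"),
    putrescine = list(kind = "exponential", slope = pfit$slope,
                      intercept = pfit$intercept,
                      noise_sd = 0.2, units = "mg/kg")
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("spoilage-study simulation config\n")
  cat("  days:", paste(x$sampling_days, collapse = ", "), "\n")
  cat("  panel:", x$n_referees, "referees x", x$n_fish_per_day, "fish/day\n")
  cat(sprintf("  QI line: %.4f*day + %.4f, referee noise SD %.2f\n",
              x$qi_line$slope, x$qi_line$intercept, x$referee_noise_sd))
  cat("  indicators:", paste(names(x$indicator_models), collapse = ", "), "\n")
  invisible(x)
}

# Deterministic child seed per named stream, so panel and indicator noise are
# independent streams of one root seed. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Apportion an integer demerit total among parameters proportionally to their
# maximum demerits, by the largest-remainder method with per-parameter caps.
# Guarantees sum(result) == total whenever 0 <= total <= sum(max_demerit).
apportion_demerits <- function(total, max_demerit) {
  total <- as.integer(min(max(total, 0L), sum(max_demerit)))
  quota <- total * max_demerit / sum(max_demerit)
  base <- pmin(floor(quota), max_demerit)
  left <- total - sum(base)
  if (left > 0) {
    rem <- quota - floor(quota)
    ord <- order(rem, max_demerit, decreasing = TRUE)
    for (j in ord) {
      if (left == 0) break
      if (base[j] < max_demerit[j]) {
        base[j] <- base[j] + 1   # one point per parameter per pass
        left <- left - 1
      }
    }
    while (left > 0) {   # residual passes when many parameters are capped
      j <- which(base < max_demerit)[1]
      base[j] <- base[j] + 1
      left <- left - 1
    }
  }
  as.integer(base)
}

#' Simulate panel score sheets
#'
#' For every sampling day, fish and referee a latent freshness value
#' `f = qi_line(day) + Normal(0, referee_noise_sd)` is drawn, rounded half
#' away from zero to an integer target QI (clamped to the protocol range),
#' and apportioned to the protocol parameters proportionally to each
#' parameter's maximum demerit (largest-remainder method, capped at the
#' parameter maximum). Each sheet's demerits therefore always sum to the
#' discretized latent QI, and with `referee_noise_sd = 0` the sheets
#' reproduce the rounded calibration line exactly.
#'
#' @param config a [sim_config()].
#' @param protocol a [qim_protocol]; defaults to the bundled king weakfish
#'   scheme.
#' @return long-format assessment data.frame (`lot`, `fish_id`, `referee_id`,
#'   `storage_day`, `parameter`, `demerit`).
#' @export
simulate_panel_scores <- function(config, protocol = king_weakfish_protocol()) {
  pars <- protocol_parameters(protocol)
  maxd <- pars$max_demerit
  grid <- expand.grid(referee = seq_len(config$n_referees),
                      fish = seq_len(config$n_fish_per_day),
                      day = config$sampling_days)
  set.seed(child_seed(config$seed, "panel"))
  latent <- config$qi_line$slope * grid$day + config$qi_line$intercept +
    stats::rnorm(nrow(grid), 0, config$referee_noise_sd)
  target <- pmin(pmax(round_half_away(latent), 0), sum(maxd))
  demerits <- vapply(target, apportion_demerits, integer(length(maxd)),
                     max_demerit = maxd)
  data.frame(
    lot = "sim",
    fish_id = rep(paste0("fish", grid$day, "_", grid$fish), each = nrow(pars)),
    referee_id = rep(paste0("ref", grid$referee), each = nrow(pars)),
    storage_day = rep(grid$day, each = nrow(pars)),
    parameter = rep(pars$parameter, times = nrow(grid)),
    demerit = as.integer(demerits),
    stringsAsFactors = FALSE
  )
}

#' Simulate spoilage-indicator time series
#'
#' Evaluates each configured indicator model over the sampling days.
#' Linear and log-linear kinds return `slope*day + intercept + Normal(0,
#' noise_sd)`; the exponential kind returns
#' `exp(slope*day + intercept) * exp(Normal(0, noise_sd))`. With
#' `noise_sd = 0` the values equal the generating function exactly,
#' regardless of seed.
#'
#' @param config a [sim_config()].
#' @return list of [indicator_series] objects, one per configured indicator.
#' @export
simulate_indicators <- function(config) {
  set.seed(child_seed(config$seed, "indicators"))
  out <- lapply(names(config$indicator_models), function(nm) {
    m <- config$indicator_models[[nm]]
    mu <- m$slope * config$sampling_days + m$intercept
    eps <- if (m$noise_sd > 0)
      stats::rnorm(length(mu), 0, m$noise_sd) else numeric(length(mu))
    value <- switch(m$kind,
      linear = ,
      loglinear = mu + eps,
      exponential = exp(mu) * exp(eps),
      stop("unknown indicator model kind for '", nm, "': ", m$kind))
    indicator_series(nm, m$units, day = config$sampling_days, value = value)
  })
  names(out) <- names(config$indicator_models)
  out
}

#' Simulate a complete spoilage study
#'
#' @param config a [sim_config()].
#' @param protocol protocol the panel scores against.
#' @return list of class `simulated_study` with `assessments` (long-format
#'   data.frame), `indicators` (list of [indicator_series]) and `truth` (the
#'   generating configuration).
#' @export
simulate_study <- function(config = sim_config(),
                           protocol = king_weakfish_protocol()) {
  structure(list(assessments = simulate_panel_scores(config, protocol),
                 indicators = simulate_indicators(config),
                 truth = config),
            class = "simulated_study")
}

#' Write simulated indicator series to CSV
#'
#' Dialect `day,indicator,value,units`.
#'
#' @param indicators list of [indicator_series].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(indicators, path) {
  df <- do.call(rbind, lapply(indicators, function(s) {
    data.frame(day = s$observations$day, indicator = s$name,
               value = s$observations$value, units = s$units,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read indicator series from CSV
#'
#' @param path CSV with columns `day,indicator,value,units`.
#' @return named list of [indicator_series].
#' @export
read_indicators <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "indicator", "value", "units")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("indicator CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$indicator), function(sub) {
    sub <- sub[order(sub$day), ]
    indicator_series(sub$indicator[1], sub$units[1], sub$day, sub$value)
  })
  out[unique(df$indicator)]
}
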