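#!/usr/bin/env Rscript
# Stage 4: spoilage indicators. Fit each simulated indicator against storage
# day, detect acceptability-limit crossings (on observations and on the
# fitted lines), grade putrescine levels, and correlate everything with the
# panel quality index.

suppressPackageStartupMessages(library(qimshelf))

protocol <- king_weakfish_protocol()
panel <- aggregate_panel(read_scoresheets("results/scoresheets.csv"), protocol)
indicators <- read_indicators("results/indicators.csv")
limits <- kw_limit_rules()

crossings <- list()
for (nm in names(limits)) {
  s <- indicators[[nm]]
  if (is.null(s)) next
  fit <- fit_line(s$observations$day, s$observations$value)
  d_obs <- first_crossing_day(s, limits[[nm]])
  d_fit <- crossing_day_continuous(fit, limits[[nm]])
  crossings[[nm]] <- list(threshold = limits[[nm]]$threshold,
                          observed_day = d_obs, fitted_day = d_fit,
                          slope = fit$slope, intercept = fit$intercept,
                          r_squared = fit$r_squared)
  cat(sprintf("%-14s limit %g %s: observed crossing %s, fitted crossing %s\n",
              nm, limits[[nm]]$threshold, limits[[nm]]$units,
              format(d_obs), format(round(d_fit, 2))))
}

put <- indicators$putrescine$observations
cat("putrescine quality classes by day:\n")
print(data.frame(day = put$day, mg_kg = round(put$value, 2),
                 class = classify_amine(put$value)), row.names = FALSE)

cm <- correlation_matrix(panel, indicators)
cat("correlation of indicators with the panel QI:\n")
print(round(cm["qi", ], 3))

jsonlite::write_json(list(crossings = crossings,
                          putrescine_classes = classify_amine(put$value),
                          correlations_with_qi = as.list(cm["qi", ])),
                     "results/indicator_rules.json",
                     auto_unbox = TRUE, digits = NA)
write.csv(round(cm, 4), "results/correlation_matrix.csv")
cat("-> results/indicator_rules.json, results/correlation_matrix.csv\n")
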