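#!/usr/bin/env Rscript
# Stage 2: aggregate the panel score sheets into per-day quality indices and
# calibrate QI against days in ice; demonstrate inverse prediction (days in
# ice from an observed QI) and the remaining-shelf-life readout.

suppressPackageStartupMessages(library(qimshelf))

protocol <- king_weakfish_protocol()
assessments <- read_scoresheets("results/scoresheets.csv")
panel <- aggregate_panel(assessments, protocol)
print(panel)

fit <- fit_line(panel$summary$storage_day, panel$summary$qi_mean)
print(fit)
cat(sprintf("generating line was QI = %.4f x day + %.4f\n",
            0.9281, 1.3378))

pred <- sep(panel$summary$qi_mean,
            predict_line(fit, panel$summary$storage_day))
cat(sprintf("prediction errors: RMSEP %.3f, bias %.3f, corrected SEP %.3f\n",
            pred$rmsep, pred$bias, pred$sep_corrected))

qi_obs <- 12
est <- inverse_predict(fit, qi_obs)
cat(sprintf("a fish scoring QI %d is estimated at %.1f days in ice (%.0f%% CI %.1f-%.1f)\n",
            qi_obs, est$point, 100 * est$confidence, est$lower, est$upper))
cat(sprintf("remaining shelf-life at QI %d with an 11-day limit: %.1f days\n",
            qi_obs, remaining_shelf_life(fit, qi_obs, 11)))

out <- data.frame(panel$summary,
                  qi_fitted = predict_line(fit, panel$summary$storage_day))
write.csv(out, "results/panel_qi.csv", row.names = FALSE)
jsonlite::write_json(list(slope = fit$slope, intercept = fit$intercept,
                          r_squared = fit$r_squared,
                          residual_sd = fit$residual_sd, n = fit$n,
                          sep = pred),
                     "results/calibration.json", auto_unbox = TRUE, digits = NA)
cat("-> results/panel_qi.csv, results/calibration.json\n")
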