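#!/usr/bin/env Rscript
# Stage 3: regress storage day on the 13 per-parameter mean demerits with
# PLS1 (NIPALS), pick the component count by leave-one-out cross-validation,
# and rank the sensory attributes by VIP (importance threshold 1.0).

suppressPackageStartupMessages(library(qimshelf))

protocol <- king_weakfish_protocol()
panel <- aggregate_panel(read_scoresheets("results/scoresheets.csv"), protocol)
X <- as.matrix(panel$parameter_means[, -1])
y <- panel$parameter_means$storage_day

cv <- loo_cv_pls(X, y, ncomp_max = min(3, nrow(X) - 2))
cat("LOO RMSECV by component count:", round(cv$rmsecv, 3),
    "-> choosing", cv$chosen_ncomp, "\n")

model <- fit_pls1(X, y, ncomp = cv$chosen_ncomp)
print(model)
err <- sep(y, predict(model, X))
cat(sprintf("training prediction error (days): RMSEP %.3f, corrected SEP %.3f\n",
            err$rmsep, err$sep_corrected))

vip <- vip_scores(model)
print(vip)
cat("attributes above the VIP threshold:",
    paste(vip$selected, collapse = ", "), "\n")

groups <- protocol_parameters(protocol)
jsonlite::write_json(list(
  chosen_ncomp = cv$chosen_ncomp,
  rmsecv = cv$rmsecv,
  sep = err,
  vip = as.list(vip$vip),
  selected = vip$selected,
  group_of = as.list(setNames(groups$group, groups$parameter))),
  "results/pls_vip.json", auto_unbox = TRUE, digits = NA)
cat("-> results/pls_vip.json\n")
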