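#!/usr/bin/env Rscript
# Stage 1: generate a synthetic ice-storage study with the reference design
# (6 sampling days, 4 referees x 3 fish/day, lot-4 QI trajectory, log-linear
# microbial growth, linear TVB-N/TBARS, near-exponential putrescine) and
# write the raw tables that the later stages consume.

suppressPackageStartupMessages(library(qimshelf))
dir.create("results", showWarnings = FALSE)

seed <- as.integer(Sys.getenv("QIMSHELF_SEED", "1"))
protocol <- king_weakfish_protocol()
cfg <- sim_config(seed = seed)
print(cfg)

study <- simulate_study(cfg, protocol)
write_scoresheets(study$assessments, "results/scoresheets.csv")
write_indicators(study$indicators, "results/indicators.csv")

n_sheets <- nrow(unique(study$assessments[c("fish_id", "referee_id",
                                            "storage_day")]))
cat(sprintf("wrote %d score sheets (%d rows) and %d indicator series\n",
            n_sheets, nrow(study$assessments), length(study$indicators)))
cat("-> results/scoresheets.csv, results/indicators.csv\n")
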