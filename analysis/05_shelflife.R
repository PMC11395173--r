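#!/usr/bin/env Rscript
# Stage 5: integrate sensory rejection (panel mean QI at the protocol
# maximum) with the indicator limit crossings into a shelf-life decision and
# write the full machine- and human-readable study report.

suppressPackageStartupMessages(library(qimshelf))

protocol <- king_weakfish_protocol()
assessments <- read_scoresheets("results/scoresheets.csv")
indicators <- read_indicators("results/indicators.csv")

report <- build_report(assessments, indicators, protocol)
write_report(report, json_path = "results/report.json",
             md_path = "results/report.md")

cat(sprintf("first rejection day: %s\n",
            format(report$shelf_life$first_rejection_day)))
cat(sprintf("integrated shelf-life: %s days (%s)\n",
            format(report$shelf_life$shelf_life_days),
            report$shelf_life$status))
for (f in report$shelf_life$findings)
  cat(sprintf("  - %-16s day %-4s %s\n", f$criterion,
              format(f$rejection_day), f$evidence))
cat("-> results/report.json, results/report.md\n")
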