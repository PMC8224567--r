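#!/usr/bin/env Rscript
# Scoliotic affection analysis: per-segment affected/unaffected bookkeeping
# from the stable-vertebra levels, and the patient-only mixed model of NP gag
# scores by affection status. Writes the affection table under results/.

suppressMessages(library(gagcest))

records <- read.csv("results/disc_records.csv")
metadata <- read.csv("results/cohort_metadata.csv")

sv <- metadata$stable_vertebra[metadata$cohort == "AIS"]
tab <- affection_table(sv)
cat("Affected discs per segment (patients):\n")
print(tab$per_segment)
cat(sprintf("Total: %d of %d patient discs affected (%.0f%%)\n",
            tab$total, tab$n_discs, tab$percent))

aff <- affection_report(records)
cat("\nAffection x segment corrected NP means (patients only):\n")
print(aff$table, row.names = FALSE)
cat(sprintf("affected vs unaffected contrast p = %.3f\n", aff$p_overall))

write.csv(aff$table, "results/affection_table.csv", row.names = FALSE)
jsonlite::write_json(list(per_segment = as.list(tab$per_segment),
                          total = tab$total, percent = tab$percent,
                          p_overall = aff$p_overall),
                     "results/affection_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Wrote results/affection_table.csv and results/affection_summary.json\n")
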