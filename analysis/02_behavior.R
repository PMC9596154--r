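#!/usr/bin/env Rscript

# Step 2 — descriptive behavioral metrics.
#
# Computes per-subject helping percentages (overall, by imminence, by
# imminence x threat level), the signed imminent-minus-distal helping
# difference, and the three-way imminence-preference classification of the
# cohort. Writes helping_summary.tsv and imminence_classification.tsv.

suppressPackageStartupMessages(library(threatRSA))

dir <- file.path("results", "pipeline")
schedule <- read_table_tsv(file.path(dir, "schedule.tsv"))
decisions <- read_table_tsv(file.path(dir, "decisions.tsv"))

summary <- helping_summary(decisions, schedule)
by_cell <- helping_percentage(decisions, schedule, "imminence_level")
classification <- classify_imminence_preference(summary)

write_table_tsv(summary, file.path(dir, "helping_summary.tsv"))
write_table_tsv(by_cell, file.path(dir, "helping_by_cell.tsv"))
write_table_tsv(classification, file.path(dir, "imminence_classification.tsv"))

log_message(sprintf("Mean helping: %.1f%% (SD %.1f) across %d subjects.",
                mean(summary$helping_pct_overall),
                sd(summary$helping_pct_overall), nrow(summary)))
log_message(paste(sprintf("%s: %d", classification$imminence_class,
                      classification$n), collapse = "; "))
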