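#!/usr/bin/env Rscript

# Step 5 — human-readable report.
#
# Regenerates the summary report from the saved tables (idempotent): the
# per-ROI coefficient tables, the FDR-surviving list, the imminence
# classification, the predominance table, and the configuration echo.

suppressPackageStartupMessages(library(threatRSA))

dir <- file.path("results", "pipeline")
models <- read_table_tsv(file.path(dir, "roi_models.tsv"))
similarity <- read_table_tsv(file.path(dir, "similarity.tsv"))
pred <- read_table_tsv(file.path(dir, "predominance.tsv"))
classification <- read_table_tsv(file.path(dir,
                                           "imminence_classification.tsv"))
cfg <- read_pipeline_config(file.path(dir, "config_echo.yaml"))

rsa <- list(models = models, similarity = similarity,
            fdr_pool_size = sum(!is.na(models$p_fdr)),
            alpha = cfg$alpha, variant = cfg$tau_variant)
report <- render_report(rsa, classification = classification,
                        predominance = pred, config = cfg)
writeLines(report, file.path(dir, "report.txt"))
log_message(sprintf("Wrote %s", file.path(dir, "report.txt")))
log_message(paste(utils::head(report, 12), collapse = "\n"))
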