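#!/usr/bin/env Rscript

# Step 4 — second-order similarity and ROI-level inference.
#
# Computes Kendall's tau between each neural RDM and the threat / distress
# behavioral RDMs (per subject, ROI and imminence condition), fits one
# linear model per ROI predicting overall helping percentage from the two
# similarities plus imminence, applies Benjamini-Hochberg FDR across the
# slope p-values of all models, and runs the paired threat-vs-distress
# predominance comparison. Writes similarity.tsv, roi_models.tsv and
# predominance.tsv.

suppressPackageStartupMessages(library(threatRSA))

dir <- file.path("results", "pipeline")
schedule <- read_table_tsv(file.path(dir, "schedule.tsv"))
decisions <- read_table_tsv(file.path(dir, "decisions.tsv"))
ratings <- list(distress = read_table_tsv(file.path(dir,
                                                    "ratings_distress.tsv")),
                threat = read_table_tsv(file.path(dir, "ratings_threat.tsv")))
cfg <- read_pipeline_config(file.path(dir, "config_echo.yaml"))

subjects <- sort(unique(schedule$subject_id))
patterns <- lapply(subjects, function(s) {
  sapply(cfg$roi_list, function(roi) read_beta_matrix(dir, s, roi),
         simplify = FALSE)
})
names(patterns) <- as.character(subjects)

rsa <- run_rsa(patterns, schedule, ratings, decisions,
               roi_list = cfg$roi_list, variant = cfg$tau_variant,
               alpha = cfg$alpha)
pred <- predominance_test(rsa$similarity, alpha = cfg$alpha)

write_table_tsv(rsa$similarity, file.path(dir, "similarity.tsv"))
write_table_tsv(rsa$models, file.path(dir, "roi_models.tsv"))
write_table_tsv(pred, file.path(dir, "predominance.tsv"))

sig <- rsa$models[!is.na(rsa$models$significant) & rsa$models$significant, ]
log_message(sprintf("%d models fitted; FDR pool of %d p-values; %d coefficient(s) significant.",
                length(unique(rsa$models$roi)), rsa$fdr_pool_size, nrow(sig)))
if (nrow(sig)) {
  log_message(paste(sprintf("  %s / %s: beta = %.2f, p_fdr = %.4g", sig$roi,
                        sig$term, sig$beta, sig$p_fdr), collapse = "\n"))
}
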