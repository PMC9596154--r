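#!/usr/bin/env Rscript

# Step 1 — simulate a complete helping-under-threat experiment.
#
# Reads the pipeline configuration, simulates the cohort (schedules,
# post-scan ratings, ROI voxel patterns with planted geometry, decisions,
# outcomes), and writes every table plus one beta matrix per (subject, ROI)
# under results/pipeline/. The configuration is echoed alongside for
# provenance. Later steps consume only these files.

suppressPackageStartupMessages(library(threatRSA))

cfg_path <- commandArgs(trailingOnly = TRUE)
if (!length(cfg_path)) {
  cfg_path <- system.file("extdata", "default_config.yaml",
                          package = "threatRSA")
}
cfg <- read_pipeline_config(cfg_path)
out_dir <- file.path("results", "pipeline")

log_message(sprintf("Simulating %d subjects x %d ROIs (seed %d) ...",
                cfg$n_subjects, length(cfg$roi_list), cfg$seed))
cohort <- simulate_cohort(design = cfg$design, n_subjects = cfg$n_subjects,
                          rating_params = cfg$ratings,
                          neural_params = cfg$neural,
                          decision_params = cfg$decision,
                          seed = cfg$seed)
write_cohort(cohort, out_dir)
echo_config(cfg, out_dir)

n_shock <- sum(cohort$schedule$level != "safe")
n_help <- sum(cohort$decisions$response == "help")
log_message(sprintf("Wrote %s: %d trials (%d shock), %d help decisions (%.1f%% of shock trials).",
                out_dir, nrow(cohort$schedule), n_shock, n_help,
                100 * n_help / n_shock))
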