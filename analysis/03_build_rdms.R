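#!/usr/bin/env Rscript

# Step 3 — representational dissimilarity matrices.
#
# For every subject, ROI and imminence condition, builds the neural RDM
# (1 - Pearson r between trial-wise voxel patterns) and, per subject and
# condition, the behavioral threat and distress RDMs (Euclidean distances
# on the post-scan ratings). RDMs are written as labelled square tables
# with JSON sidecars under results/pipeline/rdms/. This step is purely
# illustrative persistence: step 4 recomputes RDMs in memory from the beta
# matrices, which is faster than re-reading thousands of files.
#
# To keep the output tree small this driver writes the RDMs of the first
# N_PERSIST subjects (default 3); pass a number to persist more.

suppressPackageStartupMessages(library(threatRSA))

args <- commandArgs(trailingOnly = TRUE)
n_persist <- if (length(args)) as.integer(args[1]) else 3L

dir <- file.path("results", "pipeline")
rdm_dir <- file.path(dir, "rdms")
dir.create(rdm_dir, showWarnings = FALSE, recursive = TRUE)

schedule <- read_table_tsv(file.path(dir, "schedule.tsv"))
distress <- read_table_tsv(file.path(dir, "ratings_distress.tsv"))
threat <- read_table_tsv(file.path(dir, "ratings_threat.tsv"))
cfg <- read_pipeline_config(file.path(dir, "config_echo.yaml"))

subjects <- head(sort(unique(schedule$subject_id)), n_persist)
n_files <- 0L
for (s in subjects) {
  rows_s <- schedule[schedule$subject_id == s, ]
  for (cond in c("distal", "imminent")) {
    rows <- rows_s[rows_s$imminence == cond, ]
    ids <- as.character(rows$global_trial_id)
    dis_s <- distress[distress$subject_id == s, ]
    dis_rdm <- rating_rdm(dis_s$distress_rating[
      match(rows$global_trial_id, dis_s$global_trial_id)], ids,
      condition = cond, source = "distress")
    thr <- trial_threat_ratings(rows, threat[threat$subject_id == s, ])
    thr_rdm <- rating_rdm(thr$threat_rating[
      match(rows$global_trial_id, thr$global_trial_id)], ids,
      condition = cond, source = "threat")
    write_rdm(dis_rdm, file.path(rdm_dir, sprintf(
      "sub-%02d_model-distress_cond-%s_rdm.tsv", s, cond)))
    write_rdm(thr_rdm, file.path(rdm_dir, sprintf(
      "sub-%02d_model-threat_cond-%s_rdm.tsv", s, cond)))
    n_files <- n_files + 2L
    for (roi in cfg$roi_list) {
      mat <- read_beta_matrix(dir, s, roi)
      nr <- neural_rdm(mat[ids, , drop = FALSE], condition = cond,
                       source = roi)
      write_rdm(nr, file.path(rdm_dir, sprintf(
        "sub-%02d_roi-%s_cond-%s_rdm.tsv", s, roi, cond)))
      n_files <- n_files + 1L
    }
  }
}
log_message(sprintf("Wrote %d RDM files for %d subject(s) to %s.",
                n_files, length(subjects), rdm_dir))
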