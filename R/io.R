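#' Read and write pipeline tables
#'
#' All tables are tab-separated UTF-8 text with a header row and "."
#' decimal marks. Numeric values are written with R's default 15
#' significant digits, so a write -> read -> write cycle is byte-identical.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a data frame.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write or read one beta pattern matrix
#'
#' One file per (subject, ROI), named `sub-<id>_roi-<name>_betas.tsv`, with
#' a header row of voxel ids and one row per trial keyed by
#' `global_trial_id`.
#'
#' @param mat Trials-by-voxels matrix with trial-id row names and voxel-id
#'   column names.
#' @param dir Output directory.
#' @param subject_id,roi Identify the file.
#' @return The file path (written or read from); `read_beta_matrix`
#'   returns the matrix.
#' @export
write_beta_matrix <- function(mat, dir, subject_id, roi) {
  path <- file.path(dir, sprintf("sub-%02d_roi-%s_betas.tsv",
                                 as.integer(subject_id), roi))
  df <- data.frame(global_trial_id = rownames(mat), mat,
                   check.names = FALSE)
  write_table_tsv(df, path)
  path
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(dir, subject_id, roi) {
  path <- file.path(dir, sprintf("sub-%02d_roi-%s_betas.tsv",
                                 as.integer(subject_id), roi))
  df <- read_table_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$global_trial_id)
  mat
}

#' Serialize an RDM with labels and sidecar metadata
#'
#' The matrix is written as a delimited square table with trial-id header
#' row and label column; a JSON sidecar (`<path>.json`) records the kind,
#' condition and source.
#'
#' @param rdm An [new_rdm()] object.
#' @param path File path for the matrix (sidecar gets `.json` appended).
#' @return `write_rdm` returns `path` invisibly; `read_rdm` returns the
#'   reconstructed `rdm` object.
#' @export
write_rdm <- function(rdm, path) {
  df <- data.frame(trial_id = rownames(rdm), unclass(rdm),
                   check.names = FALSE)
  write_table_tsv(df, path)
  meta <- list(kind = attr(rdm, "kind"), condition = attr(rdm, "condition"),
               source = attr(rdm, "source"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- read_table_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  ids <- as.character(df$trial_id)
  dimnames(mat) <- list(ids, ids)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_rdm(mat, kind = meta$kind,
          condition = if (is.null(meta$condition)) NA_character_ else
            meta$condition,
          source = if (is.null(meta$source)) NA_character_ else meta$source)
}

#' Write all tables of a simulated cohort to a directory
#'
#' Writes `schedule.tsv`, `decisions.tsv`, `outcomes.tsv`,
#' `ratings_distress.tsv`, `ratings_threat.tsv` and one
#' `sub-<id>_roi-<name>_betas.tsv` per (subject, ROI).
#'
#' @param cohort A `threat_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table_tsv(cohort$schedule, file.path(dir, "schedule.tsv"))
  write_table_tsv(cohort$decisions, file.path(dir, "decisions.tsv"))
  write_table_tsv(cohort$outcomes, file.path(dir, "outcomes.tsv"))
  write_table_tsv(cohort$ratings$distress,
                  file.path(dir, "ratings_distress.tsv"))
  write_table_tsv(cohort$ratings$threat,
                  file.path(dir, "ratings_threat.tsv"))
  for (s in names(cohort$patterns)) {
    for (roi in names(cohort$patterns[[s]])) {
      write_beta_matrix(cohort$patterns[[s]][[roi]], dir,
                        as.integer(s), roi)
    }
  }
  invisible(dir)
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with nested sections: `paths`, `design`
#' (task design fields), `ratings`, `neural`, `decision` (generator
#' parameters), plus top-level `roi_list`, `tau_variant`, `alpha`,
#' `n_subjects` and the master `seed`.
#'
#' @param path YAML file path.
#' @return A validated list of class `pipeline_config` with parameter
#'   objects materialized (`design`, `ratings`, `neural`, `decision`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must provide a master seed")
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(cfg$roi_list) || !length(cfg$roi_list)) {
    stop("config must provide a non-empty roi_list")
  }
  if (is.null(cfg$tau_variant)) cfg$tau_variant <- "tau_a"
  if (is.null(cfg$n_subjects)) cfg$n_subjects <- 49L
  cfg$design <- do.call(task_design, as.list(cfg$design))
  cfg$ratings <- do.call(rating_params, as.list(cfg$ratings))
  neural_args <- as.list(cfg$neural)
  neural_args$rois <- unlist(cfg$roi_list)
  cfg$neural <- do.call(neural_params, neural_args)
  cfg$decision <- do.call(decision_params, as.list(cfg$decision))
  cfg$roi_list <- unlist(cfg$roi_list)
  structure(cfg, class = "pipeline_config")
}

#' Echo a configuration into an output directory for provenance
#'
#' @param config A `pipeline_config`.
#' @param dir Output directory.
#' @return The echoed file path, invisibly.
#' @export
echo_config <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- file.path(dir, "config_echo.yaml")
  plain <- lapply(unclass(config), function(x) {
    if (is.object(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, out)
  invisible(out)
}

#' Timestamped log message to standard error
#'
#' @param ... Passed to [sprintf()] when more than one argument is given,
#'   otherwise emitted as is.
#' @return Invisibly, the formatted line.
#' @export
log_message <- function(...) {
  args <- list(...)
  msg <- if (length(args) > 1) do.call(sprintf, args) else as.character(args[[1]])
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  invisible(line)
}
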