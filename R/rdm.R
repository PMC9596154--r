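#' Representational dissimilarity matrices
#'
#' An `rdm` is a labelled symmetric trial-by-trial dissimilarity matrix with
#' a zero diagonal. Neural RDMs hold `1 - Pearson r` between the voxel
#' vectors of trial pairs (entries in \[0, 2\]); behavioral RDMs hold the
#' Euclidean distance between scalar ratings of trial pairs (entries >= 0).
#'
#' @param mat Square numeric matrix with trial-id dimnames.
#' @param kind `"neural_1_minus_r"` or `"rating_euclidean"`.
#' @param condition Optional imminence condition label.
#' @param source ROI name or rating family the RDM derives from.
#' @return An object of class `rdm` (a matrix with metadata attributes).
#' @export
new_rdm <- function(mat, kind = c("neural_1_minus_r", "rating_euclidean"),
                    condition = NA_character_, source = NA_character_) {
  kind <- match.arg(kind)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) stop("mat must be square")
  if (is.null(rownames(mat))) stop("mat must carry trial-id dimnames")
  if (max(abs(mat - t(mat))) > 1e-10) stop("mat must be symmetric")
  if (any(diag(mat) != 0)) stop("diagonal must be zero")
  structure(mat, class = c("rdm", class(mat)),
            kind = kind, condition = condition, source = source)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %s | condition: %s | source: %s | %d trials\n",
              attr(x, "kind"), attr(x, "condition"), attr(x, "source"),
              nrow(x)))
  invisible(x)
}

#' Neural RDM from a trials-by-voxels pattern matrix
#'
#' Entry (i, j) is `1 - Pearson r` between the voxel vectors of trials i
#' and j, the standard correlation-distance representational dissimilarity.
#'
#' @param patterns Numeric matrix, trials in rows (row names are trial ids),
#'   voxels in columns; at least 3 trials and 2 voxels.
#' @param condition,source Metadata labels stored on the result.
#' @return An [new_rdm()] object of kind `neural_1_minus_r`.
#' @export
neural_rdm <- function(patterns, condition = NA_character_,
                       source = NA_character_) {
  if (!is.matrix(patterns)) patterns <- as.matrix(patterns)
  if (nrow(patterns) < 3) stop("need at least 3 trials")
  if (ncol(patterns) < 2) stop("need at least 2 voxels")
  if (anyNA(patterns)) stop("pattern matrix contains missing values")
  ids <- rownames(patterns)
  if (is.null(ids)) stop("pattern matrix must carry trial ids as row names")
  # correlation distances computed in C++ (equivalent to 1 - cor(t(m)),
  # clamped to [0, 2]); degenerate rows come back as indices to name
  res <- one_minus_r_cpp(patterns)
  if (length(res$bad)) {
    stop("degenerate trial(s) with constant voxel vector: ",
         paste(ids[res$bad], collapse = ", "))
  }
  d <- res$rdm
  dimnames(d) <- list(ids, ids)
  # invariants hold by construction (tcrossprod output is exactly
  # symmetric), so skip the constructor's re-validation
  structure(d, class = c("rdm", class(d)), kind = "neural_1_minus_r",
            condition = condition, source = source)
}

#' Behavioral RDM from per-trial scalar ratings
#'
#' Entry (i, j) is the Euclidean distance between the scalar ratings of
#' trials i and j, i.e. the absolute rating difference.
#'
#' @param ratings Numeric vector of per-trial ratings.
#' @param trial_ids Trial ids aligned with `ratings`.
#' @param condition,source Metadata labels stored on the result.
#' @return An [new_rdm()] object of kind `rating_euclidean`.
#' @export
rating_rdm <- function(ratings, trial_ids, condition = NA_character_,
                       source = NA_character_) {
  if (length(ratings) != length(trial_ids)) {
    stop("ratings and trial_ids must have equal length")
  }
  if (anyNA(ratings)) {
    stop("missing rating for trial(s): ",
         paste(trial_ids[is.na(ratings)], collapse = ", "))
  }
  d <- abs(outer(as.numeric(ratings), as.numeric(ratings), "-"))
  ids <- as.character(trial_ids)
  dimnames(d) <- list(ids, ids)
  new_rdm(d, "rating_euclidean", condition = condition, source = source)
}

#' Map each trial to its subject's felt-threat cue rating
#'
#' Each trial is assigned the subject's post-scan rating of that trial's
#' threat cue (the level-by-imminence cue image), producing the per-trial
#' scalars that feed the threat RDM.
#'
#' @param schedule Trial schedule (possibly filtered to one condition).
#' @param threat Threat-cue rating table (columns `subject_id`, `imminence`,
#'   `level`, `threat_rating`).
#' @param condition Optional imminence condition to filter the schedule to.
#' @return Data frame with `subject_id`, `global_trial_id`, `threat_rating`.
#' @export
trial_threat_ratings <- function(schedule, threat, condition = NULL) {
  if (!is.null(condition)) {
    schedule <- schedule[schedule$imminence == condition, , drop = FALSE]
  }
  key_s <- paste(schedule$subject_id, schedule$imminence, schedule$level)
  key_t <- paste(threat$subject_id, threat$imminence, threat$level)
  m <- match(key_s, key_t)
  if (anyNA(m)) {
    bad <- unique(key_s[is.na(m)])
    stop("missing threat-cue rating for: ", paste(bad, collapse = "; "))
  }
  data.frame(subject_id = schedule$subject_id,
             global_trial_id = schedule$global_trial_id,
             threat_rating = threat$threat_rating[m])
}

#' Split a schedule (and aligned tables) by threat imminence
#'
#' The RSA is run separately for distal and imminent trials; this partitions
#' the trials by the imminence factor. The partitions are disjoint and their
#' union is the input.
#'
#' @param schedule Trial schedule.
#' @param ... Optional further data frames with a `global_trial_id` column
#'   (and `subject_id`), each split by the same partition.
#' @return Named list with elements `distal` and `imminent`; each is the
#'   filtered schedule, or (when tables are supplied) a list of filtered
#'   tables named `schedule` plus the names of `...`.
#' @export
split_by_condition <- function(schedule, ...) {
  extra <- list(...)
  conds <- c("distal", "imminent")
  out <- lapply(conds, function(cc) {
    sub <- schedule[schedule$imminence == cc, , drop = FALSE]
    if (!length(extra)) return(sub)
    key <- paste(sub$subject_id, sub$global_trial_id)
    tabs <- lapply(extra, function(tb) {
      tb[paste(tb$subject_id, tb$global_trial_id) %in% key, , drop = FALSE]
    })
    c(list(schedule = sub), tabs)
  })
  names(out) <- conds
  out
}
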