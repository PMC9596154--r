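#' Helping percentage by condition
#'
#' Helping is only defined on responded shock trials: the denominator is
#' help + no_help decisions, excluding safe trials and missed responses.
#' Groups with no eligible trials yield `NA` (explicitly undefined), never
#' zero.
#'
#' @param decisions Decision set (columns `subject_id`, `global_trial_id`,
#'   `response`).
#' @param schedule Trial schedule covering the same trials.
#' @param grouping One of `"overall"`, `"imminence"`, `"imminence_level"`.
#' @return Data frame with one row per subject (and group), columns
#'   `n_help`, `n_nohelp`, `helping_pct`.
#' @export
helping_percentage <- function(decisions, schedule,
                               grouping = c("overall", "imminence",
                                            "imminence_level")) {
  grouping <- match.arg(grouping)
  key_s <- paste(schedule$subject_id, schedule$global_trial_id)
  key_d <- paste(decisions$subject_id, decisions$global_trial_id)
  m <- match(key_d, key_s)
  if (anyNA(m)) stop("decisions refer to trials absent from the schedule")
  df <- data.frame(subject_id = decisions$subject_id,
                   response = decisions$response,
                   imminence = schedule$imminence[m],
                   level = schedule$level[m],
                   stringsAsFactors = FALSE)
  eligible <- df$level != "safe" & df$response %in% c("help", "no_help")
  group_cols <- switch(grouping,
                       overall = "subject_id",
                       imminence = c("subject_id", "imminence"),
                       imminence_level = c("subject_id", "imminence", "level"))
  # enumerate all groups so empty cells appear as undefined, not dropped
  shock_levels <- setdiff(unique(schedule$level), "safe")
  grid <- switch(grouping,
    overall = data.frame(subject_id = sort(unique(schedule$subject_id))),
    imminence = expand.grid(subject_id = sort(unique(schedule$subject_id)),
                            imminence = c("distal", "imminent"),
                            stringsAsFactors = FALSE),
    imminence_level = expand.grid(
      subject_id = sort(unique(schedule$subject_id)),
      imminence = c("distal", "imminent"),
      level = shock_levels, stringsAsFactors = FALSE))
  sub <- df[eligible, , drop = FALSE]
  count_in <- function(resp) {
    if (!nrow(sub)) return(rep(0L, nrow(grid)))
    hit <- sub[sub$response == resp, group_cols, drop = FALSE]
    key_g <- do.call(paste, grid[group_cols])
    key_h <- do.call(paste, hit)
    as.integer(table(factor(key_h, levels = key_g)))
  }
  grid$n_help <- count_in("help")
  grid$n_nohelp <- count_in("no_help")
  denom <- grid$n_help + grid$n_nohelp
  grid$helping_pct <- ifelse(denom > 0, 100 * grid$n_help / denom, NA_real_)
  rownames(grid) <- NULL
  grid
}

#' Per-subject helping summary with imminence preference
#'
#' Combines the overall helping percentage with the per-imminence
#' percentages, the signed proportion difference (imminent minus distal,
#' computed on proportions so unequal missed-response counts cannot bias the
#' sign), and a three-way classification of each subject.
#'
#' @inheritParams helping_percentage
#' @return Data frame with one row per subject: `helping_pct_overall`,
#'   `helping_pct_distal`, `helping_pct_imminent`,
#'   `delta_imminent_minus_distal` (proportion difference in \[-1, 1\]), and
#'   `imminence_class` in more_imminent / more_distal / equal.
#' @export
helping_summary <- function(decisions, schedule) {
  overall <- helping_percentage(decisions, schedule, "overall")
  by_imm <- helping_percentage(decisions, schedule, "imminence")
  dist <- by_imm[by_imm$imminence == "distal", ]
  imm <- by_imm[by_imm$imminence == "imminent", ]
  out <- data.frame(subject_id = overall$subject_id,
                    helping_pct_overall = overall$helping_pct)
  out$helping_pct_distal <-
    dist$helping_pct[match(out$subject_id, dist$subject_id)]
  out$helping_pct_imminent <-
    imm$helping_pct[match(out$subject_id, imm$subject_id)]
  out$delta_imminent_minus_distal <-
    (out$helping_pct_imminent - out$helping_pct_distal) / 100
  d <- out$delta_imminent_minus_distal
  out$imminence_class <- ifelse(is.na(d), NA_character_,
                                ifelse(d > 0, "more_imminent",
                                       ifelse(d < 0, "more_distal", "equal")))
  out
}

#' Classify subjects by imminence preference
#'
#' Counts how many subjects helped more under imminent threat, more under
#' distal threat, or the same amount (exact zero difference).
#'
#' @param summary Data frame from [helping_summary()], one row per subject.
#' @return Data frame with columns `imminence_class` and `n`, one row per
#'   class (zeros included); counts sum to the number of classified
#'   subjects.
#' @export
classify_imminence_preference <- function(summary) {
  if (anyDuplicated(summary$subject_id)) {
    stop("summary must contain one row per subject")
  }
  classes <- c("more_imminent", "more_distal", "equal")
  tab <- table(factor(summary$imminence_class, levels = classes))
  data.frame(imminence_class = classes, n = as.integer(tab))
}
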