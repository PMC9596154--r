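#' Parameters of the post-scan rating generator
#'
#' Ratings are generated as latent Gaussian values (baseline + condition
#' effects + noise) rounded to the nearest integer and clipped to the
#' 9-point scale. Two families are produced: per-trial distress ratings of
#' the co-participant (one unique clip per trial) and per-cue felt-threat
#' ratings (one rating per level-by-imminence cue image). Default condition
#' effects follow the manipulation-check structure of the scanned cohort:
#' distress is higher for imminent clips and increases with threat level;
#' felt threat increases steeply with level, with an imminence increment for
#' shock cues only.
#'
#' @param distress_baseline Latent mean distress of a distal safe clip.
#' @param distress_imminence Additive imminence effect on distress.
#' @param distress_level Named additive level effects on distress.
#' @param distress_noise_sd Latent noise SD for distress ratings.
#' @param threat_baseline Latent mean felt threat of a distal safe cue.
#' @param threat_level Named additive level effects on felt threat.
#' @param threat_imminence Additive imminence effect on felt threat.
#' @param threat_imminence_shock_only If `TRUE` (default) the imminence
#'   increment applies only to shock cues, not to safe cues.
#' @param threat_noise_sd Latent noise SD for felt-threat ratings.
#' @return An object of class `rating_params`.
#' @export
rating_params <- function(distress_baseline = 3.5,
                          distress_imminence = 0.418,
                          distress_level = c(safe = 0, "1shock" = 0.279,
                                             "2shocks" = 0.559),
                          distress_noise_sd = 1.5,
                          threat_baseline = 2,
                          threat_level = c(safe = 0, "1shock" = 2.255,
                                           "2shocks" = 3.92),
                          threat_imminence = 0.9,
                          threat_imminence_shock_only = TRUE,
                          threat_noise_sd = 1,
                          ...) {
  extra <- list(...)
  if (length(extra)) stop("unknown rating parameters: ",
                          paste(names(extra), collapse = ", "))
  # accept plain named lists (e.g. parsed from YAML) as level effects
  distress_level <- unlist(distress_level)
  threat_level <- unlist(threat_level)
  p <- list(distress_baseline = distress_baseline,
            distress_imminence = distress_imminence,
            distress_level = distress_level,
            distress_noise_sd = distress_noise_sd,
            threat_baseline = threat_baseline,
            threat_level = threat_level,
            threat_imminence = threat_imminence,
            threat_imminence_shock_only = isTRUE(threat_imminence_shock_only),
            threat_noise_sd = threat_noise_sd)
  missing <- names(p)[vapply(p, function(x) is.null(x) || anyNA(x), logical(1))]
  if (length(missing)) stop("missing rating parameters: ",
                            paste(missing, collapse = ", "))
  structure(p, class = "rating_params")
}

clip_rating <- function(x) pmin(pmax(round(x), 1), 9)

#' Generate post-scan distress and felt-threat ratings
#'
#' @param schedule Trial schedule from [generate_schedule()].
#' @param params A [rating_params()] object.
#' @param seed Integer master seed; each subject draws from its own stream.
#' @return A list with two data frames: `distress` (one integer rating in
#'   1--9 per scheduled trial) and `threat` (one rating per subject for each
#'   of the level-by-imminence cue images).
#' @export
generate_ratings <- function(schedule, params = rating_params(), seed = 1L) {
  if (!inherits(params, "rating_params")) {
    stop("params must be created with rating_params()")
  }
  levels_seen <- unique(schedule$level)
  missing_lv <- setdiff(levels_seen, names(params$distress_level))
  if (length(missing_lv)) {
    stop("missing distress level effect for: ", paste(missing_lv, collapse = ", "))
  }
  missing_lv <- setdiff(levels_seen, names(params$threat_level))
  if (length(missing_lv)) {
    stop("missing threat level effect for: ", paste(missing_lv, collapse = ", "))
  }
  subjects <- sort(unique(schedule$subject_id))
  distress <- vector("list", length(subjects))
  threat <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    rows <- schedule[schedule$subject_id == s, , drop = FALSE]
    res <- with_local_seed(derive_seed(seed, 2L, s), {
      imm <- as.numeric(rows$imminence == "imminent")
      mu_d <- params$distress_baseline +
        params$distress_imminence * imm +
        unname(params$distress_level[rows$level])
      d <- clip_rating(mu_d + rnorm(nrow(rows), sd = params$distress_noise_sd))
      cues <- expand.grid(imminence = c("distal", "imminent"),
                          level = names(params$threat_level),
                          stringsAsFactors = FALSE)
      cue_imm <- as.numeric(cues$imminence == "imminent")
      if (params$threat_imminence_shock_only) {
        cue_imm <- cue_imm * as.numeric(cues$level != "safe")
      }
      mu_t <- params$threat_baseline +
        unname(params$threat_level[cues$level]) +
        params$threat_imminence * cue_imm
      t_r <- clip_rating(mu_t + rnorm(nrow(cues), sd = params$threat_noise_sd))
      list(d = d, cues = cues, t_r = t_r)
    })
    distress[[i]] <- data.frame(subject_id = s,
                                global_trial_id = rows$global_trial_id,
                                distress_rating = as.integer(res$d))
    threat[[i]] <- data.frame(subject_id = s,
                              imminence = res$cues$imminence,
                              level = res$cues$level,
                              threat_rating = as.integer(res$t_r))
  }
  list(distress = do.call(rbind, distress),
       threat = do.call(rbind, threat))
}
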