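#' Parameters of the helping decision policy
#'
#' On shock trials the probability of helping follows a logistic policy
#' \eqn{P(\mathrm{help}) = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 a_s +
#' \gamma_2\,\mathrm{imminent})}, where \eqn{a_s} is the subject's
#' threat-coding strength in the target ROI. Safe trials always produce the
#' arbitrary `safe_choice` response. Defaults centre cohort helping near
#' 50% (\eqn{\gamma_0 = -\gamma_1\,\bar a}), plant a strong positive link
#' between target-ROI threat coding and helping (\eqn{\gamma_1 = 2.5}), and
#' a modest imminence facilitation (\eqn{\gamma_2 = 0.3}) so that most
#' simulated subjects help more under imminent than distal threat.
#'
#' @param gamma0 Intercept on the log-odds scale.
#' @param gamma1 Slope on the target-ROI threat-coding strength.
#' @param gamma2 Additive log-odds effect of imminent (vs distal) threat.
#' @param p_miss Probability that a response is missed (any trial type).
#' @param rt_mean_ms,rt_sd_ms Constant-plus-noise reaction-time placeholder.
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(gamma0 = -2.5, gamma1 = 2.5, gamma2 = 0.3,
                            p_miss = 0, rt_mean_ms = 850, rt_sd_ms = 150) {
  if (p_miss < 0 || p_miss > 1) stop("p_miss must lie in [0, 1]")
  structure(list(gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                 p_miss = p_miss, rt_mean_ms = rt_mean_ms,
                 rt_sd_ms = rt_sd_ms),
            class = "decision_params")
}

#' Extract per-subject decision traits from drawn coding strengths
#'
#' @param weights Data frame from [draw_neural_weights()].
#' @param target_roi ROI whose threat-coding strength enters the policy.
#' @return Data frame with columns `subject_id`, `a_target`.
#' @export
target_traits <- function(weights, target_roi = "amygdala_L") {
  w <- weights[weights$roi == target_roi, , drop = FALSE]
  if (!nrow(w)) stop("no weights found for target ROI ", target_roi)
  data.frame(subject_id = w$subject_id, a_target = w$a)
}

#' Simulate help/no-help decisions
#'
#' @param schedule Trial schedule from [generate_schedule()].
#' @param traits Data frame with columns `subject_id` and `a_target`
#'   (see [target_traits()]).
#' @param params A [decision_params()] object.
#' @param seed Integer master seed.
#' @return Data frame with columns `subject_id`, `global_trial_id`,
#'   `response` in help / no_help / safe_choice / missed, and `rt_ms`.
#' @export
generate_decisions <- function(schedule, traits, params = decision_params(),
                               seed = 1L) {
  if (!inherits(params, "decision_params")) {
    stop("params must be created with decision_params()")
  }
  subjects <- sort(unique(schedule$subject_id))
  missing_tr <- setdiff(subjects, traits$subject_id)
  if (length(missing_tr)) {
    stop("traits missing for subject(s) ", paste(missing_tr, collapse = ", "))
  }
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    rows <- schedule[schedule$subject_id == s, , drop = FALSE]
    a <- traits$a_target[match(s, traits$subject_id)]
    res <- with_local_seed(derive_seed(seed, 5L, s), {
      n <- nrow(rows)
      imm <- as.numeric(rows$imminence == "imminent")
      p_help <- plogis(params$gamma0 + params$gamma1 * a + params$gamma2 * imm)
      response <- ifelse(rows$level == "safe", "safe_choice",
                         ifelse(runif(n) < p_help, "help", "no_help"))
      if (params$p_miss > 0) {
        response[runif(n) < params$p_miss] <- "missed"
      }
      rt <- pmax(round(rnorm(n, params$rt_mean_ms, params$rt_sd_ms)), 200)
      rt[response == "missed"] <- NA_real_
      list(response = response, rt = rt)
    })
    out[[i]] <- data.frame(subject_id = s,
                           global_trial_id = rows$global_trial_id,
                           response = res$response, rt_ms = res$rt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate shock outcomes from decisions
#'
#' Applies the task contingencies: a missed response shocks both
#' participants with certainty on any trial; deciding not to help always
#' shocks the co-participant (and never the participant); deciding to help
#' shocks both with probability `design$p_both_shocked_on_help` and neither
#' otherwise; responded safe trials shock no one.
#'
#' @param decisions Decision set from [generate_decisions()].
#' @param schedule Trial schedule covering the same trials.
#' @param design A [task_design()] object (carries the help contingency).
#' @param seed Integer master seed.
#' @return Data frame with columns `subject_id`, `global_trial_id`,
#'   `participant_shocked`, `coparticipant_shocked`.
#' @export
simulate_outcomes <- function(decisions, schedule, design = task_design(),
                              seed = 1L) {
  key_s <- paste(schedule$subject_id, schedule$global_trial_id)
  key_d <- paste(decisions$subject_id, decisions$global_trial_id)
  unknown <- setdiff(key_d, key_s)
  if (length(unknown)) {
    stop("decisions refer to unscheduled trial(s): ",
         paste(utils::head(unknown, 5), collapse = "; "))
  }
  missing <- setdiff(key_s, key_d)
  if (length(missing)) {
    stop("no decision for scheduled trial(s): ",
         paste(utils::head(missing, 5), collapse = "; "))
  }
  m <- match(key_d, key_s)
  level <- schedule$level[m]
  subjects <- sort(unique(decisions$subject_id))
  part <- logical(nrow(decisions))
  copart <- logical(nrow(decisions))
  for (s in subjects) {
    idx <- which(decisions$subject_id == s)
    res <- with_local_seed(derive_seed(seed, 6L, s), {
      resp <- decisions$response[idx]
      lv <- level[idx]
      p <- logical(length(idx)); cp <- logical(length(idx))
      miss <- resp == "missed"
      p[miss] <- TRUE; cp[miss] <- TRUE
      cp[resp == "no_help"] <- TRUE
      hp <- resp == "help" & lv != "safe"
      both <- runif(sum(hp)) < design$p_both_shocked_on_help
      p[hp] <- both; cp[hp] <- both
      list(p = p, cp = cp)
    })
    part[idx] <- res$p; copart[idx] <- res$cp
  }
  data.frame(subject_id = decisions$subject_id,
             global_trial_id = decisions$global_trial_id,
             participant_shocked = part,
             coparticipant_shocked = copart)
}
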