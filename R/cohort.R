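#' Simulate a complete synthetic experiment
#'
#' Orchestrates the full generative chain: trial schedules, post-scan
#' ratings, per-subject representational coding strengths, ROI voxel
#' patterns, helping decisions (driven by the target-ROI threat-coding
#' strength), and shock outcomes. All randomness flows from the single
#' master seed through per-generator, per-subject derived streams, so the
#' result is bit-reproducible and subject streams are disjoint.
#'
#' @param design A [task_design()] object.
#' @param n_subjects Cohort size (the scanned cohort had 49 subjects).
#' @param rating_params,neural_params,decision_params Generator parameter
#'   objects; see [rating_params()], [neural_params()], [decision_params()].
#' @param seed Integer master seed.
#' @return An object of class `threat_cohort`: a list with `design`,
#'   `schedule`, `ratings`, `weights`, `patterns`, `decisions`, `outcomes`,
#'   and the parameter objects under `params`.
#' @export
#' @examples
#' co <- simulate_cohort(n_subjects = 2,
#'                       neural_params = neural_params(rois = "amygdala_L",
#'                                                     n_voxels = 20),
#'                       seed = 7)
#' names(co)
simulate_cohort <- function(design = task_design(), n_subjects = 49L,
                            rating_params = threatRSA::rating_params(),
                            neural_params = threatRSA::neural_params(),
                            decision_params = threatRSA::decision_params(),
                            seed = 1L) {
  schedule <- generate_schedule(design, n_subjects, seed = seed)
  ratings <- generate_ratings(schedule, rating_params, seed = seed)
  weights <- draw_neural_weights(neural_params, n_subjects, seed = seed)
  pat <- generate_roi_patterns(schedule, ratings, neural_params,
                               seed = seed, weights = weights)
  traits <- target_traits(weights, neural_params$target_roi)
  decisions <- generate_decisions(schedule, traits, decision_params,
                                  seed = seed)
  outcomes <- simulate_outcomes(decisions, schedule, design, seed = seed)
  structure(list(design = design, schedule = schedule, ratings = ratings,
                 weights = weights, patterns = pat$patterns,
                 decisions = decisions, outcomes = outcomes,
                 params = list(rating = rating_params, neural = neural_params,
                               decision = decision_params, seed = seed)),
            class = "threat_cohort")
}
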