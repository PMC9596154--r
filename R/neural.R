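#' Parameters of the synthetic ROI pattern generator
#'
#' Trial-wise voxel patterns for each (subject, ROI) pair are built from a
#' rank-two generative model: a threat axis and a distress axis, each a fixed
#' random unit-norm voxel pattern, weighted per trial by the subject's own
#' standardized rating of the trial's threat cue and of the trial's clip
#' distress, plus i.i.d. Gaussian noise. The per-subject coding strengths
#' `a` (threat) and `d` (distress) are drawn per ROI from cohort-level
#' folded-normal distributions, so strengths are nonnegative magnitudes.
#' Defaults (100 voxels, noise SD 0.12, mean strength 1, between-subject
#' SDs 0.5 for threat and 0.4 for distress coding) were chosen by a power
#' analysis so that with 49 subjects the planted link between target-ROI
#' threat coding and helping is reliably recovered by the RSA pipeline; see
#' the package vignette.
#'
#' @param rois Character vector of ROI names to simulate.
#' @param n_voxels Voxels per ROI (>= 2).
#' @param a_mean,a_sd Cohort mean/SD of the threat-coding strength.
#' @param d_mean,d_sd Cohort mean/SD of the distress-coding strength.
#' @param noise_sd Per-voxel noise SD (> 0), on the beta
#'   (percent-signal-change) scale of the patterns.
#' @param target_roi ROI whose threat-coding strength drives the decision
#'   policy in [generate_decisions()].
#' @return An object of class `neural_params`.
#' @export
neural_params <- function(rois = default_roi_list(), n_voxels = 100L,
                          a_mean = 1, a_sd = 0.5,
                          d_mean = 1, d_sd = 0.4,
                          noise_sd = 0.12,
                          target_roi = "amygdala_L") {
  if (n_voxels < 2) stop("n_voxels must be >= 2")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!length(rois)) stop("rois must be non-empty")
  if (!target_roi %in% rois) stop("target_roi must be one of rois")
  structure(list(rois = as.character(rois), n_voxels = as.integer(n_voxels),
                 a_mean = a_mean, a_sd = a_sd, d_mean = d_mean, d_sd = d_sd,
                 noise_sd = noise_sd, target_roi = target_roi),
            class = "neural_params")
}

#' Draw per-subject representational coding strengths
#'
#' @param params A [neural_params()] object.
#' @param n_subjects Number of subjects.
#' @param seed Integer master seed.
#' @return Data frame with columns `subject_id`, `roi`, `a` (threat-coding
#'   strength) and `d` (distress-coding strength); strengths are
#'   folded-normal draws, independent across subjects and ROIs.
#' @export
draw_neural_weights <- function(params, n_subjects, seed = 1L) {
  if (!inherits(params, "neural_params")) {
    stop("params must be created with neural_params()")
  }
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    w <- with_local_seed(derive_seed(seed, 3L, s), {
      k <- length(params$rois)
      data.frame(subject_id = s, roi = params$rois,
                 a = abs(rnorm(k, params$a_mean, params$a_sd)),
                 d = abs(rnorm(k, params$d_mean, params$d_sd)),
                 stringsAsFactors = FALSE)
    })
    out[[s]] <- w
  }
  do.call(rbind, out)
}

# Within-subject z-scoring; a constant vector maps to all zeros (no signal).
zscore_or_zero <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate trial-wise ROI voxel patterns with planted geometry
#'
#' For subject \eqn{s}, ROI \eqn{r}, trial \eqn{t} and voxel \eqn{v}, the
#' beta estimate is
#' \deqn{\beta_{tv} = a\, z(\mathrm{threat}_t)\, u_v +
#'       d\, z(\mathrm{distress}_t)\, w_v + \epsilon_{tv},}
#' where \eqn{u, w} are fixed random unit-norm voxel patterns per
#' (subject, ROI), \eqn{z(\cdot)} standardizes the subject's trial-level
#' ratings (the trial's cue rating for threat, the trial's clip rating for
#' distress), and \eqn{\epsilon} is i.i.d. Gaussian noise.
#'
#' @param schedule Trial schedule from [generate_schedule()].
#' @param ratings Rating set from [generate_ratings()].
#' @param params A [neural_params()] object.
#' @param seed Integer master seed.
#' @param weights Optional pre-drawn weights from [draw_neural_weights()];
#'   when `NULL` they are drawn from the same master seed.
#' @return Nested list: `patterns[[subject]][[roi]]` is a trials-by-voxels
#'   matrix with global trial ids as row names, plus a `weights` data frame.
#' @export
generate_roi_patterns <- function(schedule, ratings, params = neural_params(),
                                  seed = 1L, weights = NULL) {
  if (!inherits(params, "neural_params")) {
    stop("params must be created with neural_params()")
  }
  subjects <- sort(unique(schedule$subject_id))
  if (is.null(weights)) {
    weights <- draw_neural_weights(params, max(subjects), seed = seed)
  }
  patterns <- vector("list", length(subjects))
  names(patterns) <- as.character(subjects)
  vox_ids <- sprintf("v%03d", seq_len(params$n_voxels))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    rows <- schedule[schedule$subject_id == s, , drop = FALSE]
    thr <- trial_threat_ratings(rows, ratings$threat)
    zt <- zscore_or_zero(thr$threat_rating[match(rows$global_trial_id,
                                                 thr$global_trial_id)])
    dis <- ratings$distress[ratings$distress$subject_id == s, , drop = FALSE]
    md <- match(rows$global_trial_id, dis$global_trial_id)
    if (anyNA(md)) {
      stop("distress ratings missing for subject ", s, ", trial(s) ",
           paste(rows$global_trial_id[is.na(md)], collapse = ", "))
    }
    zd <- zscore_or_zero(dis$distress_rating[md])
    w_s <- weights[weights$subject_id == s, , drop = FALSE]
    sub_list <- vector("list", length(params$rois))
    names(sub_list) <- params$rois
    for (j in seq_along(params$rois)) {
      roi <- params$rois[j]
      a <- w_s$a[w_s$roi == roi]
      d <- w_s$d[w_s$roi == roi]
      if (!length(a)) stop("weights missing for subject ", s, ", ROI ", roi)
      mat <- with_local_seed(
        derive_seed(seed, 4L, s, j),
        gen_pattern_cpp(zt, zd, a, d, params$noise_sd, params$n_voxels))
      dimnames(mat) <- list(as.character(rows$global_trial_id), vox_ids)
      sub_list[[j]] <- mat
    }
    patterns[[i]] <- sub_list
  }
  list(patterns = patterns, weights = weights)
}
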