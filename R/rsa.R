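#' Second-order similarity between a neural and a behavioral RDM
#'
#' Kendall's tau between the lower-triangle entries (diagonal excluded) of
#' two RDMs. Alignment is by trial id, never by position: the behavioral
#' RDM is reordered to the neural RDM's labels, and any label mismatch is
#' an error.
#'
#' @param neural,behavioral [new_rdm()] objects over the same trial set.
#' @param variant Kendall variant, see [kendall_tau()].
#' @return List with `tau`, `n_pairs` and `variant`.
#' @export
second_order_similarity <- function(neural, behavioral,
                                    variant = c("tau_a", "tau_b")) {
  variant <- match_variant(variant)
  ln <- rownames(neural); lb <- rownames(behavioral)
  if (!identical(ln, lb)) {
    only_n <- setdiff(ln, lb); only_b <- setdiff(lb, ln)
    if (length(only_n) || length(only_b)) {
      stop("RDM label mismatch; only in neural: ",
           paste(only_n, collapse = ", "), "; only in behavioral: ",
           paste(only_b, collapse = ", "))
    }
    m <- match(ln, lb)
    behavioral <- unclass(behavioral)[m, m, drop = FALSE]
  }
  lt <- lower.tri(neural)
  st <- kendall_stats_cpp(unclass(neural)[lt], unclass(behavioral)[lt])
  list(tau = tau_from_stats(st, variant), n_pairs = sum(lt),
       variant = variant)
}

#' Per-subject, per-ROI, per-condition second-order similarity table
#'
#' For every subject, ROI and imminence condition, builds the neural RDM
#' (1 - Pearson r over trial-wise voxel patterns), the threat RDM and the
#' distress RDM (Euclidean distances over the subject's own ratings), and
#' records Kendall's tau between the neural RDM and each behavioral model.
#'
#' @param patterns Nested list `patterns[[subject]][[roi]]` of
#'   trials-by-voxels matrices (as from [generate_roi_patterns()]).
#' @param schedule,ratings Trial schedule and rating set covering the
#'   patterns.
#' @param roi_list ROIs to process; defaults to those present for the first
#'   subject.
#' @param variant Kendall variant, see [kendall_tau()].
#' @return Data frame with columns `subject_id`, `roi`, `condition`,
#'   `tau_threat`, `tau_distress`, `n_pairs`.
#' @export
similarity_table <- function(patterns, schedule, ratings, roi_list = NULL,
                             variant = c("tau_a", "tau_b")) {
  variant <- match_variant(variant)
  subjects <- sort(unique(schedule$subject_id))
  if (is.null(roi_list)) roi_list <- names(patterns[[1]])
  gaps <- character(0)
  for (s in subjects) {
    have <- names(patterns[[as.character(s)]])
    miss <- setdiff(roi_list, have)
    if (is.null(have)) miss <- roi_list
    if (length(miss)) {
      gaps <- c(gaps, paste0("subject ", s, ": ",
                             paste(miss, collapse = ", ")))
    }
  }
  if (length(gaps)) {
    stop("missing pattern matrices for ", paste(gaps, collapse = "; "))
  }
  n_rec <- length(subjects) * length(roi_list) * 2L
  rec_subject <- integer(n_rec); rec_roi <- character(n_rec)
  rec_cond <- character(n_rec); rec_tt <- numeric(n_rec)
  rec_td <- numeric(n_rec); rec_np <- integer(n_rec)
  k <- 0L
  for (s in subjects) {
    rows_s <- schedule[schedule$subject_id == s, , drop = FALSE]
    dis_s <- ratings$distress[ratings$distress$subject_id == s, ,
                              drop = FALSE]
    for (cond in c("distal", "imminent")) {
      rows <- rows_s[rows_s$imminence == cond, , drop = FALSE]
      ids <- as.character(rows$global_trial_id)
      md <- match(rows$global_trial_id, dis_s$global_trial_id)
      if (anyNA(md)) {
        stop("distress ratings missing for subject ", s, ", trial(s) ",
             paste(rows$global_trial_id[is.na(md)], collapse = ", "))
      }
      dis_rdm <- rating_rdm(dis_s$distress_rating[md], ids,
                            condition = cond, source = "distress")
      thr <- trial_threat_ratings(rows, ratings$threat)
      thr_rdm <- rating_rdm(
        thr$threat_rating[match(rows$global_trial_id, thr$global_trial_id)],
        ids, condition = cond, source = "threat")
      # behavioral lower triangles are shared across ROIs. Rating-derived
      # RDM entries take few distinct values, so the categorical Kendall
      # kernel (which also shares the sort of the neural vector across the
      # two models) applies; it agrees exactly with
      # second_order_similarity(), which the tests assert.
      lt <- lower.tri(dis_rdm)
      thr_lt <- unclass(thr_rdm)[lt]
      dis_lt <- unclass(dis_rdm)[lt]
      n_pairs <- length(thr_lt)
      thr_vals <- sort(unique(thr_lt))
      thr_cat <- match(thr_lt, thr_vals) - 1L
      dis_vals <- sort(unique(dis_lt))
      dis_cat <- match(dis_lt, dis_vals) - 1L
      for (roi in roi_list) {
        mat <- patterns[[as.character(s)]][[roi]]
        n_rdm <- neural_rdm(mat[ids, , drop = FALSE],
                            condition = cond, source = roi)
        sts <- kendall_stats_categorical_cpp(unclass(n_rdm)[lt],
                                             thr_cat, length(thr_vals),
                                             dis_cat, length(dis_vals))
        k <- k + 1L
        rec_subject[k] <- s; rec_roi[k] <- roi; rec_cond[k] <- cond
        rec_tt[k] <- tau_from_stats(sts[1, ], variant)
        rec_td[k] <- tau_from_stats(sts[2, ], variant)
        rec_np[k] <- n_pairs
      }
    }
  }
  data.frame(subject_id = rec_subject, roi = rec_roi, condition = rec_cond,
             tau_threat = rec_tt, tau_distress = rec_td, n_pairs = rec_np,
             stringsAsFactors = FALSE)
}

#' Ordinary least squares model of helping percentage for one ROI
#'
#' Regresses each subject's overall helping percentage (duplicated across
#' the subject's distal and imminent rows, as the two-rows-per-subject
#' design implies) on the neural-threat similarity, the neural-distress
#' similarity, and threat imminence (coded 0 = distal, 1 = imminent).
#' Two-sided p-values use the t distribution with n - 4 degrees of freedom.
#' The duplicated outcome makes the rows non-independent; an optional
#' cluster-robust (by subject) covariance is available but off by default.
#'
#' @param similarity Data frame from [similarity_table()].
#' @param helping Data frame from [helping_summary()].
#' @param roi ROI to fit.
#' @param robust If `TRUE`, replace the classical standard errors with
#'   cluster-robust (by subject) ones (requires the sandwich package).
#' @return Data frame with one row per coefficient: `roi`, `term`, `beta`,
#'   `se`, `t`, `p`, `n_rows`.
#' @export
fit_roi_model <- function(similarity, helping, roi, robust = FALSE) {
  sub <- similarity[similarity$roi == roi, , drop = FALSE]
  if (!nrow(sub)) stop("no similarity records for ROI ", roi)
  mh <- match(sub$subject_id, helping$subject_id)
  if (anyNA(mh)) {
    stop("helping summary missing for subject(s) ",
         paste(unique(sub$subject_id[is.na(mh)]), collapse = ", "))
  }
  df <- data.frame(helping_pct = helping$helping_pct_overall[mh],
                   threat_similarity = sub$tau_threat,
                   distress_similarity = sub$tau_distress,
                   imminence = as.numeric(sub$condition == "imminent"),
                   subject_id = sub$subject_id)
  if (anyNA(df$helping_pct)) {
    stop("helping percentage undefined for some subjects in ROI ", roi)
  }
  X <- model.matrix(~ threat_similarity + distress_similarity + imminence,
                    data = df)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear or constant predictors for ROI ", roi,
         ": design matrix is rank deficient")
  }
  fit <- lm(helping_pct ~ threat_similarity + distress_similarity + imminence,
            data = df)
  beta <- coef(fit)
  if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      stop("robust = TRUE requires the sandwich package")
    }
    V <- sandwich::vcovCL(fit, cluster = df$subject_id)
  } else {
    V <- vcov(fit)
  }
  se <- sqrt(diag(V))
  tval <- beta / se
  dfree <- nrow(df) - length(beta)
  pval <- 2 * pt(abs(tval), df = dfree, lower.tail = FALSE)
  terms <- c("intercept", "threat_similarity", "distress_similarity",
             "imminence")
  data.frame(roi = roi, term = terms, beta = unname(beta), se = unname(se),
             t = unname(tval), p = unname(pval), n_rows = nrow(df),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with the usual monotonicity enforcement, plus
#' significance flags at the chosen level.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha FDR level for the flags.
#' @return List with `p_fdr` (adjusted p-values, same order as input) and
#'   `significant` (logical flags, `p_fdr < alpha`).
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  adj <- p.adjust(p, method = "BH")
  list(p_fdr = adj, significant = adj < alpha)
}

#' Run the full ROI-based RSA inference
#'
#' Computes the second-order similarity table, the per-subject helping
#' summary, one linear model per ROI, and a joint FDR correction across the
#' models' p-values (by default the three substantive slopes of every
#' model, intercepts excluded).
#'
#' @inheritParams similarity_table
#' @param decisions Decision set for the helping outcome.
#' @param alpha FDR level.
#' @param fdr_pool `"slopes"` (default: threat similarity, distress
#'   similarity and imminence coefficients of every model) or `"all"`
#'   (intercepts included).
#' @param robust Passed to [fit_roi_model()].
#' @return List with `similarity`, `helping`, `models` (coefficient table
#'   with `p_fdr` and `significant` columns; `NA` outside the FDR pool),
#'   `fdr_pool_size`, `alpha`, `variant`.
#' @export
run_rsa <- function(patterns, schedule, ratings, decisions, roi_list = NULL,
                    variant = c("tau_a", "tau_b"), alpha = 0.05,
                    fdr_pool = c("slopes", "all"), robust = FALSE) {
  variant <- match.arg(variant)
  fdr_pool <- match.arg(fdr_pool)
  if (is.null(roi_list)) roi_list <- names(patterns[[1]])
  sim <- similarity_table(patterns, schedule, ratings, roi_list, variant)
  helping <- helping_summary(decisions, schedule)
  models <- do.call(rbind, lapply(roi_list, function(roi) {
    fit_roi_model(sim, helping, roi, robust = robust)
  }))
  in_pool <- if (fdr_pool == "all") rep(TRUE, nrow(models)) else
    models$term != "intercept"
  adj <- fdr_adjust(models$p[in_pool], alpha = alpha)
  models$p_fdr <- NA_real_
  models$significant <- NA
  models$p_fdr[in_pool] <- adj$p_fdr
  models$significant[in_pool] <- adj$significant
  list(similarity = sim, helping = helping, models = models,
       fdr_pool_size = sum(in_pool), alpha = alpha, variant = variant)
}

#' Test whether ROIs predominantly represent threat or distress
#'
#' For each ROI-by-condition cell, compares the per-subject neural-threat
#' and neural-distress similarities with a two-sided paired Wilcoxon
#' signed-rank test on the differences, then FDR-corrects across cells.
#' When every paired difference is exactly zero the statistic is 0 and
#' p = 1 by convention.
#'
#' @param similarity Data frame from [similarity_table()].
#' @param alpha FDR level.
#' @return Data frame with one row per ROI-by-condition cell: `roi`,
#'   `condition`, `statistic`, `p`, `p_fdr`, `significant`, `direction`
#'   (threat / distress / none, the sign of the mean paired difference),
#'   and `n` subjects.
#' @export
predominance_test <- function(similarity, alpha = 0.05) {
  cells <- unique(similarity[, c("roi", "condition")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- similarity[similarity$roi == cells$roi[i] &
                        similarity$condition == cells$condition[i], ]
    diffs <- sub$tau_threat - sub$tau_distress
    if (length(diffs) < 5) {
      stop("insufficient data for ", cells$roi[i], "/", cells$condition[i],
           ": need at least 5 paired subjects, have ", length(diffs))
    }
    if (all(diffs == 0)) {
      stat <- 0; pv <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(diffs, mu = 0, exact = FALSE,
                                         correct = TRUE))
      stat <- unname(wt$statistic); pv <- wt$p.value
    }
    md <- mean(diffs)
    data.frame(roi = cells$roi[i], condition = cells$condition[i],
               statistic = stat, p = pv,
               direction = if (md > 0) "threat" else
                 if (md < 0) "distress" else "none",
               n = length(diffs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- fdr_adjust(out$p, alpha = alpha)
  out$p_fdr <- adj$p_fdr
  out$significant <- adj$significant
  out[, c("roi", "condition", "statistic", "p", "p_fdr", "significant",
          "direction", "n")]
}
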