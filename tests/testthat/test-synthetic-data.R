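test_that("default schedule reproduces the task's factorial structure", {
  sched <- generate_schedule(task_design(), n_subjects = 1, seed = 1)
  expect_equal(nrow(sched), 144)
  cells <- table(sched$imminence, sched$level)
  expect_true(all(cells == 24))
  per_run <- table(sched$run, sched$imminence)
  expect_true(all(per_run == 9))
  # contiguous imminence blocks within each run
  for (r in unique(sched$run)) {
    imm <- sched$imminence[sched$run == r]
    expect_equal(length(rle(imm)$lengths), 2)
    expect_true(all(rle(imm)$lengths == 9))
  }
  # equal level counts within each block
  blk <- table(sched$run, sched$imminence, sched$level)
  expect_true(all(blk == 3))
})

test_that("schedule cell counts are design-determined for random valid designs", {
  set.seed(101)
  for (rep in 1:10) {
    n_lv <- 3
    per_lv <- 2 * sample(1:3, 1)
    tpr <- per_lv * n_lv
    d <- task_design(n_runs = sample(1:4, 1), trials_per_run = tpr,
                     n_distal_per_run = tpr / 2, n_imminent_per_run = tpr / 2,
                     n_per_level_per_run = per_lv)
    sched <- generate_schedule(d, n_subjects = 2, seed = rep)
    expect_equal(nrow(sched), 2 * d$n_runs * tpr)
    cells <- table(sched$subject_id, sched$imminence, sched$level)
    expect_true(all(cells == d$n_runs * per_lv / 2))
  }
})

test_that("tiny single-run design is forced by the invariants", {
  d <- task_design(n_runs = 1, trials_per_run = 6, n_distal_per_run = 3,
                   n_imminent_per_run = 3, n_per_level_per_run = 2)
  sched <- generate_schedule(d, 1, seed = 9)
  expect_equal(nrow(sched), 6)
  expect_true(all(table(sched$imminence, sched$level) == 1))
})

test_that("inconsistent design counts are rejected", {
  expect_error(task_design(n_distal_per_run = 8), "trials_per_run")
  expect_error(task_design(n_per_level_per_run = 5), "even|levels")
  expect_error(task_design(p_both_shocked_on_help = 1.2), "\\[0, 1\\]")
})

test_that("generators are bit-reproducible and subject streams are disjoint", {
  d <- task_design()
  s1 <- generate_schedule(d, 3, seed = 7)
  s2 <- generate_schedule(d, 3, seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_schedule(d, 3, seed = 8)
  expect_false(identical(s1, s3))
  # subject 2's rows do not depend on how many subjects are generated
  wide <- generate_schedule(d, 5, seed = 7)
  sub2 <- wide[wide$subject_id == 2, ]
  rownames(sub2) <- NULL
  ref2 <- s1[s1$subject_id == 2, ]
  rownames(ref2) <- NULL
  expect_identical(sub2, ref2)
})

test_that("noise-free ratings are ordered by level and imminence, and clip", {
  sched <- generate_schedule(task_design(), 1, seed = 2)
  p0 <- rating_params(distress_noise_sd = 1e-12, threat_noise_sd = 1e-12,
                      distress_level = c(safe = 0, "1shock" = 1,
                                         "2shocks" = 2),
                      distress_imminence = 1)
  r <- generate_ratings(sched, p0, seed = 2)
  mu <- tapply(r$distress$distress_rating,
               sched$level[match(r$distress$global_trial_id,
                                 sched$global_trial_id)], mean)
  expect_true(mu[["safe"]] < mu[["1shock"]])
  expect_true(mu[["1shock"]] < mu[["2shocks"]])
  by_imm <- tapply(r$distress$distress_rating,
                   sched$imminence[match(r$distress$global_trial_id,
                                         sched$global_trial_id)], mean)
  expect_true(by_imm[["distal"]] < by_imm[["imminent"]])
  # threat cues: increasing with level; imminence bump on shock cues only
  thr <- r$threat
  m_thr <- tapply(thr$threat_rating, list(thr$imminence, thr$level), mean)
  expect_true(m_thr["distal", "safe"] < m_thr["distal", "1shock"])
  expect_true(m_thr["distal", "1shock"] < m_thr["distal", "2shocks"])
  expect_equal(m_thr["distal", "safe"], m_thr["imminent", "safe"])
  expect_gt(m_thr["imminent", "1shock"], m_thr["distal", "1shock"])
  # clipping at the scale ceiling
  p9 <- rating_params(distress_baseline = 9, distress_noise_sd = 1e-12,
                      threat_baseline = 9, threat_noise_sd = 1e-12)
  r9 <- generate_ratings(sched, p9, seed = 2)
  expect_true(all(r9$distress$distress_rating == 9))
  expect_true(all(r9$threat$threat_rating == 9))
  expect_true(all(r$distress$distress_rating >= 1 &
                    r$distress$distress_rating <= 9))
})

test_that("fitted imminence effect on distress matches the planted effect", {
  # many trials -> Monte-Carlo estimate close to the generating equation
  d <- task_design()
  sched <- generate_schedule(d, 8, seed = 31)   # 1152 trials
  pars <- rating_params()
  r <- generate_ratings(sched, pars, seed = 31)
  imm <- sched$imminence[match(r$distress$global_trial_id +
                                 1000 * (r$distress$subject_id - 1),
                               sched$global_trial_id +
                                 1000 * (sched$subject_id - 1))]
  fit <- lm(r$distress$distress_rating ~ (imm == "imminent"))
  est <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  # rounding/clipping attenuates slightly; 3 SE band around planted effect
  expect_lt(abs(est - pars$distress_imminence), 3 * se)
})

test_that("roi patterns are deterministic and respect planted structure", {
  co <- small_cohort(n_subjects = 2, seed = 13)
  co2 <- small_cohort(n_subjects = 2, seed = 13)
  expect_identical(co$patterns, co2$patterns)
  m <- co$patterns[["1"]][["amygdala_L"]]
  expect_equal(dim(m), c(144, 40))
  expect_identical(rownames(m),
                   as.character(co$schedule$global_trial_id[
                     co$schedule$subject_id == 1]))
  # missing ratings are an error
  r_bad <- co$ratings
  r_bad$distress <- r_bad$distress[-1, ]
  expect_error(generate_roi_patterns(co$schedule, r_bad,
                                     neural_params(rois = "amygdala_L",
                                                   n_voxels = 10), seed = 1),
               "missing")
})

test_that("pure-noise patterns give near-zero second-order similarity", {
  np <- neural_params(rois = "amygdala_L", n_voxels = 40,
                      a_mean = 0, a_sd = 1e-12, d_mean = 0, d_sd = 1e-12)
  taus <- c()
  for (seed in 1:25) {
    co <- simulate_cohort(n_subjects = 4, neural_params = np, seed = seed)
    sim <- similarity_table(co$patterns, co$schedule, co$ratings)
    taus <- c(taus, sim$tau_threat, sim$tau_distress)
  }
  expect_gte(length(taus) / 4, 100)   # >= 100 simulated subjects
  expect_lt(abs(mean(taus)), 0.02)
})

test_that("strong threat coding dominates distress coding in the readout", {
  np <- neural_params(rois = "amygdala_L", n_voxels = 60,
                      a_mean = 2, a_sd = 1e-12, d_mean = 0, d_sd = 1e-12,
                      noise_sd = 0.05)
  wins <- 0; total <- 0
  for (seed in 1:10) {
    co <- simulate_cohort(n_subjects = 10, neural_params = np, seed = seed)
    sim <- similarity_table(co$patterns, co$schedule, co$ratings)
    per_sub <- aggregate(cbind(tau_threat, tau_distress) ~ subject_id,
                         sim, mean)
    wins <- wins + sum(per_sub$tau_threat > per_sub$tau_distress)
    total <- total + nrow(per_sub)
  }
  expect_gte(wins / total, 0.95)
})

test_that("decision policy: symmetric logistic gives ~50% helping", {
  sched <- generate_schedule(task_design(), 30, seed = 5)
  traits <- data.frame(subject_id = 1:30, a_target = 0)
  dec <- generate_decisions(sched, traits,
                            decision_params(gamma0 = 0, gamma1 = 0,
                                            gamma2 = 0), seed = 5)
  shock <- dec$response[dec$response %in% c("help", "no_help")]
  p_hat <- mean(shock == "help")
  n <- length(shock)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
  expect_false(any(dec$response == "missed"))
  # safe trials only carry safe_choice (or missed)
  key <- paste(sched$subject_id, sched$global_trial_id)
  lv <- sched$level[match(paste(dec$subject_id, dec$global_trial_id), key)]
  expect_true(all(dec$response[lv == "safe"] %in% c("safe_choice", "missed")))
  expect_true(all(dec$response[lv != "safe"] %in%
                    c("help", "no_help", "missed")))
})

test_that("strong coding-to-helping link yields positive correlation in >=95% of cohorts", {
  hits <- 0
  for (seed in 1:100) {
    with_local <- asNamespace("threatRSA")$with_local_seed
    sched <- generate_schedule(task_design(), 15, seed = seed)
    traits <- with_local(seed, data.frame(subject_id = 1:15,
                                          a_target = abs(rnorm(15, 1, 0.5))))
    dec <- generate_decisions(sched, traits, decision_params(), seed = seed)
    h <- helping_summary(dec, sched)
    if (cor(traits$a_target, h$helping_pct_overall) > 0) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})

test_that("planted helping link is recovered by regression in >=80% of cohorts", {
  np <- neural_params()
  hits <- 0
  n_cohorts <- 200
  for (seed in 1:n_cohorts) {
    sched <- generate_schedule(task_design(), 49, seed = seed)
    w <- draw_neural_weights(np, 49, seed = seed)
    traits <- target_traits(w, np$target_roi)
    dec <- generate_decisions(sched, traits, decision_params(), seed = seed)
    h <- helping_summary(dec, sched)
    fit <- summary(lm(h$helping_pct_overall ~ traits$a_target))
    co <- fit$coefficients
    if (co[2, 1] > 0 && co[2, 4] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_cohorts, 0.80)
})

test_that("outcome contingencies follow the task rules", {
  d <- task_design()
  sched <- generate_schedule(d, 2, seed = 3)
  traits <- data.frame(subject_id = 1:2, a_target = 1)
  dec <- generate_decisions(sched, traits, seed = 3)
  out <- simulate_outcomes(dec, sched, d, seed = 3)
  key <- paste(sched$subject_id, sched$global_trial_id)
  m <- match(paste(out$subject_id, out$global_trial_id), key)
  lv <- sched$level[m]
  resp <- dec$response[match(paste(out$subject_id, out$global_trial_id),
                             paste(dec$subject_id, dec$global_trial_id))]
  # safe responded trials: nobody shocked
  safe <- lv == "safe" & resp != "missed"
  expect_false(any(out$participant_shocked[safe]))
  expect_false(any(out$coparticipant_shocked[safe]))
  # no-help: co-participant always, participant never
  nh <- resp == "no_help"
  expect_true(all(out$coparticipant_shocked[nh]))
  expect_false(any(out$participant_shocked[nh]))
  # help: both or neither
  hp <- resp == "help"
  expect_true(all(out$participant_shocked[hp] ==
                    out$coparticipant_shocked[hp]))
  # all-no-help input
  dec_nh <- dec
  dec_nh$response[lv[match(paste(dec$subject_id, dec$global_trial_id),
                           key)] != "safe"] <- "no_help"
  out_nh <- simulate_outcomes(dec_nh, sched, d, seed = 4)
  shock_rows <- lv != "safe"
  expect_true(all(out_nh$coparticipant_shocked[shock_rows]))
  expect_false(any(out_nh$participant_shocked))
  # missed responses shock both, on any trial type
  dec_ms <- dec
  dec_ms$response[1] <- "missed"
  out_ms <- simulate_outcomes(dec_ms, sched, d, seed = 5)
  expect_true(out_ms$participant_shocked[1] && out_ms$coparticipant_shocked[1])
  # decisions for unknown trials rejected
  dec_bad <- dec
  dec_bad$global_trial_id[1] <- 999
  expect_error(simulate_outcomes(dec_bad, sched, d, seed = 1), "unscheduled")
})

test_that("help-trial both-shocked frequency matches the contingency", {
  d <- task_design()
  sched <- generate_schedule(d, 4, seed = 21)
  dec <- data.frame(subject_id = sched$subject_id,
                    global_trial_id = sched$global_trial_id,
                    response = ifelse(sched$level == "safe", "safe_choice",
                                      "help"),
                    rt_ms = 500)
  out <- simulate_outcomes(dec, sched, d, seed = 21)
  hp <- dec$response == "help"
  frac <- mean(out$participant_shocked[hp])
  n <- sum(hp)
  expect_lt(abs(frac - 0.70), 3 * sqrt(0.7 * 0.3 / n))
})
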