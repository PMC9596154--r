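#' Define the threat-imminence task design
#'
#' Encodes the factorial structure of the helping-under-threat task: runs of
#' trials split into a distal and an imminent block, with a balanced number
#' of trials per threat level (safe, 1 shock, 2 shocks), and the shock
#' contingency applied when the participant decides to help. The defaults
#' reproduce the scanned task: 8 runs of 18 trials (9 distal + 9 imminent,
#' 6 per threat level), 144 trials in total, and a 70% chance that a help
#' decision ends with both participants shocked.
#'
#' @param n_runs Number of functional runs.
#' @param trials_per_run Trials per run.
#' @param n_distal_per_run Distal trials per run.
#' @param n_imminent_per_run Imminent trials per run.
#' @param n_per_level_per_run Trials per threat level per run (must be even,
#'   so each imminence block carries half).
#' @param levels Ordered threat-level labels.
#' @param p_both_shocked_on_help Probability that both the participant and
#'   the co-participant are shocked after a help decision.
#' @return An object of class `task_design`.
#' @export
#' @examples
#' d <- task_design()
#' d$n_runs * d$trials_per_run  # 144 trials
task_design <- function(n_runs = 8L, trials_per_run = 18L,
                        n_distal_per_run = 9L, n_imminent_per_run = 9L,
                        n_per_level_per_run = 6L,
                        levels = c("safe", "1shock", "2shocks"),
                        p_both_shocked_on_help = 0.70) {
  counts <- c(n_runs = n_runs, trials_per_run = trials_per_run,
              n_distal_per_run = n_distal_per_run,
              n_imminent_per_run = n_imminent_per_run,
              n_per_level_per_run = n_per_level_per_run)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("design counts must be positive integers")
  }
  if (n_distal_per_run + n_imminent_per_run != trials_per_run) {
    stop("invalid design: n_distal_per_run + n_imminent_per_run (",
         n_distal_per_run + n_imminent_per_run, ") != trials_per_run (",
         trials_per_run, ")")
  }
  if (n_per_level_per_run * length(levels) != trials_per_run) {
    stop("invalid design: n_per_level_per_run * number of levels (",
         n_per_level_per_run * length(levels), ") != trials_per_run (",
         trials_per_run, ")")
  }
  if (n_distal_per_run != n_imminent_per_run) {
    stop("invalid design: distal and imminent blocks must be the same size")
  }
  if (n_per_level_per_run %% 2L != 0L) {
    stop("invalid design: n_per_level_per_run must be even so levels balance ",
         "within each imminence block")
  }
  if (!is.numeric(p_both_shocked_on_help) ||
      p_both_shocked_on_help < 0 || p_both_shocked_on_help > 1) {
    stop("p_both_shocked_on_help must lie in [0, 1]")
  }
  structure(list(n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 n_distal_per_run = as.integer(n_distal_per_run),
                 n_imminent_per_run = as.integer(n_imminent_per_run),
                 n_per_level_per_run = as.integer(n_per_level_per_run),
                 levels = as.character(levels),
                 p_both_shocked_on_help = p_both_shocked_on_help),
            class = "task_design")
}

# Deterministic seed derivation so that every generator and every subject
# draws from its own stream. Multiplier kept small enough that the modular
# arithmetic stays exact in doubles; result is always a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  h <- as.double(as.integer(seed) %% 2147483647L)
  for (k in ks) h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(h)
}

# Runs `code` under set.seed(seed) while leaving the caller's RNG state
# untouched. Cheaper than withr::with_seed in per-subject inner loops.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate randomized trial schedules
#'
#' Builds per-subject trial schedules honouring the task design: each run is
#' split into a contiguous distal and a contiguous imminent block (which
#' block comes first is randomized independently per run and subject), and
#' threat levels are shuffled within each block with equal counts per block.
#'
#' @param design A [task_design()] object.
#' @param n_subjects Number of subjects to schedule.
#' @param seed Integer master seed; identical seeds give identical
#'   schedules, and each subject draws from its own derived stream.
#' @return A data frame with columns `subject_id`, `run`,
#'   `trial_index_in_run`, `global_trial_id`, `imminence`, `level`,
#'   `block_order`.
#' @export
#' @examples
#' sched <- generate_schedule(task_design(), n_subjects = 1, seed = 1)
#' nrow(sched)                       # 144
#' table(sched$imminence, sched$level)  # 24 per cell
generate_schedule <- function(design, n_subjects = 1L, seed = 1L) {
  if (!inherits(design, "task_design")) {
    stop("design must be created with task_design()")
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  per_block <- design$n_per_level_per_run %/% 2L
  block_len <- design$trials_per_run %/% 2L
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    rows <- with_local_seed(derive_seed(seed, 1L, s), {
      runs <- lapply(seq_len(design$n_runs), function(r) {
        first <- sample(c("distal", "imminent"), 1L)
        blocks <- c(first, setdiff(c("distal", "imminent"), first))
        shuffle_levels <- function() sample(rep(design$levels, each = per_block))
        data.frame(run = r,
                   trial_index_in_run = seq_len(design$trials_per_run),
                   imminence = rep(blocks, each = block_len),
                   level = c(shuffle_levels(), shuffle_levels()),
                   block_order = first,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, runs)
    })
    rows$subject_id <- s
    out[[s]] <- rows
  }
  sched <- do.call(rbind, out)
  sched$global_trial_id <-
    (sched$run - 1L) * design$trials_per_run + sched$trial_index_in_run
  rownames(sched) <- NULL
  sched[, c("subject_id", "run", "trial_index_in_run", "global_trial_id",
            "imminence", "level", "block_order")]
}
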