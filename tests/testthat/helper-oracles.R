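# Independent oracles, deliberately naive: exhaustive pair enumeration for
# Kendall's tau, the literal step-up definition for Benjamini-Hochberg, and
# the closed-form normal equations for OLS.

oracle_kendall <- function(x, y, variant = "tau_a") {
  n <- length(x)
  conc <- 0; disc <- 0; tie_x <- 0; tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx * dy > 0) conc <- conc + 1
      if (dx * dy < 0) disc <- disc + 1
      if (dx == 0) tie_x <- tie_x + 1
      if (dy == 0) tie_y <- tie_y + 1
    }
  }
  n0 <- n * (n - 1) / 2
  if (variant == "tau_a") return((conc - disc) / n0)
  den <- sqrt((n0 - tie_x) * (n0 - tie_y))
  if (den == 0) return(NA_real_)   # undefined
  (conc - disc) / den
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  # step-up: enforce monotonicity from the largest rank down
  if (m > 1) {
    for (i in (m - 1):1) ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  adj <- pmin(ranked, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Small cohort used across tests: 2 ROIs, few voxels, defaults otherwise.
small_cohort <- function(n_subjects = 8, seed = 42, n_voxels = 40,
                         rois = c("amygdala_L", "insula_L"), ...) {
  simulate_cohort(n_subjects = n_subjects,
                  neural_params = neural_params(rois = rois,
                                                n_voxels = n_voxels, ...),
                  seed = seed)
}
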