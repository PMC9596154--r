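---
title: "Simulating and analysing helping under threat with trial-wise RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing helping under threat with trial-wise RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`threatRSA` couples two components:

* a **synthetic-experiment generator** for a threat-imminence helping task
  — trial schedules, help/no-help decisions, shock outcomes, post-scan
  ratings, and ROI voxel patterns with a *planted* representational
  geometry; and
* an **RSA inference pipeline** — trial-wise neural representational
  dissimilarity matrices (RDMs), behavioral RDMs from ratings,
  second-order similarity by Kendall's tau, per-ROI linear models of
  helping percentage with joint FDR correction, and a predominance
  comparison of threat versus distress coding.

Because the generator plants known effects, the pipeline's statistical
machinery can be validated end to end: the planted link between
threat coding and helping must be recovered, and must vanish under a null
configuration.

## The task model

The simulated task mirrors a two-by-three within-subject design: 8 runs of
18 trials; each run holds one contiguous *distal* block and one contiguous
*imminent* block of 9 trials (which block comes first is randomized
independently per run and subject); each run carries 6 trials per threat
level (safe, 1 shock, 2 shocks), balanced 3/3 across the two blocks, with
level order shuffled within block. That yields 144 trials and 24 per
imminence-by-level cell.

Decision contingencies on shock trials: helping leads to both participants
being shocked with probability 0.70 (and neither otherwise); not helping
always shocks the co-participant and never the participant; a missed
response shocks both with certainty on any trial. Safe trials take an
arbitrary `safe_choice`. Missed responses default to probability 0, since
no miss rate is available to emulate; the option exists for robustness
experiments.

## The rating model

Post-scan ratings are latent Gaussian values, rounded and clipped to the
1–9 scale:

* **Distress** (one rating per trial clip): baseline 3.5, imminence effect
  0.418, level effects 0.279 (1 shock) and 0.559 (2 shocks), noise SD 1.5.
* **Felt threat** (one rating per level-by-imminence cue image): baseline
  2, level effects 2.255 and 3.92, an imminence increment of 0.9 applied
  to shock cues only, noise SD 1.0.

The condition effects are the fixed-effect estimates observed in the
empirical cohort this design emulates; the baselines and noise SDs are the
package's own choices, set so that ratings occupy the lower-to-middle part
of the scale with realistic overlap between conditions (clipping is rare
but possible). With noise disabled the generator is deterministic, which
the tests exploit.

## The neural model

For subject $s$, ROI $r$, trial $t$ and voxel $v$:

$$\beta_{tv} = a\, z(\mathrm{threat}_t)\, u_v + d\, z(\mathrm{distress}_t)\, w_v + \varepsilon_{tv},\qquad \varepsilon_{tv} \sim \mathcal N(0, \sigma^2),$$

where $u, w$ are fixed random unit-norm voxel patterns per (subject, ROI),
and $z(\cdot)$ standardizes, within subject, the trial-level rating of the
trial's cue (threat) or clip (distress). The threat signal is deliberately
driven by the subject's *own cue ratings* rather than the nominal level:
the pipeline compares neural RDMs against rating-derived RDMs, so recovery
of the planted geometry is well-posed.

Coding strengths $a$ (threat) and $d$ (distress) are folded-normal draws
per subject and ROI. Helping follows a logistic policy on shock trials:

$$P(\mathrm{help}) = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1\, a_{\mathrm{target}} + \gamma_2\, \mathrm{imminent}),$$

with the left amygdala as the default target ROI — the headline region of
the defensive-circuitry account this package operationalizes. $\gamma_2 > 0$
plants the behavioral tilt that makes "helps more when the threat is
imminent" the modal individual pattern.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `n_voxels` | 100 | typical anatomical ROI at 2 mm after masking, desk-scale |
| `a_mean`, `a_sd` | 1, 0.5 | clear threat coding with wide individual differences |
| `d_mean`, `d_sd` | 1, 0.4 | distress coding of comparable mean strength (no built-in predominance) |
| `noise_sd` | 0.12 | see below |
| `gamma0`, `gamma1` | −2.5, 2.5 | centres cohort helping near 50% and plants a strong coding–helping link |
| `gamma2` | 0.3 | modest imminence facilitation of helping |

The defaults were fixed by an a-priori power analysis: with 49 subjects
and the full 13-ROI FDR pool, the left-amygdala threat-similarity slope
must be recovered (positive and FDR-significant) in at least 80% of
cohorts. Two findings from that analysis shaped the choices. First,
`tau_threat` and `tau_distress` are strongly negatively correlated across
subjects (around −0.85) *by construction*: correlation-distance RDMs
normalize each trial pattern, so the two signals compete for the same
geometry. This collinearity, not sample size, is the main power limiter of
the per-coefficient test. Second, moderate pattern noise *helps*
identifiability: with very low noise the two similarities collapse onto a
one-dimensional function of the coding ratio $a/d$, and the subject-level
strength $a$ — which is what drives helping — becomes unrecoverable from
them. `noise_sd = 0.12` breaks that degeneracy while keeping the planted
geometry dominant.

## The analysis pipeline

1. **Neural RDMs** (`neural_rdm`): entry $(i,j)$ is $1 - r$, the Pearson
   correlation distance between the voxel vectors of trials $i$ and $j$;
   entries lie in $[0, 2]$. Trials with a constant voxel vector are a hard
   error naming the trial. Betas enter raw; no additional normalization is
   applied before the correlation.
2. **Behavioral RDMs** (`rating_rdm`, `trial_threat_ratings`): Euclidean
   distances between scalar ratings, taken raw (not standardized). Safe
   trials are *included*: their ratings exist, and with discrete 9-point
   ratings the variance they contribute is essential. Trials with missed
   responses also remain — the modelled window is the threat cue, not the
   response.
3. **Second-order similarity** (`second_order_similarity`): Kendall's tau
   on the RDM lower triangles, aligned by trial id (never by position).
   The default is tau-a, the recommended choice when candidate RDMs
   contain many ties, as rating-derived RDMs on a 9-point scale invariably
   do; tau-b is available by flag but is undefined for completely tied
   inputs (e.g. a constant-rating subject). The RSA is run separately for
   distal and imminent trials (72 each, 2,556 trial pairs per condition).
4. **ROI models** (`fit_roi_model`, `run_rsa`): per ROI, OLS of overall
   helping percentage (0–100 points) on `tau_threat`, `tau_distress` and
   imminence (0 = distal reference). Each subject contributes two rows
   with a duplicated outcome, exactly as the two-condition design implies;
   the non-independence is documented rather than corrected, and a
   cluster-robust (by subject) standard-error option exists but is off by
   default. p-values use the t distribution with $n - 4$ degrees of
   freedom.
   The pipeline is ROI-agnostic: any region with pattern inputs (e.g.
   exploratory temporo-parietal junction masks) can be analysed by adding
   it to `roi_list`, and the FDR pool follows the supplied list.
5. **FDR** (`fdr_adjust`): Benjamini–Hochberg across the 3 slope
   coefficients of all 13 models (39 p-values). Intercepts are excluded —
   the pool is meant to cover the substantive predictors — but pool
   membership is configurable (`fdr_pool = "all"`).
6. **Predominance** (`predominance_test`): per ROI and condition, a
   two-sided paired Wilcoxon signed-rank test of
   `tau_threat − tau_distress`, FDR-corrected across the ROI-by-condition
   cells. The test choice is a documented package decision (no canonical
   test is prescribed for this comparison) and is deliberately swappable;
   all-zero differences yield statistic 0 and $p = 1$ by convention.

## Numerical and engineering choices

* **Kendall's tau** is computed by an $O(n \log n)$ merge-sort (Knight)
  algorithm in C++, validated against an exhaustive $O(n^2)$
  pair-enumeration oracle on thousands of short vectors. Inside
  `similarity_table` an internal kernel exploits that rating-derived RDM
  entries take few distinct values: it sorts the neural vector once and
  counts concordances against both behavioral models by category in
  $O(nk)$; it is asserted to agree exactly with the public
  single-comparison path.
* **Correlation distances** use a scaled cross-product rather than
  `cor()`, which is algebraically identical and much faster over
  thousands of small matrices; values are clamped to $[0, 2]$ against
  floating-point spill.
* **Determinism**: every generator derives per-subject, per-component
  seeds from one master seed via a small modular hash, so cohorts are
  bit-reproducible and a subject's data do not depend on how many other
  subjects are simulated. The C++ pattern generator draws from R's RNG in
  a documented order.
* **Degenerate inputs**: constant trial patterns, missing ratings or cue
  entries, label mismatches between RDMs, rank-deficient model matrices,
  out-of-range p-values and non-binary masks are all hard, named errors
  rather than silent coercions.

## What the simulation does and does not show

The generator reproduces the design's factorial structure, the outcome
contingencies, the rating structure of the manipulation checks, and a
planted low-rank representational geometry with subject-varying coding
strengths. It does **not** simulate BOLD time series, hemodynamic
convolution, autocorrelated or spatially structured fMRI noise, run
effects, or motion; patterns are generated directly at the trial-wise beta
level, which is where the pipeline's inputs live. Passing tests therefore
validate the *analysis machinery* — RDM construction, tau, the linear
models, FDR behavior, and end-to-end parameter recovery under the stated
generative model — not the preprocessing pipeline of any real dataset, and
real-data effect sizes need not match the planted ones.

Problem sizes used by the test suite were chosen to keep a full run
desk-scale: the parameter-recovery study uses 200 cohorts of 49 subjects
(plus 200 null cohorts) at 100 voxels per ROI across all 13 ROIs; most
other properties are exercised on reduced designs (fewer runs, voxels or
subjects) where the property itself does not depend on scale.

## Known limitations

* The ROI linear model duplicates each subject's outcome across its two
  condition rows; classical standard errors are therefore optimistic.
  This mirrors the modelling convention the pipeline implements; the
  cluster-robust option quantifies the difference.
* tau-a values over heavily tied behavioral RDMs are diluted toward zero;
  comparisons between ROIs are unaffected, but absolute tau magnitudes
  should not be interpreted against conventional effect-size benchmarks.
* The volumetric reader consumes binary masks on the same grid as the
  beta volumes; it performs no resampling or registration.
* Reaction times are a constant-plus-noise placeholder; no latency model
  is implied.
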