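---
title: "Detecting responding-to-joint-attention events from eye-tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting responding-to-joint-attention events from eye-tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rjafinder)
```

## The measurement problem

Responding to joint attention (RJA) — following an actor's gaze or pointing
cue to the object it indicates — is measured here from 300 Hz binocular
eye-tracking of participants watching 12 short clips (6 *looking*, 6
*pointing*). The actor rests, cues the target during an action window, and
rests again. The analysis question is binary per clip and cumulative per
participant: did the gaze travel from the actor's face to the cued target
during the action window, and how many such face-to-target excursions
occurred?

`rjafinder` answers this with a fixed pipeline: binocular averaging → gap
filling → I-VT velocity classification → fixation aggregation → per-clip
windowing → a four-criterion scan over the fixation sequence → QC and
summaries. Every stage is deterministic given the data and configuration.

## The I-VT filter and its parameters

The velocity-threshold (I-VT) classifier assumes gaze alternates between
quasi-stationary fixations and fast saccades, so a single velocity cut
separates them. All six parameters live in `ivt_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `velocity_threshold_deg_s` | 30 | deg/s | fixation iff velocity strictly below |
| `velocity_window_ms` | 20 | ms | symmetric window for the velocity estimate |
| `gap_fill_max_ms` | 75 | ms | longest interpolated dropout |
| `min_fixation_ms` | 60 | ms | shortest retained fixation |
| `merge_max_gap_ms` | 75 | ms | temporal merge distance |
| `merge_max_angle_deg` | 0.5 | deg | angular merge distance |

These are the vendor-standard defaults for remote trackers of this class;
no noise-reduction smoothing is applied. Decisions that the defaults leave
open, resolved here:

* **The boundary velocity is a saccade.** "Below threshold is a fixation"
  is read strictly, so exactly 30 deg/s classifies as saccade; the boundary
  is unit-tested.
* **Window edges snap to the nearest recorded sample**, and the angle
  between the edge positions is divided by the *actual* elapsed time
  between those samples rather than the nominal window length. On a clean
  300 Hz grid the two coincide; with irregular timestamps the actual-time
  form is the unbiased estimate.
* **Velocity is undefined** — and the sample unclassifiable — wherever the
  sample itself or either window edge is invalid, or the window leaves the
  clip. Unfilled gaps therefore split fixations rather than silently
  bridging them.
* **Visual angles** come from 3-D eye-to-point vectors under a
  `viewing_geometry()` (default: 1920 × 1080 px, 509.8 × 286.7 mm, 650 mm
  viewing distance), assuming the screen is orthogonal to the gaze axis.
  The small-angle approximation agrees within 1% below 2°, which bounds the
  error of treating screen-plane pixels as angular positions.
* **Off-screen coordinates are retained** for velocity computation;
  fixation centroids landing off-screen are flagged, not clamped.
* **QC uses raw validity only.** The valid sampling rate counts samples
  with *both* pupils detected before any interpolation, so gap filling can
  never inflate data quality. Interpolated samples are tagged and excluded
  from the QC count by construction.

## AOI geometry

Face, target and non-target AOIs are polygons in screen pixels. Centres are
arithmetic means over *all pixels inside* the polygon (the mask semantics
of stimulus-annotation tools), radii are maximum centre-to-boundary-pixel
distances. A vertex-only mode exists for analytic checks; for convex
polygons the two radius definitions agree at the farthest vertex, which the
tests assert. A zero-length movement vector is assigned 0° against the
benchmark — a stationary step carries no directional evidence against the
face-to-target direction, and ties broken the other way would let duplicate
centroids veto otherwise valid sequences.

## The event detector

Within the action window (membership by fixation onset, closed interval; an
overlap policy is available), the scan opens a candidate at each fixation
inside 1.2 · R_F of the face centre, extends while each added fixation is
strictly closer to the target than the non-target and each movement vector
stays strictly below 90° to the benchmark, and closes at the *first*
fixation inside 1.2 · R_T of the target. Events never share fixations.

Design choices that were genuinely open:

* **Earliest termination.** Closing at the first target fixation yields
  minimal, unambiguous, non-nested events and a well-defined count. The
  alternative (extend while criteria keep holding, close at the last target
  fixation) is available as `detector_config(termination = "maximal")` for
  sensitivity analyses.
* **All comparisons strict.** Distances equal to the circle radius and
  angles equal to 90° fail; equidistant target/non-target ties fail
  criterion 3. Boundary cases are constructed exactly in the tests.
* **Counting.** Multiple events per clip are counted individually in the
  totals; a per-clip any-event flag is kept alongside for
  agreement-with-coders analyses.
* **Correctness.** The scan is proven against brute-force enumeration of
  all contiguous subsequences followed by the same
  earliest-start/earliest-end/non-overlap reduction, over 10⁴ seeded random
  layouts in the acceptance checks (and a smaller nightly version in the
  unit tests), plus monotonicity in the thresholds and invariance under
  rigid motion of fixations and AOIs together.

## Quality control

Per-clip valid sampling rates are averaged *unweighted* across the 12
clips: clips differ in length (5–7 s), but the inclusion rule treats each
clip as one unit of protocol compliance; a duration-weighted mean is
available behind an argument. Inclusion requires the average rate to be
strictly above 0.60 — the boundary participant at exactly 0.60 is excluded,
and both sides of the boundary are tested.

## Statistics

Cohen's kappa uses the marginal-product chance correction; the degenerate
case (both raters constant and identical) reports 1 under perfect agreement
and `NA` otherwise. The Mann–Whitney z uses the tie-corrected variance and
a 0.5 continuity correction (configurable); the effect size is
r = |z|/√(n₁+n₂). For small untied samples (both n ≤ 20) the reported p is
exact. The continuity-corrected normal approximation itself deviates from
the exact two-sided p by up to ≈ 0.03–0.04 at the smallest sizes
(n₁ = n₂ = 3), a property of the approximation verified by enumeration in
the test suite; consumers needing exact small-sample inference get it
automatically. Fisher's exact test follows the probability-mass two-sided
convention of mainstream statistical environments. Spearman correlations
use midranks, with Benjamini–Hochberg step-up q-values across each batch.

## The classifier

`fit_logistic()` fits `logit P(ASD) = b₀ + b₁·rate + b₂·events` by IRLS,
converging when the largest coefficient change drops below 1e-8 (cap 100
iterations). Complete separation is detected from diverging fitted
log-odds and reported as a distinct status instead of returning huge
coefficients. Evaluation mirrors the cohort protocol: a stratified 80/20
split (stratification is implied by preserved class ratios in the split
counts; plain random splitting is available), stratified 10-fold CV,
accuracy at the fixed 0.5 threshold, trapezoidal ROC/AUC, decile
calibration bins, and diagnostics computed from the IRLS weights —
standardized Pearson residuals, Cook's distances, per-feature VIF from
regressing each feature on the others, and a logit-linearity check
comparing the deviance of the linear model against quartile-binned
features. Every stochastic step takes a recorded seed.

## What the synthetic generator emulates — and what it does not

`simulate_session()` renders per-clip scanpath plans into 300 Hz binocular
samples: fixations are stationary segments with temporally correlated
AR(1) wobble (marginal SD 0.15° by default, autocorrelation 0.95 per
sample), transitions are minimum-jerk movements whose peak velocity
(1.875 · amplitude / duration) is forced above 300 deg/s, and track loss
is a two-state Markov process (bursty, mean burst 50 ms) hitting a
configured long-run rate — real dropout clusters, and the QC metric should
be exercised under clustering, not i.i.d. thinning. With probability
`p_rja` per clip (defaults 0.6 looking / 0.8 pointing, reflecting the
stronger salience of pointing cues) the plan is an RJA scanpath: a face
fixation, 0–3 forward intermediates, a target fixation, all onsets inside
the 2000–4000 ms action window; otherwise a distractor scanpath that stays
clear of the face circle. Both branches are *verified against the
detector's own criteria at generation time* (RJA plans must pass, no
distractor subsequence may pass), with clean margins — endpoints within
0.5 × the AOI radius, steps ≥ 80 px and < 70° to the benchmark — so that
rendering jitter cannot flip a planted outcome. Feature-level cohorts
(`simulate_cohort()`) draw the two features directly from group
distributions (ASD below TDC below TDA on both, negative-binomial event
counts with matched dispersion), or from a planted logistic model for
parameter-recovery tests.

The generator does **not** model pupil dynamics, vergence, blinks beyond
track loss, calibration drift, smooth pursuit, or head movement. Passing
tests therefore demonstrate correctness of the *pipeline* under controlled
kinematics — recall and false-positive rates on real recordings depend on
behaviour the simulator does not produce, and no claim is made of
reproducing cohort-level accuracies from undeposited participant data.

## Problem sizes and numerical notes

The validation suite uses 50 simulated participants × 12 clips for
end-to-end recovery, 10⁴ random layouts for detector–oracle equivalence,
20 cohorts of n = 5000 for coefficient recovery (chosen so the planted
odds-ratio interpretations — 2.29 per −0.1 sampling rate, 1.24 per event —
sit 3 standard errors inside the ±10% recovery band), and n = 400 for the
label-shuffled null AUC. IRLS weights are floored at 1e-10; probabilities
in deviance terms at 1e-300; `acos` arguments are clamped to [−1, 1];
exactly coincident points return an angle of exactly zero. Degenerate
inputs (empty AOIs, single-class labels, empty samples, zero age variance)
raise typed errors rather than propagating NaN.

## Known limitations

* AOIs are static per clip; a moving actor would need per-frame AOIs.
* Only face→target (RJA) sequences are detected; initiating joint
  attention and target→face returns are out of scope.
* The 60% inclusion rule and all thresholds are exposed but the defaults
  are the protocol's; changing them changes what an "event" means.
* The Mann–Whitney normal approximation is intrinsically a few hundredths
  off the exact p at the smallest sample sizes; exact p-values are used
  there instead.
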