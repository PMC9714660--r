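# rjafinder

Automated detection and quantification of **responding to joint attention
(RJA)** gaze events in eye-tracking recordings.

Responding to joint attention — following another person's gaze or pointing
cue to the object it refers to — emerges early in typical development and is
attenuated in autism spectrum disorder (ASD). In the paradigm this package
implements, participants watch short video clips of an actor who either
*looks at* or *points to* one of two on-screen objects while a remote eye
tracker records binocular gaze at 300 Hz. `rjafinder` turns those raw gaze
streams into interpretable quantities: fixations, face-to-target gaze-shift
events, a data-quality metric, group statistics, and a two-feature ASD/TDC
classifier. A seeded synthetic-session generator with ground truth makes the
whole pipeline testable end to end without any participant data.

The package is aimed at researchers analysing gaze-cueing / joint-attention
protocols who want a scriptable, reproducible alternative to manual frame
coding.

## The method

**Fixation classification (I-VT).** The two eyes are averaged into a
cyclopean stream (single-eye samples pass through; both-eye dropouts are
invalid). Gaps up to 75 ms are linearly interpolated. The angular velocity at
sample *i* is the visual angle between the gaze positions at the edges of a
20 ms window centred on *t_i*, divided by the elapsed time; samples with
velocity *v* < 30 deg/s are fixation samples, *v* ≥ 30 deg/s saccade
samples. Runs of fixation samples become fixations (centroid = mean
position); adjacent candidates within 75 ms and 0.5° merge, and candidates
shorter than 60 ms are dropped.

**AOI geometry.** Each clip has three areas of interest — the actor's face,
the target object and the non-target object. Their centres **F**, **T**,
**N** are the arithmetic means of all pixels inside the drawn polygons; the
radii *R_F*, *R_T*, *R_N* are the maximum centre-to-edge distances; the
vector **F→T** is the *benchmark vector*.

**RJA events.** Within each clip's action window, a sequence of consecutive
fixations *f_1 … f_k* (k ≥ 2) is an RJA event iff

1. ‖f₁ − F‖ < 1.2 · R_F,
2. ‖f_k − T‖ < 1.2 · R_T,
3. ‖f_i − T‖ < ‖f_i − N‖ for every i > 1, and
4. every movement vector f_i → f_{i+1} makes an angle < 90° with **F→T**.

A deterministic left-to-right scan extracts non-overlapping events (closing
each at the first fixation satisfying criterion 2); it provably equals
brute-force subsequence enumeration with the same selection rule.

**QC.** The *valid sampling rate* of a clip is the fraction of raw samples
with both pupils detected; participants whose unweighted mean across the 12
clips is not strictly above 60% are excluded.

**Statistics and classifier.** Percent agreement and Cohen's kappa against
manual coders; Mann–Whitney U with tie-corrected z and effect size
r = |z|/√N; Fisher's exact test; Spearman correlations with
Benjamini–Hochberg correction; OLS age trends. A logistic model
`logit P(ASD) = b₀ + b₁·rate + b₂·events` is fitted by IRLS with a
stratified 80/20 split, stratified 10-fold cross-validation, ROC/AUC,
decile calibration, and Cook's-distance / standardized-residual / VIF
diagnostics. Odds ratios are reported per −0.1 sampling rate and per
additional event.

## Worked example

```r
library(rjafinder)

clips <- default_protocol()                      # 12 clips, 6 looking + 6 pointing
geoms <- lapply(default_aois(clips), aoi_geometry)

ses <- simulate_session("P001", group = "TDC", clips = clips,
                        aoi_map = geoms, seed = 42)
fx  <- detect_fixations(ses$samples)             # I-VT filter
ev  <- detect_session_events(fx, clips, geoms, participant_id = "P001")
qc  <- qc_participant(ses$samples, clips$clip_id)
summarize_participant(ev, clips, qc, group = "TDC")
#> # A tibble: 1 × 7
#>   participant_id group avg_valid_sampling_rate n_events_total n_events_looking
#> 1 P001           TDC                     0.947              7                2
```

The summary row is the participant's feature vector: 94.7% of raw samples
had both pupils detected (included, > 60%), and 7 RJA events were detected
across the 12 clips (2 in looking clips, 5 in pointing clips), matching the
session's planted ground truth.

```r
coh <- simulate_cohort(n_per_group = 120, seed = 1)   # ASD lower on both features
res <- cmd_classify(dplyr::transmute(coh, participant_id, group,
                                     avg_valid_sampling_rate, n_events_total),
                    seed = 1)
res
#> <rja_eval> train acc 0.802 | test acc 0.729 | CV 0.801 +/- 0.089 | AUC 0.778 (seed 1)
tidy(res$fit)
#> # A tibble: 3 × 5
#>   term        estimate std.error statistic       p.value
#> 1 (Intercept)   11.7      1.93        6.05 0.00000000147
#> 2 rate         -11.4      2.15       -5.30 0.000000117
#> 3 events        -0.361    0.0600     -6.02 0.00000000178
```

Both coefficients are negative: a lower valid sampling rate and fewer RJA
events each raise the predicted odds of ASD. `autoplot()` methods draw the
ROC curve and calibration bins; `plot_scanpath()` overlays a clip's
fixations on its AOI layout.

A command-line wrapper (`inst/cli/rjafinder.R`) exposes
`simulate | detect | qc | stats | classify` subcommands over YAML/JSON run
configs.

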