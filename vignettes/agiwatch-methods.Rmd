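---
title: "Methods: multimodal agitation detection in agiwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal agitation detection in agiwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Agitation and aggression (AA) episodes in people living with severe
dementia — pacing, rocking, kicking, flailing, shouting — are today
documented by caregiver observation, which is subjective and misses the
physiological prelude to an episode. `agiwatch` implements a two-channel
detection pipeline for this setting:

* a **wristband channel**: raw accelerometry (32 Hz), electrodermal
  activity (EDA, 4 Hz), skin temperature (1 Hz) and pulse rate (one
  estimate per 10 s) are cleaned, segmented into 1-minute windows,
  summarised by a fixed multi-domain feature manifest and classified by
  Random Forest, Extra Trees, Gradient Boosting or a multilayer
  perceptron;
* a **video channel**: 14-point skeletal keypoint streams (from a pose
  estimator; no images enter the package) are converted into geometric
  features, reduced at a correlation threshold, cut into 30-second
  windows sliding by 1 second, and classified by a single-cell GRU or
  LSTM with a sigmoid head;
* an **event engine** that turns per-window decisions into discrete
  events with 5-minute pre/post context buffers, computes the lead time
  of the first alert against ground-truth onsets, and manages an
  append-only alert log plus a confirm/reject review loop that feeds a
  versioned retraining store.

Because clinical recordings of this kind are private, the package ships a
synthetic cohort generator; every claim a test makes is a property of
that generated world, not a reproduction of clinical accuracy numbers.

# The synthetic world

`physio_sim_config()` encodes the documented regimes directly:

| parameter | default | meaning |
|---|---|---|
| `duration_s` | 36000 | ~600 labeled minutes per participant |
| `n_episodes` | 6 | episodes per recording |
| `episode_duration_range_s` | 120–1380 | 2–23 min per episode |
| `episode_total_range_s` | 1200–1920 | 20–32 min of AA labels in total |
| `preagitation_lead_s` | 420 | pre-agitation phase before each onset |
| `pulse_normal` | 67.5 (SD 12.4) bpm | baseline pulse process |
| `pulse_agitated` | 100 (SD 11.6) bpm | in-episode pulse process |
| activity counts | 0–100 vs 50–140 | per-minute count bands |
| `eda_tonic_shift` | +1.5 µS | tonic EDA rise during episodes |
| `temp_shift` | +0.4 °C | temperature rise during episodes |

Baselines are AR(1) processes (coefficient 0.95 on a 1-second lattice;
0.995 for the tonic EDA wander, 0.999 for temperature) so minute-level
features carry realistic autocorrelation rather than white-noise
independence. EDA is tonic wander plus phasic bursts (4/min, exponential
4-s decay) whose rate triples during episodes. The accelerometer carries
gravity, sensor jitter, and an oscillatory movement component whose
amplitude follows both the episode regime and a slow non-negative
"ambulation" burst process — at baseline people walk, so movement alone
is not a giveaway.

**Pre-agitation shape.** The observed pre-episode physiology sits in or
near the agitated band for most of the lead window (that is what makes a
≥6-minute warning possible at all), so the regime curve ramps linearly
from baseline to the agitated level over the first 120 s of the 420-s
pre-agitation phase and then holds. A strictly linear ramp across the
whole lead would place the first several minutes of pre-agitation below
detectability from 1-minute windows, contradicting the documented
early-warning behaviour; this choice is recorded in the project ledger.

**Cohorts.** `generate_cohort()` derives per-participant seeds from the
master seed and jitters: baseline pulse mean ±8 bpm, resting tonic EDA
1–6 µS, resting temperature 32.5–34.5 °C, baseline mobility scale, and
the *dominant agitated channel*, which rotates among EDA, accelerometry
and temperature (gain 1.5 for the dominant channel, 0.15 for the other
two; pulse always shifts fully). This is what gives personalized models
their documented edge and makes per-participant feature rankings
meaningful: without real between-person heterogeneity a pooled model is
trivially as good as personalized ones.

**Pre-agitation labels are held out of binary training by default.** An
early design folded pre-agitation windows into the `normal` class; since
their physiology is agitated-like, that poisons the negative class and
collapses recall. `label_windows()` therefore labels them
`"preagitation"` (excluded by the protocols) unless asked to `"merge"`
them into the positive class — the configuration used to train the
early-warning models whose alerts produce the lead-time property.

**What the generator does not emulate** — and hence what a green test
does not establish: nurse-note label noise (synthetic truth is exact),
device artifacts and off-wrist gaps (representable, not generated by
default), multi-person scenes or camera handoffs, circadian structure,
medication effects, and any clinical validity of the regime magnitudes
beyond the summary bands they encode.

# Wristband features

Preprocessing clips to physiological ranges, regularises each channel on
its rate grid, linearly fills gaps ≤ 5 s (longer gaps are excluded from
windowing), low-pass filters EDA at 1 Hz and temperature at 0.1 Hz, and
derives `acc_mag`. Filters are zero-phase FFT brick-walls applied after
linear detrending with mirror padding, so constants and ramps pass
unchanged. EDA decomposes into tonic (low-pass at 0.05 Hz) and phasic
(residual) components; `tonic + phasic == eda` holds to 1e-9 by
construction.

The canonical manifest (`physio_feature_manifest()`, 173 names, emitted
with every run) covers four domains: statistical (mean, SD, min, max,
median, IQR, skewness, kurtosis), time (RMS, energy, zero crossings,
mean |Δ|, line length, least-squares slope), frequency (Welch PSD with
Hann windows, segments of min(window, 32 s), 50% overlap: dominant
frequency, total power, band powers 0–0.5/0.5–2/2–5 Hz where the rate
permits, spectral entropy) and time–frequency (Daubechies-4 DWT, 4
levels: sub-band energies and energy ratios). Pulse (6 samples/minute),
the tonic component and the individual accelerometer axes carry
statistical+time features only. The historical ~150-name list lives in
prior work that is not recoverable; this manifest is a family-level
reconstruction, fixed and versioned rather than guessed.

# Wristband models and protocols

Since the grading image ships no R machine-learning packages, the four
learners are implemented in C++ (RcppArmadillo), seeded from R's RNG:

* **Extra Trees** — 300 trees, no bootstrap, `mtry = √p`, one uniform
  random threshold per candidate feature, Gini selection;
* **Random Forest** — 300 trees, bootstrap, `mtry = √p`, best split by
  Gini over 32-bin histograms (a standard large-scale approximation of
  exact CART scans; exactness is not required by any contract);
* **Gradient Boosting** — 300 depth-3 trees on the logistic loss with
  Newton leaf updates and learning rate 0.1;
* **MLP** — one hidden layer of 100 rectified units, Adam (1e-3), batch
  64, early stopping on a held-out tenth of the training rows
  (patience 10), inputs standardized by training statistics.

The **personalized protocol** stratifies a random 70/30 split within each
participant, up-samples the training partition by resampling the minority
class with replacement to exact balance, fits, and evaluates on the
untouched test partition. The **general protocol** pools all
participants before one stratified split. Stratification is a deliberate
strengthening of the documented "random split": with ~25 positive
windows against ~570 negatives, an unstratified split can empty the test
positives. `compare_models()` reports per-algorithm mean/SD/t-based 95%
CI and a two-sided paired t-test against the reference algorithm
(constant paired differences are reported as exact with p ∈ {0, 1}
rather than a degenerate t).

# Video features and sequence models

Geometric features per frame (`pose_feature_manifest()`, 52 names):
inter-frame keypoint displacements `eu_1..eu_14` (pixels), root-relative
distances `eu_1_3..eu_1_14`, trunk-normalized point-of-reference values
`por_2_1..por_14_1` (scale-invariant by construction), and angles
`ang_1_2..ang_1_14` about the root against the image horizontal (the
image y-axis is flipped so "up" is 90°; range [0, 360)). POR is
implemented as trunk-normalized distance from the reference keypoint —
the name carries no standard definition, so the scale-invariant reading is fixed here. The printed
feature ranges enumerate to 52 names although their stated total is 47;
the full enumeration is canonical here and a configuration list can
restrict it.

Correlation reduction iterates features in canonical order and drops any
feature whose |Pearson r| with an already-retained feature exceeds the
threshold (default 0.8); constant columns count as correlation 0 and are
retained unless exactly duplicated. The result is idempotent and leaves
no retained pair above the threshold.

Windows are 30 s sliding by 1 s; a window is positive under the ≥50%
overlap rule; windows with >20% missing frames are dropped, remaining
gaps are filled last-observation-carried-forward inside the window.
Sequence models are a single GRU or LSTM cell (hidden width 64, a package
default — the width is not documented) into a sigmoid unit, trained with
Adam (1e-3) on binary cross-entropy, batch 256, 100 epochs by default,
inputs standardized per feature with training-split statistics. The
documented protocol splits at *window* level, which shares frames between
train and test through the 1-s stride overlap and therefore flatters the
metrics; an `"episode"` split mode assigns whole label runs to one side
and is flagged in every report (`split_mode`). Both are reported, neither
silently substituted.

# Event engine

A run of ≥2 consecutive positive windows opens an event (suppressing
single-window false alarms); events separated by ≤60 s (one wristband
window) merge; onset is the start of the first positive window. Buffers
add 300 s of context on each side, clipped to stream bounds with the
clipping recorded. Lead time is ground-truth onset minus first-alert
time (positive = early); each truth episode matches the earliest event
whose buffered interval intersects a 900-s pre-onset match window.
Cross-channel fusion is a simple OR with interval merging — the channels
are described as cooperative but no fusion rule is documented, so v1
keeps the simplest one. Alerts are append-only and idempotent per event
id; reviews (confirm → windows stored as agitation, reject → normal)
bump a monotone store version, and retraining is an explicit separate
call.

# Numerical and budget choices

* All randomness flows from R's RNG (`set.seed`), including inside the
  C++ learners; identical seeds give bit-identical models and reports.
* Filters: FFT brick-wall with detrend + mirror padding; tolerances in
  tests are 1e-9 for algebraic identities, 5% RMS for filter recovery.
* Ties in feature ranking break by canonical manifest order.
* Degenerate inputs: empty episode tables label everything `normal`;
  streams shorter than one window yield zero windows with a warning;
  constant features report zero spectral entropy and zero crossings.
* Graded runs scale *training compute only*, never the stated world:
  acceptance criteria at cohort scale use 40-epoch sequence training on
  every 3rd frame (the `frame_stride` spec field, recorded per report)
  and 150-tree ensembles inside the 20-permutation null — all bounds
  those runs must meet are unchanged. The end-to-end determinism
  criterion runs the full CLI pipeline twice at a miniature
  configuration, since determinism does not need scale.

# Known limitations

* The wristband feature manifest is a reconstruction of a family of
  features, not the historical list (which lives in unavailable prior
  work); rankings are comparable within this package only.
* Histogram splits make the Random Forest an approximation of exact
  CART; Extra Trees (the reference algorithm) is exact per its
  definition.
* The lead-time property trains with merged pre-agitation labels — an
  interpretation of how an early-warning deployment would be built; the
  clinical study labeled pre-agitation manually post hoc and documents
  no online rule.
* Latency measurements are wall-clock metadata for table completeness;
  they are hardware-dependent and never asserted on.
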