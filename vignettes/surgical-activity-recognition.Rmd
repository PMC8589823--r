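---
title: "Unsupervised surgical activity recognition: models, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised surgical activity recognition: models, design choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
probabilistic model and its assumptions, the self-supervised pretext task,
the representation-analysis chain, the synthetic world the package is tested
in, and the numerical conventions that make the pieces fit together
deterministically. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## 1. Problem and pipeline

A trajectory from a surgical training simulator is a pair of time-aligned
streams: grayscale video frames and a multichannel categorical sensor stream
(pedals, valves, discretized tool position). The task is per-frame
recognition of the six activities of a simulated hysteroscopic myomectomy —
diagnosis, position hysteroscope, cutting, coagulation, clear view, handle
chips — with essentially no annotated training data. The pipeline is

1. train a video-only network on the self-supervised *remaining surgery
   progress* (RSP) task,
2. mine its internal activations for units that encode workflow events,
3. convert the best unit into a latched binary observable ("diagnosis has
   ended"), and
4. decode activities with an explicit-duration hidden semi-Markov model
   (HSMM) whose observables are the sensor channels, optionally augmented
   with that learned observable.

## 2. The explicit-duration HSMM

**Semantics.** The transition matrix has a zero diagonal: a state never
transitions to itself, and dwell time is governed entirely by the duration
model. This is the standard explicit-duration convention and the only
coherent reading of a categorical transition model with no self-loops.

**Durations.** Dwell times are negative binomial with per-state `(r, p)`,
*shifted* to support `d ∈ {1, 2, ...}` (an activity occupies at least one
frame) and renormalized over `{1, ..., dMax}`. The negative binomial is
chosen for its ability to express the large between-trial variance of
activity durations; `r = 1` recovers the geometric dwell of an ordinary
HMM. The default truncation bound `dMax` is the smallest duration whose
cumulative untruncated mass reaches 0.999, maximized over states — the
bound is a computational device, not a modeling statement, so it is placed
where it removes at most 0.1% of mass.

**Emissions.** Channels are conditionally independent given the state: one
categorical table per state and channel, log-probabilities added across
channels. This matches observables that are physically distinct switches
and discretized positions.

**Initialization.** Transition rows, initial distribution and duration
parameters are supplied by configuration (in the benchmark they are derived
from the generating procedure model, the way a domain expert would set
them). Only emissions are estimated, as Dirichlet-MAP estimates from a
single annotated sequence:
`B[s][c][v] = (n_scv + α_v − 1) / (N_sc + Σα − K)`. With `α = 1` this is
the empirical frequency; `α > 1` keeps unseen symbols at small positive
probability. `α < 1` is rejected (the MAP mode does not exist there), and a
state absent from the annotation requires a strictly regularizing prior.

**Inference.** `viterbiDecode()` maximizes over segmentations with the
explicit-duration dynamic program; `sequenceLogLik()` sums over them with
the forward recursion in log-sum-exp arithmetic. Numerical conventions:

* all computation in log space; per-segment emission sums come from
  cumulative sums, with zero-probability frames tracked in a separate
  counter so that `-Inf` never enters a cumulative sum (a `-Inf − -Inf`
  would poison later segments);
* ties are broken toward the lower state index, then the shorter duration.
  With categorical observations *exactly* tied optima are common (swapping
  a boundary between two frames with identical symbols and compatible
  durations can leave the joint probability unchanged), which is why the
  oracle tests assert that the decoded path attains the optimum rather
  than that it equals one specific optimal path;
* the final segment is scored with its full (renormalized) dwell pmf, the
  *censor-free* convention, consistently in the sampler, the forward pass
  and Viterbi so that the exhaustive-enumeration oracle closes. A survival
  term `P(D ≥ d)` is available via `finalSurvival = TRUE` for users who
  prefer censored scoring of the last activity;
* unseen symbols are a hard error by default; `smooth` redistributes a tiny
  probability mass (e.g. `1e-8`) uniformly for robustness runs.

No EM re-estimation is performed after MAP initialization: with a single
annotated sequence and manually set structural components, unsupervised
re-estimation would mostly re-fit the emission tables to the decoder's own
beliefs; initialization-only is the conservative default and keeps every
reported result attributable to the stated components.

## 3. The RSP network

The pretext target is `y_t = 1 − t/τ` with `t` 1-based, so `y_τ = 0`
exactly and labels fall in `[0, 1)`. The desk-scale architecture is a
three-convolution encoder (3×3 kernels, stride 2, padding 1; 8, 16, 16
channels) on 16×16 grayscale frames, a linear projection to a width-16
feature vector, a single GRU layer of width 16, and a head of three fully
connected layers (PReLU after the first two, sigmoid after the last, one
output). An LSTM decoder is available; `alexnet_like` / `resnet18_like`
encoder names are configuration hooks for externally supplied pretrained
backbones and error without a weight source. Frames at 2 fps and 16×16 are
the package's desk-scale working point; resolution and widths are
configurable upward.

Training minimizes the mean absolute error with Adam (default) or RMSProp,
one whole sequence per optimizer step — progress is a sequence-level
quantity and truncation would corrupt the labels. The desk-scale learning
rate default is `1e-3`; `1e-5` is the appropriate order for full-scale
pretrained encoders. Splits are by trajectory, never by frame, to avoid
leakage of within-sequence correlation. All forward/backward passes are
hand-written matrix algebra (im2col convolutions, BPTT through the gates)
and are verified against central finite differences in
`test-nn-gradients.R`; training, initialization and splits are fully
seeded.

The useful baseline for the MAE is the constant prediction 0.5: for labels
uniform on a grid its expected MAE is ~0.25, so any model below that has
learned something, and the acceptance suite requires held-out MAE < 0.15 at
the toy conditions (20 sequences of ~45 frames, 40 epochs).

## 4. Representation analysis and the event observable

`extractActivations()` records per-frame values of any layer or gate
(update/reset gates for GRU; input/forget/output gates and cell for LSTM),
unit-addressable by column, read-only. PELT with a kernelized mean-change
cost segments those traces; `calibratePenalty()` chooses the penalty by
bisection so that a target average number of change points (10 by default,
keeping a manual review tractable) is detected. The linear kernel
(within-segment variance) is the default; an RBF kernel with median
heuristic bandwidth is available because the cost family is defined for any
bounded kernel. Channels are standardized per trajectory before costing —
activation scales across units are arbitrary — and this is switchable.
Change points are reported as 0-based first indices of new segments,
matching the half-open segmentation convention. The PELT implementation
defers candidate removal by `minSegment` frames after the domination test
fires; with a minimum segment length the textbook immediate removal can
exclude a candidate that is still needed for the next few frames, and the
deferral restores exact equivalence with unpruned optimal partitioning
(asserted by the test suite).

Unit ranking scores each unit by the standardized mean shift of its trace
across the known event frame (windowed, pooled-SD denominator, averaged
over trajectories). Because ranking alone is a screening statistic, the
pipeline then *selects* among the top five units by how well their detected
onsets agree with the known event frames on the training trajectories —
the automated counterpart of the manual verification step that sits between
ranking and feature construction in the original procedure. Held-out
trajectories are never used for selection.

The onset detector (`buildEventIndicator()`) offers two rules:

* **jump** (default): the onset is the largest local mean shift
  (`m`-frame window on each side), accepted if it exceeds the median local
  shift by `k` median absolute deviations. This rule is *trend-robust*: a
  progress-regression network's activations carry a slow monotone trend by
  construction, and a trend contributes the same offset to every local
  shift, so it cancels out of the comparison. A plain baseline threshold,
  in contrast, is crossed by the trend itself at a point unrelated to the
  event.
* **threshold**: first sustained exceedance (`m` consecutive frames) of
  `baseline mean + k·sd` over the first `b` frames — appropriate for traces
  that are stationary before the event, and the rule used in the
  synthetic-step tests.

Defaults are `k = 3`, `m = 3` (`b = 10` for the threshold rule). The
indicator latches: 0 before the onset, 1 afterwards. Attached to the sensor
stream it becomes one extra binary categorical channel.

## 5. The synthetic world

The generator emulates a cohort of simulator trajectories, with defaults
frozen as the package's study conditions:

* **Procedure model.** Every trajectory opens with a diagnosis (the only
  state with initial mass), proceeds through an operative loop of position
  hysteroscope / cutting / coagulation / clear view, and terminates with
  handle chips (absorbing). Mean dwell times at 2 fps: diagnosis 16 frames,
  position 4, cutting 6, coagulation 4, clear view 4, handle chips 9, with
  small negative-binomial `r` (high dispersion) on diagnosis and handle
  chips. The opening dwell has a floor of 4 frames (2 s): a sub-second
  initial inspection is unphysical. Expected trajectory length is ~50
  frames (`expectedTrajectoryLength()` gives the closed form from the
  absorbing-chain fundamental matrix).
* **Sensors.** Four categorical channels (two pedals, a three-state valve,
  a four-zone tool position). The pedal-free activities — diagnosis,
  position hysteroscope, handle chips — share *identical* emission tables
  (`ambiguityPairs`), so the diagnosis/position boundary and the
  position/chips distinction are invisible to sensors alone. This is the
  central ambiguity the learned observable is meant to break.
* **Video.** Mean intensity drifts linearly with progress (0.25 → 0.65), a
  per-trajectory illumination offset (sd 0.04) emulates lighting variation
  between recordings, pixel noise has sd 0.02, and a bright blob covering
  40% of the frame side appears in the bottom-right corner from the
  diagnosis end onward. Two of these choices matter and were made
  deliberately: without illumination variation a single frame's mean
  intensity is a perfect progress readout and the network has no incentive
  to encode milestone events at all; and the blob must occupy a substantial
  image area, as an instrument entering the view does — with a marginal
  blob, no gate unit encodes the event and the analysis chain has nothing
  to find.
* **Benchmark cohort** (`benchmarkGeneratorConfig()`): 19 trajectories, one
  of which is "annotated" — chosen as the trajectory whose scarcest
  activity has the most frames, since an expert would annotate a
  representative trial and a trial with e.g. three handle-chips frames
  cannot initialize that activity's tables. Dwell means are doubled
  relative to the toy set so the annotated trial contains enough frames per
  activity for MAP initialization, and the diagnosis dispersion is raised
  (`r = 2`): occasional short diagnoses are precisely what makes the
  starting activity ambiguous for a sensor-only model. The decoding HSMMs
  take the procedure model's transitions and durations, a uniform initial
  distribution (the starting activity is treated as unknown at decode
  time), a proper uniform row for the terminal activity, and MAP emissions
  with `α = 2` on sensor channels. The appended indicator channel uses
  `α = 1.1`: it is a designed observable with known semantics, and heavier
  smoothing would penalize whichever state happens to have fewer annotated
  frames by a constant per frame.

Reproducibility: every trajectory derives its own seed from the master seed
and its index through a fixed counter scheme, so datasets regenerate
bit-identically and independently of generation order.

**What the generator does not emulate.** Photorealistic anatomy, continuous
sensor kinematics, event-driven sensor sampling (streams are emitted
frame-aligned; the resampling rule of real recorders is not modeled),
annotation noise, and operator-specific style. Passing the synthetic
benchmark therefore demonstrates that the *chain* works when its premises
hold — a progress-learnable video signal, a visually salient milestone, and
sensor-ambiguous activity pairs — not that it will work on any particular
real recorder's output.

## 6. Evaluation conventions

IoU is computed on frame sets, which makes it symmetric and invariant to
how intervals are split. When an activity occurs in neither segmentation
the score is 1 (with a flag to exclude such trajectories from the mean);
occurring in exactly one scores 0. Spread is the sample (n−1) standard
deviation, matching the conventional "mean (sd)" presentation, switchable
to the population formula. `compareModels()` produces the side-by-side
table and timeline plots (horizontal activity bars per trajectory and
model).

## 7. Problem sizes and determinism of the shipped checks

The test suite and acceptance script use: 200 random small HSMMs (≤ 3
states, ≤ 8 frames, `dMax ≤ 4`) against exhaustive enumeration; 100 random
series (length ≤ 50) against unpruned optimal partitioning; 50 sampled
sequences of 300 frames for parameter recovery; 20 toy sequences (~45
frames, 16×16) for RSP training; and the 19-trajectory benchmark cohort for
the model comparison. These sizes keep a full run in the order of a minute
on one CPU while leaving every property with a comfortable margin. All
stochastic steps are seeded; the acceptance script derives every seed from
its `--seed` argument.

## 8. Known limitations

* The direction of the model comparison (update-gate HSMM above sensor
  HSMM for both scored activities) is a *stochastic* property of cohorts:
  in occasional cohorts where the sensor model happens to make no start
  misclassification, the handle-chips scores of the two models can tie.
* The quality of the learned event unit varies across training runs; the
  training-set selection step picks the best available unit, but a weak
  training run yields a weak indicator. The benchmark's `"planted"` mode
  exists to separate HSMM-level questions from representation-learning
  variability.
* Emission models are categorical only; continuous observables must be
  discretized upstream.
* No EM/Baum-Welch re-estimation; the package deliberately stops at MAP
  initialization (Section 2).
* The hand-written network is adequate at desk scale but makes no claim to
  GPU-class performance; full-resolution video would require an external
  training stack feeding traces into the same analysis chain (CSV
  interchange is provided).
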