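---
title: "Decoding whisker stimuli from laminar LFPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding whisker stimuli from laminar LFPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdecode)
```

# The problem

A head-fixed, water-restricted mouse performs a go/no-go detection task: a
single whisker receives a 60 Hz sinusoidal vibration lasting 100 ms at one of
five intensities (20-100% of maximum deflection), or no vibration at all
(catch trial, 0%), and the animal reports detection by licking a water spout
within 500 ms. A laminar silicon probe in the corresponding barrel-cortex
column records the local field potential (LFP) across cortical layers 2/3 to
6 at 1 kHz. Each trial spans -420 to +120 ms around stimulus onset; the
epoch from -400 to 0 ms is spontaneous ("PRE") activity, 0 to +100 ms is
the evoked ("PERI") response.

`lfpdecode` implements, end to end and on synthetic data, the analysis such a
recording supports: trial quality control, causal filtering, RAW and FFT
feature extraction, a benchmark of six lightweight classifiers — including a
from-scratch spiking Liquid State Machine (LSM) — under leave-one-mouse-out
bootstrap validation, and calibration analysis for imbalanced deployment.

Two binary tasks are studied. *Stimulus detection* (SD): was a stimulus
presented (intensity > 0)? *Response prediction* (RP): did the animal lick
within the +100 to +500 ms window of opportunity?

# The synthetic cohort generator

`generate_cohort()` stands in for the recordings and defines the conditions
every downstream test runs under. What the experimental design fixes is
taken as given: 50 catch + 5 x 50 stimulus trials per session in randomized
order (so 5/6 ≈ 83% of trials carry a stimulus), 32 electrodes at 25 µm
spacing, a response rate that rises monotonically with intensity above a
false-alarm floor on catch trials, and an evoked LFP deflection that troughs
5-10 ms after stimulus onset, strongest in layer 4.

What no experimental report specifies, the generator fixes once:

* **Background activity** is a first-order autoregressive process per
  channel (coefficient 0.9 at 1 ms steps, stationary SD 0.1 mV) with 20% of
  innovation variance shared across channels. AR(1) is the simplest process
  with realistic short-range autocorrelation; the shared component mimics
  volume conduction.
* **Evoked kernel**: a difference of exponentials (rise 2 ms, decay 15 ms)
  normalized to trough at 7 ms post-onset, amplitude 0.8 mV at 100%
  intensity in L4 and linear in intensity. The depth profile is a sum of
  Gaussian bumps (SD 90 µm) centered on each layer's representative
  channel with relative amplitudes L2/3 0.6, L4 1.0, L5 0.7, L6 0.45 —
  a focal L4-dominant generator whose spatial curvature, and hence the CSD
  sink, is deepest at the L4 channel.
* **Lick latencies** are 100 ms plus a log-normal delay (median ≈ 130 ms),
  placing most responses inside the window of opportunity.
* The optional 60 Hz stimulus-following component is **off by default**;
  such oscillatory signatures are inconsistent across recordings and the
  RAW/FFT comparison is cleaner without them.
* **Artifacts** are injectable, not spontaneous: amplifier saturation
  (±2.5 mV pulse), a movement burst (a 60 ms high-amplitude transient
  common to all electrodes), continuous 50 Hz line noise (0.4 mV), and an
  early lick with a broadband muscle transient.

What the generator deliberately does *not* model: spiking units, biophysical
cortical dynamics, whisker kinematics, attentional brain states, or
inter-session electrode drift. Passing tests on this data therefore
demonstrates that the pipeline's machinery is correct and recovers planted
structure — not that real awake-mouse LFPs are decodable at any particular
accuracy.

# Quality control

Four trial filters operate on the full -420 to +120 ms range
(`filter_trials()`); a trial survives only if all four pass.

* **Saturation**: any sample at |v| ≥ 2 mV.
* **Bursts**: moving 20 ms windows (10 ms stride) in which *all* electrode
  pairs correlate (Pearson). The threshold is the one genuinely open choice:
  the stereotyped evoked response is itself a near-common waveform across a
  laminar probe, and on clean 100%-intensity trials the minimum pairwise
  window correlation reaches ~0.94. The default threshold is therefore
  r ≥ 0.95, above evoked activity but below injected movement bursts
  (≥ ~0.98). A pair involving a constant channel scores 0, so degenerate
  windows cannot trip the filter.
* **Line noise**: rectangular-window periodogram over the QC window; flag
  when power within ±1 Hz of 50 Hz exceeds 25% of total 1-150 Hz power on
  any channel. With 540 samples at 1 kHz, 50 Hz falls exactly on DFT bin 27,
  so a pure 50 Hz contaminant concentrates all its power inside the band —
  a tapered or segment-averaged estimate would leak power out of it, which
  is why the plain periodogram is used.
* **Early licks**: lick latency in [0, 100) ms; licking artifacts make these
  trials unusable.

At these defaults the false-rejection rate on clean generated trials is
under 5% and each injected artifact type is detected above 95% — both are
asserted by the test suite at n = 1,000.

# Filtering, CSD and layer assignment

LFPs are filtered causally (`apply_butterworth()`): first-order Butterworth
low-pass at 150 Hz, then a band-stop removing 47-53 Hz, design order 6
("order" here is the prototype order passed to the design; the realized
band-stop transfer function is order 12). Zero initial conditions mean the
first samples of each trial carry the transient — accepted, because train
and test trials are processed identically. One numerical point matters: a
single order-12 difference equation loses the notch to coefficient rounding
(attenuation only ~0.03 at 50 Hz); the filter is therefore realized as a
cascade of second-order sections from the zero-pole design, which keeps the
50 Hz response below 10^-8. `butterworth_response()` exposes the designed
magnitude response.

`compute_csd()` is the plain second spatial difference along depth
(sink-negative convention; no Vaknin padding or spatial smoothing — the
full CSD methodology is out of scope here). `assign_layers()` puts L4 at the
most-negative CSD value within the first 25 ms post-onset (ties go to the
shallowest channel), and places L2/3, L5 and L6 at fixed depth offsets
(-200, +175, +375 µm) from it, mirroring depth-based estimation of the
deeper borders. On the default generator geometry this recovers the
ground-truth layer map exactly.

# Features and scaling

RAW features are the filtered trace itself at 1 kHz: 400 samples (PRE),
100 (PERI), 500 (FULL), per layer; the four-layer concatenation (ALL)
quadruples each count. FFT features are single-sided amplitude spectra with
bins kept up to 147.5 Hz for PRE (2.5 Hz spacing, 60 features) and 140 Hz
for PERI (10 Hz spacing, 15 features); FULL transforms the two epochs
separately and concatenates (75). "Strength" of a component is defined as
2|X_k|/N for k ≥ 1 and the signed X_0/N at k = 0, so the 0 Hz feature
equals the window mean exactly. The caps are applied as Hz thresholds, so a
truncated PERI window (the signal-length sweep) recomputes its bin count
gracefully. Feature order is layer-major (L2/3, L4, L5, L6), PRE before
PERI, ascending index.

Min-Max scaling is fit on training rows only and maps training minima and
maxima to 0 and 1; test values are not clipped. A constant training column
maps to 0 with a warning. A mutation test asserts that perturbing test rows
never changes the fitted scaler.

# The Liquid State Machine

The LSM is built from scratch (`build_reservoir()`, `simulate_reservoir()`,
`fit_readout()`): 135 leaky integrate-and-fire neurons on a 3 x 3 x 15
grid, 80% excitatory, connected with probability
`C_pair * exp(-(d/lambda)^2)` (C = 0.3/0.2/0.4/0.1 for EE/EI/IE/II, lambda =
2 grid units — the classical construction). Weight magnitudes are
half-normal around 0.12; inhibitory outgoing weights are negative with
twice the scale, balancing the 80/20 split. The membrane update is explicit
Euler at dt = 1 ms (aligned with the 1 kHz LFP):
`v <- v + (dt/tau_m)(-v + input + recurrent)`, threshold 1, reset 0,
refractory 2 ms, one-step spike propagation delay. Spikes are low-pass
filtered (`s <- s exp(-dt/tau_s) + spikes`) and the final-time filtered
state feeds a ridge-penalized logistic readout.

Two defaults deserve justification:

* **Input encoding**: Min-Max-scaled RAW traces are injected as analog
  currents onto a random 30% of neurons through fixed positive per-neuron
  gains (U(0.5, 1.5), overall gain 6 threshold units). Scaled inputs are
  non-negative, so negatively signed input weights would silence their
  neurons and halve the effective input dimension; positive gains keep the
  map linear (zero input ⇒ zero current) and every input neuron active.
  FFT vectors are distributed cyclically over the input neurons and held as
  constant currents for 50 steps — no spike pre-coding scheme is invented.
* **State filter tau_s = 800 ms**: the evoked response occupies the first
  ~30 ms of the 100 ms PERI window. With a fast filter (say 20 ms) the
  discriminative state has decayed by e^(-90/20) ≈ 1% at readout time and
  held-out accuracy stalls near 0.78. A filter much slower than the window
  makes the final-time state a near-uniform leaky spike count over the whole
  window — the statistic that actually carries the evoked information here —
  and held-out accuracy rises to ~0.85-0.95 across generator seeds. The
  readout stays strictly final-time (dimension = number of neurons, plus
  intercept).

Inference is noise-free; (config, seed, data) fully determine the model and
its predictions. A diagnostics warning fires if the mean reservoir firing
rate leaves the 1-100 Hz band. The single-neuron dynamics are pinned by
tests to the analytic membrane solution (no-spike regime, 10^-6 relative)
and to the closed-form inter-spike interval
`tau_m log(I/(I - theta)) + refractory` within one time step.

# Baselines

Five non-spiking classifiers share the LSM's fit/predict-probability
contract (`build_classifier()`): a decision tree (rpart), random forest
(ranger), gradient-boosted trees (xgboost), ridge-penalized logistic
regression (glmnet), and a ROCKET-style random-convolutional-kernel
transform implemented in-package (random length/dilation/padding kernels
with centered weights, max and proportion-of-positive pooling, ridge
logistic readout; multivariate input mixes a random channel subset per
kernel). Implementing the kernel transform in-repo keeps the
inference-runtime accounting honest — the transform cost is paid at both
training and prediction time. Hyperparameter grids are small (≤ 12 points)
and documented in `default_grid()`; the GLM grid spans four orders of
magnitude of penalty.

# Validation design

`make_split_plan()` builds leave-one-mouse-out splits: all trials of one
mouse form the test set; the remaining mice supply training data. Per
held-out mouse, 10 bootstrap samples are drawn, giving 40 evaluations per
scenario-algorithm for a 4-mouse cohort. Bootstrap seeds derive only from
(plan seed, mouse, bootstrap index), so different algorithms receive
byte-identical training multisets and accuracy differences can be compared
pairwise (Wilcoxon signed-rank on the 40 aligned pairs).

Order of operations per evaluation, all on training mice only: balance
classes by downsampling the majority (so chance is 50%), draw the bootstrap
with replacement to the balanced size, fit the Min-Max scaler on the
bootstrap multiset, tune by stratified 3-fold grid search (ties go to grid
order), refit the winner on the full multiset, evaluate on the held-out
mouse. Balancing precedes bootstrapping so every training multiset keeps
the 50% positive rate; testing sets are balanced by default too (the
benchmark's chance level), with the natural class mix retained in the
imbalanced-data analysis. Accuracy uses a fixed 0.5 threshold —
decision-threshold optimization is explicitly out of scope.

Metrics are computed in-package and pinned to brute-force oracles in tests:
trapezoidal ROC AUC (equivalently the tie-corrected Mann-Whitney
statistic), average-precision PR AUC, and the Brier score. The Wilcoxon
implementation drops zero differences (classic convention, count reported),
uses the exact signed-rank null up to 25 untied pairs and a tie- and
continuity-corrected normal approximation beyond. Fisher's exact test
against chance builds the 2 x 2 of observed vs expected-by-chance correct
counts.

`platt_calibrate()` holds out a stratified 33% of the training set, refits
the primary model on the remaining 67%, and fits a univariate logistic map
from hold-out probabilities to labels; the calibrator is monotone and is
applied to test probabilities before any metric. On synthetically
overconfident probabilities it reduces the Brier score; on well-calibrated
ones it moves it by less than 0.02 (both asserted at n = 2,000).

# Problem sizes and numerical choices

The test suite and the acceptance script run on scaled-down cohorts chosen
once: 4 mice x 1 session, 8 channels at 100 µm (still spanning all four
layers), 12-or-fewer repeats per intensity, and 3-10 bootstraps depending
on what the check needs. Control analyses (the pre-stimulus negative
control, the signal-length sweep) fix tuning to a single documented grid
point, since their conclusions do not depend on tuning. The full-size
defaults (32 channels, 50 repeats, 10 bootstraps) remain the generator's
and planner's defaults.

Other numerical conventions: all windows are half-open `[start, end)` in ms
with 0 at stimulus onset (this is what makes the 400/100/500 feature counts
exact); RP labels licks in [100, 500) ms and requires early-lick trials to
be excluded upstream; degenerate CSD profiles (no sink above 10^-12) raise
an error rather than guessing; equal sinks resolve to the shallowest
channel; constant scaler columns map to 0.

# Known limitations

The generator's evoked response is deterministic given intensity — real
trial-to-trial amplitude variability, adaptation, and state dependence are
absent, which makes the synthetic SD task easier than the real one at
matched SNR. Layer assignment assumes the probe spans all four layers with
a single dominant sink. The RP task inherits its signal entirely from the
SD structure (licks are driven by intensity through the psychometric
curve), so RP accuracies on synthetic data mainly exercise the plumbing.
Runtime measurements are wall-clock and hardware-dependent; only their
relative ordering and the per-sample normalization are meaningful.
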