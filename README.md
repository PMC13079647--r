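# lfpdecode

Decoding whisker stimulation from laminar local field potentials (LFPs) of
mouse barrel cortex with lightweight classifiers, including a from-scratch
spiking Liquid State Machine (LSM).

## The problem

In a go/no-go detection task, a head-fixed mouse reports a 100 ms, 60 Hz
single-whisker vibration (intensity 0-100% of maximum deflection; 0% =
catch trial) by licking within 500 ms. A laminar probe records the LFP
across cortical layers L2/3-L6 at 1 kHz over -420 to +120 ms around
stimulus onset. Two binary decoding tasks arise:

* **SD** (stimulus detection): was a stimulus presented?
* **RP** (response prediction): did the animal lick within the +100 to
  +500 ms window of opportunity?

`lfpdecode` implements the full analysis pipeline on synthetic cohorts that
emulate these recordings: a laminar LFP generator with a stereotyped evoked
response (negative deflection troughing 5-10 ms post-onset, largest in
layer 4) and monotone psychometric behavior; trial quality control
(saturation, bursts, 50 Hz line noise, early licks); causal Butterworth
filtering (150 Hz low-pass, 47-53 Hz band-stop); CSD-based layer
assignment; RAW and FFT features over PRE `[-400, 0)`, PERI `[0, 100)` and
FULL windows with train-anchored Min-Max scaling; six classifiers (DT, RF,
XGB, ROCKET-style kernels, ridge-logistic GLM, spiking LSM) under a shared
fit/predict-probability contract; leave-one-mouse-out bootstrap validation
with class balancing and 3-fold grid search; ROC/PR/Brier metrics, Platt
calibration, Wilcoxon signed-rank and Fisher exact tests.

The LSM is the core model: 135 leaky integrate-and-fire neurons on a
3×3×15 grid (80% excitatory), distance-dependent connectivity
`C·exp(-(d/λ)²)`, analog current injection of the scaled LFP trace at
dt = 1 ms, and a ridge-logistic readout of the exponentially filtered spike
trains at the final time step:

```
v ← v + (dt/τ_m)(−v + I_input + I_recurrent);  spike at v ≥ θ, reset, 2 ms refractory
s ← s·exp(−dt/τ_s) + spikes;                   p(stimulus) = σ(w·s + b)
```

## Worked example

Generate a 4-mouse cohort, run quality control, and benchmark GLM against
the LSM on stimulus detection (catch vs 100% intensity, peri-stimulus RAW
features from layer 4):

```r
library(lfpdecode)

cohort <- generate_cohort(generator_config(
  n_mice = 4, n_catch = 12, intensity_repeats = 12,
  n_channels = 8, channel_spacing_um = 100, seed = 7))
qc <- filter_trials(cohort)
cohort <- preprocess_cohort(qc$kept)          # causal Butterworth filtering

plan <- make_split_plan(cohort, n_bootstraps = 10, seed = 7)
sc <- scenario_spec("SD", "PERI", "RAW", "L4", intensity_subset = c(0, 100))
ev_glm <- run_scenario(cohort, sc, "GLM", plan)
ev_lsm <- run_scenario(cohort, sc, "LSM", plan)
glance(ev_glm); glance(ev_lsm)
paired_wilcoxon(ev_glm$accuracy, ev_lsm$accuracy)
```

```
#> trials kept: 288 of 288
#>   algorithm n_evaluations median_accuracy mean_roc_auc  mean_brier
#> 1       GLM            40               1            1 0.001623883
#>   algorithm n_evaluations median_accuracy mean_roc_auc mean_brier
#> 1       LSM            40       0.8333333    0.9092014  0.1260793
#>   statistic     p_value n_nonzero n_zero
#> 1       780 4.92055e-08        39      1
```

Each of the 40 rows in `ev_glm`/`ev_lsm` is one leave-one-mouse-out
evaluation: the held-out mouse's (class-balanced) trials are scored by a
model tuned and trained on the other mice only, on one bootstrap of their
balanced training trials. The GLM saturates on this high signal-to-noise
0% vs 100% contrast; the spiking LSM reaches a median of 0.83 on this
cohort seed (0.87-0.96 under the acceptance script's conditions below),
and the signed-rank p-value says the two accuracy distributions differ on
the shared splits. On pre-stimulus windows (`window = "PRE"`) the same
pipeline drops to chance-level performance — the negative control.

`autoplot()` methods draw the benchmark heatmap and the
accuracy-vs-signal-length sweep; `plot_psychometric()` and `plot_evoked()`
show the generated behavior and evoked responses.

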