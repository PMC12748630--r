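---
title: "Classifying vestibular-deficit gait from wearable IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying vestibular-deficit gait from wearable IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vestgait)
```

## The problem

Vestibular schwannoma and related vestibular deficits produce subtle gait
adaptations — restricted head motion, altered trunk sway, changed limb
dynamics — that clinician-scored instruments such as the Functional Gait
Assessment often miss, because each item is scored on a coarse 0–3 integer
scale. Wearable inertial measurement units (IMUs) record six channels per
body site (three linear accelerations in m/s², three angular velocities in
deg/s, at 500 Hz in the motivating study), and a classifier trained on raw
gait cycles can act as a continuous digital biomarker where clinical scores
show no group difference.

`vestgait` implements the complete pipeline: cycle segmentation from the
right-ankle pitch gyroscope, fixed-length cycle matrices, a six-branch 1-D
convolutional network, paired subject-level leave-one-out cross-validation
(LOOCV), transfer learning with a frozen convolutional stage, and the
sensor/subject/sample ablation experiment drivers — together with a
synthetic cohort generator so every stage is testable without clinical
recordings.

## Pipeline

### Segmentation

A gait cycle is delimited by successive dominant positive peaks of the
right-ankle pitch angular velocity — the swing-phase peak of a
shank-mounted gyroscope, the standard event for shank-gyro cycle
detection. The detector takes local maxima of an optionally smoothed copy
of the signal (moving average, default 0.05 s), keeps those whose
topographic prominence exceeds `min_peak_prominence` (default 0.3) times
the robust range (95th − 5th percentile), and forms half-open intervals
`[peak_i, peak_{i+1})`. Cycles whose duration falls outside a physiologic
window (defaults 0.6–2.0 s) are discarded, never merged; leading and
trailing incomplete cycles are dropped. The stored cycle data are the raw
signals — smoothing exists only inside the detector.

Two conventions are deliberate stand-ins, since the clinical protocol
delegates segmentation details to prior work that this package does not
reproduce: the peak (rather than zero-crossing or heel-strike) event
definition, and the prominence threshold. Both are exposed in
`segmentation_params()`. All six placements of a subject are sliced on the
*same* ankle-derived boundaries, so per-subject cycle counts are identical
across sensors by construction; the six streams are assumed to share a
common clock and equal length (a mismatch is an alignment error, not
silently tolerated).

Each cycle is resampled to 6 × 512 by evaluating every channel at 512
points linearly spaced from the first to the last sample inclusive, with
linear interpolation. The closed grid makes resampling the identity when
the input already has 512 samples, endpoint-preserving, and exact for
affine rows. Cubic splines serve the unsegmented activity-window path,
where smooth upsampling of 300-point windows matters more than strict
shape preservation.

### Normalization

Inputs are range-normalized with parameters fitted on the training set of
each fold only: per channel, `value ↦ (value − min)/(max − min)`. Held-out
values may leave `[0, 1]` and are **not** clipped — clipping would erase
exactly the discriminative extremes. "Range of the training set" is read
per channel (six ranges) because accelerometer and gyroscope magnitudes
differ by orders of magnitude; a single global range is available via
`fit_range(mode = "global")` for comparison. A constant training channel
gets a unit denominator and maps to 0.

### The classifier

Each of the six channels feeds its own convolutional branch (no weight
sharing): four repetitions of convolution (kernel 3, padding 1, stride 1)
→ ReLU → batch normalization → max-pool (2, 2), taking the time axis
512 → 32. Branch outputs are flattened, concatenated, and passed through
two dense blocks (affine → ReLU → batch normalization → dropout 0.5) and a
single logistic output unit; probabilities at or above 0.5 are classified
as `patient` (ties positive, a documented deterministic convention).

The per-block filter counts and dense widths are configuration, not fixed
truths — the topology (six branches, four blocks, two dense layers) is the
committed part. Defaults `filters = c(8, 16, 32, 64)` and
`dense_sizes = c(128, 64)` keep the flattened width at 6 × 64 × 32 =
12,288. Initialization is fan-in-scaled normal from `spec$seed`, so a
model is a pure function of its spec.

The network is implemented in the package itself (R orchestration over
compiled layer kernels in `src/`), with convolution lowered to shifted
matrix products and ReLU/batch-norm fused. The backward pass is verified
against numerical differentiation for every parameter tensor in the test
suite — that check, not any external framework, is the correctness
anchor.

### Training

Defaults mirror the reference protocol: binary cross-entropy, the Adam
optimizer with standard moments (0.9/0.999), 100 epochs, batch 64,
learning rate 0.1 with step decay ×0.1 every 25 epochs. A rate of 0.1 is
unusually aggressive for Adam; it is kept as the default for fidelity,
with an optional global gradient-norm cap (`grad_clip`, off by default)
for small fixtures. There is no early stopping anywhere, and batches are
uniform shuffles without class balancing (the cohorts are near-balanced).
A trailing batch of one sample is folded into the previous batch so batch
statistics stay defined; batch normalization uses biased batch variance
for normalization and unbiased estimates in its running averages
(momentum 0.1).

One numerical choice matters at small step budgets: after the last epoch,
the batch-norm running statistics are re-estimated in a single
dropout-free pass over the training set. With hundreds of optimizer steps
this is a no-op in practice; with the few dozen steps of a reduced-budget
run, the momentum-averaged statistics lag the trained weights and would
otherwise distort eval-mode predictions. A frozen convolutional stage is
exempt — its statistics belong to the checkpoint.

### Evaluation

The split is by subject, never by cycle. Each LOOCV fold holds out one
control and one patient; pairing is by rank after sorting subject ids —
the protocol never states how pairs are formed, and rank pairing is
deterministic while leaving the set of tested subjects unchanged. Unequal
groups run `min(n)` paired folds plus singleton folds for the leftovers,
with a warning. Fold `i` derives its model and training seeds as
`seed + i`. Train/test subject disjointness is asserted at runtime inside
the driver.

Per-subject accuracy is the fraction of that subject's cycles classified
with the subject's true label, using *all* cycles (no per-subject cap).
Group accuracy is the mean of per-subject accuracies; the overall value is
the mean of the two group means, exactly. F1 is computed on pooled
cycle-level confusion counts by default (a subject-averaged alternative
was considered; pooling is the documented choice since the reference
material does not say which was used). A subject with zero cycles is
flagged and excluded, never silently scored zero.

### Transfer learning

Pretraining accepts either unsegmented activity windows (resampled to 512
with cubic interpolation; conventionally trained at learning rate 0.001)
or a segmented pathology cohort, reports source validation accuracy from
k-fold cross-validation (sample-level folds for windows, subject-level for
cohorts), then trains a final checkpoint on the full source. Fine-tuning
freezes the convolutional branches — weights, biases, batch-norm
parameters *and* running statistics, asserted bit-identical afterwards —
and retrains the dense stage for 20 epochs. During fine-tuning the frozen
stage runs in eval mode, which is what keeps its statistics untouched.

### Experiments

`sensor_sweep()` runs one independent LOOCV per placement under an
identical spec and config. `ablate()` subsamples either subjects
(label-stratified, uniform without replacement) or each subject's cycles
(floor of one cycle, so per-subject accuracy stays defined), with
iteration `i` drawing under `seed + i` while model seeds stay fixed —
hence `fractions = 1` reproduces the unablated baseline exactly.
`transfer_experiment()` chains pretraining, per-fold fine-tuning per
placement, and exact delta tables against a baseline
(`finetuned = baseline + delta`, cell by cell).

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
not biomechanics. Each subject walks at an individual stride frequency
(mean 1 Hz, between-subject SD 0.06 Hz); every channel of every placement
is a sum of stride-locked harmonics with fixed per-channel phases and
amplitudes typical of each site (the ankle pitch gyroscope dominates at
~250 deg/s, head accelerations are small, the vertical accelerometer
carries gravity). Cycle durations jitter multiplicatively with a lognormal
factor — chosen because it keeps periods positive and cycles ordered, not
because the distributional shape of real inter-cycle variability is known.
The ankle pitch channel is a pure fundamental, so its swing peak sits at
stride phase 0.25 exactly and the segmentation oracle (peak times
`(k + 0.25)/f` under zero jitter) is closed-form.

Patients differ in two ways: channel amplitudes are scaled by
`1 − effect × weight` under a 6 × 6 loading matrix, and cycle-duration
jitter is multiplied by `group_variability_effect`. The default loadings
put the strongest signal on head pitch/roll angular velocity (patients
restrict head motion) and, with negative sign, on mediolateral trunk
acceleration at waist and back (increased sway), with a mild 0.25 loading
elsewhere so every sensor carries some signal — this is what makes the
sensor sweep meaningful on fixtures, and `focused_effect_weights()` lets a
test load all signal on one site. Subjects also carry a fractional
amplitude random effect (SD 0.08) and additive Gaussian noise per channel
(SD as a fraction of the channel's base amplitude). Age and sex are
generated but carry no effect: the emulated cohorts are age-matched, so
the null fixture should be null.

`cohort_presets()` freezes the package's own study conditions: 8 subjects
per group, 8 s trials at 250 Hz (about 6 cycles each, matching the short
clinical task's cycle yield), noise 0.05, and an effect ladder of 0 /
0.05 / 0.15 / 0.4 (`zero`/`weak`/`medium`/`strong`); the `zero` preset
also equalizes jitter between groups so the classes are statistically
identical. What passing tests on these fixtures shows is that the
*pipeline* is sound — chance behavior on null data, effect recovery,
monotone ablation trends. It does not show that real vestibular gait is
separable at any particular accuracy: the generator has no biomechanics,
no sensor drift, no task effects, and its group differences are simple
amplitude scalings.

## Validation problem sizes

The package's own validation experiments (test suite and
`scripts/acceptance.R`) run a reduced configuration chosen once: filter
counts `c(4, 8, 8, 16)`, dense widths `c(32, 16)`, 8 epochs at batch 64,
and learning rate 0.01 — the full 100-epoch, 0.1-rate default is the
protocol's scale, not a useful setting for 100-cycle fixtures, where a
gentler rate under the short budget trains stably. Chance-level behavior
is checked over 10 seeded null cohorts against a 95% binomial band with
the subject (not the cycle) as the independent unit, since cycles within
a subject are strongly correlated. Effect recovery averages two seeds per
ladder level; ablation trends use six iterations per fraction. The
numerical gradient check covers every parameter tensor of a small spec at
tolerance 1e-4.

## Known limitations

* Rotation matrices for global-frame alignment are accepted as inputs,
  never estimated; synthetic cohorts are generated directly in the global
  frame.
* The exact layer widths of the reference architecture are unknown;
  results depend on the configured widths.
* Determinism holds for a fixed BLAS and thread configuration; bitwise
  reproducibility across numerics libraries is not promised.
* The bundled benchmark tables are transcriptions of published summary
  statistics used as arithmetic inputs; the underlying clinical recordings
  are not public, and nothing in this package re-estimates them.
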