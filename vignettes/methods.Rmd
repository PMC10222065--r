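---
title: "Modelling risk-taking behaviour from wearable physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk-taking behaviour from wearable physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During a human–robot tactile interaction study, participants play the
Balloon Analogue Risk Task (BART) while a wrist-worn sensor records four
physiological channels at different rates: electrodermal activity (EDA,
microsiemens, 4 Hz), blood volume pulse (BVP, arbitrary units, 64 Hz), skin
temperature (TEMP, °C, 4 Hz) and interbeat intervals (IBI, event-coded
seconds). Each session also carries an interaction condition — low-intensity
touch (LI), high-intensity touch (HI), verbal-only (NT) or a no-robot
control (NR) — and a BART score, the mean number of pumps per unexploded
balloon, which indexes risk-taking propensity.

`tactileRisk` implements three predictors of the BART score from these
data, in increasing order of capacity:

1. a **random-intercept mixed-effects model** on 11 hand-crafted
   physiological features, honouring the within-subject repeated-measures
   design,
2. an **RBF-kernel support vector regression (SVR)** on the same features,
3. a **multi-input convolutional multihead-attention network (MCMA)**
   trained end-to-end on the raw signals.

Because the underlying study data are available only on request, the package
ships a fully seeded synthetic generator that emulates the study's
statistical structure with known ground truth, so that every stage — feature
formulas, collinearity handling, estimators, the network, the evaluation
harness — is testable.

# Feature extraction

Eleven time-domain features summarise each session:

* IBI: mean heart rate `mHR = 60/mRRi`, mean interval `mRRi`, the
  population standard deviation `IBISDNN`, and the root mean square of
  successive differences `IBIRMSSD`. `mHR` is defined from the mean
  interval rather than as a mean of instantaneous rates; this makes
  `mHR * mRRi = 60` an exact identity (and indeed `mHR` is redundant given
  `mRRi`, which the collinearity stage later detects).
* EDA: mean conductance `mAmp`, mean absolute first difference `Slope`,
  and `event`, the number of disjoint skin-conductance-response episodes in
  which the signal gains more than 0.05 µS within a window spanning less
  than 5 s. The definition is read as *net* gain; a greedy earliest-end scan over
  qualifying windows implements it, with each counted episode extended to
  the local peak of its rise so one monotone rise counts once, validated
  against an all-pairs brute-force oracle. The alternative monotone-rise
  reading is noted in the code.
* BVP: mean absolute value `mBVP`, minimum `miBVP`, maximum `maBVP`.
* TEMP: `TCR`, the mean first difference divided by the sample period
  (°C/s), equal to the endpoint slope for uniformly sampled data but robust
  to isolated missing samples.

`IBISDNN` uses the population (n) denominator; switching to n−1 is a
one-line change and tested behaviour does not depend on it.

# Multicollinearity and selection

Physiological features are intercorrelated by construction. The package
computes variance inflation factors (`computeVif`), the Farrar–Glauber
overall test (`farrarGlauber`: the determinant of the predictor correlation
matrix with its chi-square statistic
`-(n - 1 - (2p + 5)/6) log det R` on `p(p-1)/2` degrees of freedom, plus
per-feature F statistics), and lasso selection along a cross-validated path
(`lassoSelect`, coordinate descent via glmnet). The support is read at the
one-standard-error penalty by default — the sparser conventional choice;
the CV-minimising penalty is also reported and selectable. Features are
standardised internally and coefficients reported on the original scale.
On synthetic data the near-deterministic `mHR`–`mRRi` pair is flagged
(VIF far above 10) and at most one member survives selection.

# The mixed-effects baseline

The baseline is `y ~ features + condition + (1 | subject)` fitted by REML
(ML selectable), with the condition treatment-coded against the no-robot
control NR. The published form of this model writes one coefficient per
modality; a working design needs one per feature, so the coefficient
"blocks" here are the feature columns of each modality and a contrast
vector over conditions — the only reading consistent with per-feature
importance statements. Prediction for subjects seen in training adds their
estimated random intercept; unseen subjects get the fixed effects only.
`residualDiagnostics` reports the numeric content of the four classical
panels (residuals vs fitted, Q–Q straightness as a correlation,
scale–location trend slope, leverage/influence), with a degenerate flag for
noiseless fits. An optional `log1p` response transform is provided because
the source analyses mention modelling the log of risk-taking once;
neither scale is asserted as canonical.

The SVR baseline is epsilon-SVR with an RBF kernel (libsvm via e1071),
features z-scored internally; defaults `C = 1`, `gamma = 1/p`,
`epsilon = 0.1` since the study does not state them; all overridable.

# The MCMA network

Raw inputs are canonicalised to the modal lengths 72 (EDA), 1200 (BVP),
16 (IBI) and 72 (TEMP) — longer sequences keep their most recent samples,
shorter ones are pre-padded with the edge value — and sliced into `T = 8`
time steps, giving 2-D inputs of per-step widths 9, 150, 2 and 9. Each
branch applies two zero-padded 3×3 convolutions with batch normalisation
and ReLU, an intermediate 2×2 max pooling (2×1 for the IBI branch, whose
step width of 2 would not survive two width-2 pools), and a pooling head
that **sums global average and global max pooling**. A dense layer maps
each branch to a 256-unit embedding; the condition enters as a one-hot
4-vector through its own embedding. The five tokens (B, 5, 256) are fused
by multihead self-attention (`h = 8`, `d_k = d_v = 256/8 = 32`) and passed
to a small regression head.

Design choices the source text leaves open, resolved here:

* **Attention scaling.** The printed attention formula divides scores by
  `d_k`, while the surrounding text defers to standard Transformer
  settings; the package defaults to `1/sqrt(d_k)` and exposes the printed
  linear scaling as `attnScale = "dk"`. Both are tested against a naive
  loop oracle.
* **Residual fusion.** The token matrix is added to the attention output
  (the standard Transformer residual), and the attention output projection
  is initialised at zero, so fusion starts as the exact identity and
  attention is learned smoothly. Without the residual, the near-uniform
  attention of an untrained network averages the five tokens together and
  token identity never reaches the head; training is visibly unstable.
* **Conv filter counts.** The text does not give them. Defaults are
  (8, 16) filters — deliberately small: the branch representation ahead of
  the 256-unit embedding is the summed GAP+GMP vector, and at the sample
  sizes used here larger branches only increase the generalisation gap.
* **Head and fusion.** The fused tokens are either flattened (default
  `fusion = "flatten"`) or averaged (`"mean"`) before a 64-unit hidden
  layer. Averaging gives a five-fold smaller head but dilutes each
  branch's token with the others' noise, which empirically hurts the full
  model relative to its ablations on small samples; the harnesses
  therefore use the flatten default.
* **Optimisation.** Mini-batch Adam (batch 32, learning rate 2e-3 in the
  harnesses) with decoupled weight decay (1e-4 to 1e-3) on weight matrices,
  a step learning-rate decay, early stopping on validation MAE, and full
  seeding: two runs with the same seed produce identical weights. Every
  layer's backward pass is hand-written and verified against central
  differences in the test suite.

Splitting is subject-level by default (all of a subject's records in one
split), honouring the no-leakage requirement under a within-subject design;
record-level splitting exists behind an explicit flag.

# The synthetic generator

A single latent per-session **arousal** variable mediates all channels:
`arousal = conditionEffect + subjectIntercept + jitter`. Higher arousal
raises heart rate (mean interval `60/(60 + 8·arousal)` s) and lowers
beat-to-beat variability, raises tonic skin conductance and the rate and
amplitude of SCR bumps (linear 1.5 s rise, exponential 2 s decay), scales
pulse amplitude, and tilts skin temperature. Session lengths default to
18 s of EDA/TEMP (72 samples), 18.75 s of BVP (1200 samples) and about 18
beats, so the modal lengths match the network's input lengths; the number
of records per subject and condition is a parameter, because the source
data's observation count implies sub-session segmentation that is never
described.

Two per-subject intercepts are drawn independently: one on the arousal
scale and one on the BART-score scale (`subjectSd`, in pumps). The score
random intercept is what a mixed-effects fit estimates as its
random-intercept standard deviation; conflating the two scales would make
parameter recovery ill-posed.

**Linear scores** are computed from the features *extracted from the
realised signals*: `y = b0 + X·beta + conditionContrast + u + eps`. At zero
noise this makes the regression exactly identified, which the recovery
tests exploit.

**The nonlinear variant** exists to make the central ordinal claim — that
an end-to-end model can beat feature-based models — testable at desk scale.
It is deliberately designed so that part of the score variance lives in
signal structure that the 11 summary features *cannot* represent:

* a saturating temperature-drift term `w_s · tanh(slope/s_0) · g_s[cond]`
  (the drift has an arousal-independent component visible only in the TEMP
  channel, so removing the TEMP branch genuinely degrades the network —
  mirroring the finding that temperature is the most informative channel);
* a saturating arousal-by-condition interaction
  `a · tanh(arousal − a_0) · g_a[cond]`;
* a signed within-session **heart-rate trend** (the interbeat interval
  drifts linearly across the session): dispersion summaries such as SDNN
  and RMSSD see only its magnitude, never its direction, while a
  convolution across adjacent time-step rows followed by global average
  pooling reads the mean derivative directly;
* a signed **EDA tonic drift** with the same property (the `Slope` feature
  is an absolute value, hence direction-blind).

This encodes, in generative form, the premise that manual feature
extraction discards temporally structured information that end-to-end
learning can retain. Passing the comparison property therefore shows that
the network can exploit such structure when it exists; it does not show
that real BART data contain such structure in this proportion. The term
weights (5, 5, −5, 8 pumps per scaled unit), the subject intercept
(3 pumps), the residual noise (1 pump) and the arousal parameters were
fixed once during design, are documented in `genParams()`, and are the
conditions under which the acceptance properties are asserted.

# Problem sizes used by the harnesses

The test-suite and acceptance-script runs use sizes chosen to exercise the
claims at desk scale: feature and attention oracles at 100 random inputs;
mixed-model recovery over replicates of 60 subjects (score intercept sd 5,
noise sd 1); selection behaviour at 40–100 subjects; the model comparison
on the nonlinear dataset with 80 subjects × 3 records per condition
(sub-session segmentation emulated, 960 records, subject-level 60/20/20
split); the ablation grid (seven variants × three seeds) on the same
80-subject design with one record per condition. Training runs use up to
150 epochs with early stopping. These sizes are the package's choices and
are stated here so results can be reproduced exactly.

# Numerical notes and limitations

* Max pooling and global max pooling break ties toward the first window
  position; with continuous inputs ties have probability zero.
* Batch-norm running statistics use momentum 0.9; evaluation mode is an
  affine transform, so predictions are deterministic.
* Exact collinearity in VIF is reported as an `Inf` sentinel with a flag,
  never an exception; a non-positive-definite correlation matrix yields a
  zero determinant and an infinite chi-square sentinel.
* The generator produces plausible *statistics*, not plausible *waveform
  morphology*: no dicrotic notch, no motion artifacts, no circadian
  drift. Conclusions about real sensor data require the real data.
* The SCR `event` count implements the net-gain reading of the rise
  definition, with each counted episode extended to the local peak of its
  rise so that one monotone rise counts once; monotone-rise counting would
  give systematically smaller counts on noisy data.
* At a few hundred training records, disabling a weakly informative input
  branch can act as a regulariser: in the ablation grid the IBI-off and
  BVP-off variants can slightly outperform the full model, and the full
  model's advantage reappears as records per condition grow. Ablation
  deltas at desk scale are therefore ordinal hints, not effect-size
  estimates.
* Shorter "fast-prediction" input configurations (e.g. 8-second windows)
  are not implemented; the stated modal lengths contradict them and they
  are left as a documented note.
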