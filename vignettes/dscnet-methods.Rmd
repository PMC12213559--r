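---
title: "DSCnet: model, preprocessing and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DSCnet: model, preprocessing and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscnet)
```

# The problem

Resting-state EEG carries class-discriminative structure in its
oscillatory band power — for example, altered alpha-band (8–12 Hz)
activity in clinical cohorts versus healthy controls.  `dscnet` implements
a compact convolutional architecture for two-class decoding of multichannel
EEG segments, together with everything needed to evaluate it honestly:
signal conditioning, subject-aware data splitting, a fully seeded trainer,
confusion-matrix metrics and an ablation runner.  Because clinical EEG is
rarely redistributable, the package is exercised end to end on synthetic
EEG whose class contrast is a controllable band-power ratio.

# The architecture

The network consumes a segment laid out as a $C \times 1 \times T$ feature
map ($C$ channels, $T$ samples) and has three stages.

**Stage 1 — hybrid representation.**  Three stacked $1 \times 3$
convolutions (each followed by batch normalization and GELU) map the $C$
input channels to an embedding of width $E$; a $1 \times 1$ convolution
provides a residual skip from the raw input.  The embedding is then
concatenated along the channel axis with a $1 \times 1$ projection of the
raw input, giving a $2E$-channel *hybrid representation* that retains both
learned features and (a linear image of) the original signal.  The text
this design follows leaves the exact content of the concatenation open; we
concatenate the residual-block output with a projected copy of the input
so both halves share the same width, and treat that reading as a design
decision.  Normalization placement (conv → batch norm → GELU) is likewise
our choice; the source only fixes GELU as the activation family.

**Stage 2 — multi-angle rounds.**  Each round applies a depthwise-separable
convolution (per-channel $1 \times 3$, then $1 \times 1$ cross-channel
mixing) and refines the result in two parallel branches whose outputs are
summed and compressed by temporal max pooling (factor 2):

* *DAFM (directional adaptive feature modulation).*  The input is split
  into `nLevels` equal channel groups.  Group $j$ is temporally max-pooled
  by $p^{j}$ (with $p$ = `dafmPool`, capped at $T$), passed through a
  depthwise $1 \times 3$ convolution, and restored to length $T$ by
  nearest-neighbour up-sampling; group 0 keeps full resolution.  The
  groups are re-concatenated, fused by a $1 \times 1$ convolution, passed
  through GELU, and used as a multiplicative gate on the branch input:
  $\bar X = \phi(\hat X) \odot X$.  Down-sampling is temporal only and the
  default is two levels, so each scale keeps half the channels.  The
  pooling operator itself (max; mean offered nowhere since max matches the
  adaptive-pool lineage of this operator family) and the odd-length
  behaviour (truncate the repeated grid, then replicate the last frame)
  are implementation decisions documented here and frozen by tests.
* *CoT attention.*  A grouped $1 \times k$ convolution produces a static
  context $K_1$.  The concatenation $[K_1, Q]$ with $Q = X$ passes through
  two stacked $1 \times 1$ convolutions (GELU between them) to produce,
  per position and channel, $k$ attention logits; a softmax over the $k$
  temporal taps weights the values $V = \mathrm{Conv}_{1\times1}(X)$ of
  each position's neighbourhood, giving the dynamic context $K_2$.  The
  output is $Y = K_1 + K_2$.  The $Q$ definition, the softmax
  normalization over the neighbourhood, the attention hidden width (set to
  the stage width) and the additive fusion follow the published
  conventions of this attention block; they are decisions, not given
  facts.

Two rounds with independent weights are the canonical configuration;
one and three rounds exist as ablation variants.  Whether rounds could
share weights was an open point — independent weights are the default
because nothing suggests tying, and the ablation over the round count only
makes sense with per-round parameters.

**Stage 3 — classifier.**  Global average pooling over time, a hidden
$1 \times 1$ layer (width 64, GELU), and a $1 \times 1$ output layer
produce one score per class; the prediction is the argmax, with ties
broken toward the lower class index for determinism.

Layer widths are open parameters: the defaults (`embedWidth = 16`, hybrid
width 32, `stage2Width = 32`, `classifierHidden = 64`) are proportioned
like comparable compact EEG CNNs and keep CPU training fast; every width
is configurable in `dscnetConfig()`.

```{r}
cfg <- dscnetConfig(inChannels = 8)
countParameters(cfg)
```

## Numerical choices

* **Initialization.**  Fan-in normal ($\mathrm{sd} = 1/\sqrt{\text{fan}}$),
  zero biases, fixed recorded seed.  The DAFM fusion and CoT
  attention-logit kernels are drawn 10× smaller: both feed multiplicative
  or softmax paths, and a near-zero start keeps those paths near-linear so
  activations stay $O(1)$ through stacked rounds instead of growing
  quadratically through the gate.
* **Gradients.**  All backward passes are analytic and are checked against
  central finite differences (relative error $<10^{-3}$ at step
  $10^{-4}$, double precision) in the test suite.
* **Batch normalization** uses batch statistics during training and
  running statistics (momentum 0.1) at inference; $\varepsilon = 10^{-5}$.
* **Convolutions** are zero-padded "same", stride 1; only max pooling
  changes the time length.

# Preprocessing

The conditioning chain mirrors standard resting-state EEG practice:
a 50 Hz notch (second-order IIR biquad, quality factor 30), a 0.5–64 Hz
Butterworth band-pass realized as a 4th-order high-pass/low-pass cascade
(numerically far better conditioned at a 0.5 Hz cut-off than a single
band-pass section), resampling to 128 Hz (zero-phase anti-alias low-pass
at 45 % of the target rate, then evaluation on the new time grid; output
length is exactly `round(n * target/source)`), optional re-referencing to
the mean of named reference electrodes (which are dropped afterwards, as
they become linearly dependent), and fixed-length windowing.  All filters
are applied forward–backward (`filtfilt`), hence zero-phase — phase
distortion of transients is the main artefact this avoids.  Independent
component analysis for ocular artefact removal is a standard published
procedure, not part of this package's contribution, and is out of scope;
the chain accepts already-cleaned signals.

**Standardization.**  For each segment, the cross-channel mean and
(population) standard deviation are computed at every time point; the
global curves $\mu(t), \sigma(t)$ are the averages of those per-segment
curves over the *training* segments, and every value is mapped to
$(x - \mu(t)) / \max(\sigma(t), \varepsilon)$ with
$\varepsilon = 10^{-8}$ guarding degenerate constant inputs.  The
description this follows is ambiguous between per-segment statistics
averaged globally and one pooled global statistic; the per-segment reading
is the default and a `dialect = "global"` switch provides the pooled
variant, so both are auditable.  Statistics are fitted on the training
split only — fitting them on the full dataset would leak test information
through $\mu$ and $\sigma$.

The segment length fed to the network ($T = 256$ samples, i.e. 2 s at
128 Hz, non-overlapping) is a package default, not an external fact; both
window length and stride are parameters of `segmentRecord()`.

# Synthetic EEG

`generateDataset()` draws, per channel, 1/f-shaped Gaussian background
noise (flat below 1 Hz), plus a shared band-limited oscillation obtained
by band-pass filtering white noise into the target band, mixed into the
channels with fixed per-subject uniform weights in $[0.5, 1.5]$
normalized to unit mean square — the mixing vector shapes each subject's
cross-channel profile (structure for the pointwise convolutions to
exploit) without adding subject-level gain.  The class difference is
purely multiplicative on the oscillation amplitude:
class 1 carries $\sqrt{\text{powerRatio}}$ times the class-0 amplitude,
so the measured band-power ratio converges to `powerRatio`.  Subjects are
individualized by a log-normal amplitude jitter (sd 0.1 on the log scale)
and their mixing weights, which is what makes subject-wise splits
genuinely harder than segment-wise splits.  Raw-style recordings add
optional 50 Hz mains and sub-0.5 Hz drift components for exercising the
conditioning chain.

The defaults describe the reference conditions used by the package's own
evaluation: 20 subjects per class, 50 segments per subject, 8 channels,
256-sample segments at 128 Hz, an 8–12 Hz oscillation and a band-power
ratio of 2.  The class-0 oscillation RMS equals the background RMS
(`noiseFloor`), an alpha-dominant eyes-closed-like regime in which the
in-band background contributes only a few percent of band power.

What the generator does *not* emulate: ocular/muscle artefacts,
event-related potentials, inter-channel lags, non-stationarity, volume
conduction with realistic topographies, or any stimulus protocol.
Passing the package's recovery tests therefore shows that the
architecture, gradients, splitting and training machinery work — it does
not certify performance on real clinical EEG.

```{r}
ds <- generateDataset(syntheticSpec(nSubjectsPerClass = 4,
                                    segmentsPerSubject = 10))
bandPowerRatio(ds, c(8, 12))$ratio
```

# Training and evaluation

Training minimizes softmax cross-entropy with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$) plus
decoupled (AdamW-style) weight decay; the defaults — peak learning rate
$10^{-3}$ annealed to zero by a cosine schedule over the epoch budget,
decay coefficient $0.01$, batch size 32, 30 epochs — are field-standard
choices recorded in `trainConfig()`, since no training hyperparameters
were externally fixed.

The decay pair matters on cohort EEG.  The failure mode of a long run at
a constant step size is *subject-level* overfitting: the network keys on
per-subject channel profiles, the training loss reaches zero within
roughly ten epochs, and accuracy on unseen subjects oscillates and slides
well below its early plateau.  Weight decay plus the annealed step keeps
held-out-subject accuracy at that plateau through the end of the budget,
so the final-epoch model is the deliverable and no model selection is
needed.  Early stopping is still available (`earlyStopPatience`): when
enabled without an explicit validation set, it carves a subject-wise
hold-out (20 % of training subjects, stratified by class), monitors
validation accuracy, and restores the best epoch's weights.  It is off by
default because removing a fifth of the subjects from training measurably
hurts subject-invariant generalization at cohort sizes of a few dozen
subjects — the data are worth more as training signal than as a monitor.
Initialization, the per-epoch shuffle and any hold-out derive from the
configured seed, so two runs with equal seeds produce bit-identical
parameters on a single CPU thread.  A non-finite loss aborts with an
explicit divergence error.

**Splitting.**  Descriptions of 80/20 protocols for cohort EEG are often
self-contradictory: "80 % of each subject's data" cannot coexist with "no
subject appears in both sets".  Both readings are implemented:
`per_subject_segments` (80 % of every subject's segments in train) and
`subject_wise` (80 % of subjects, stratified by class, wholly in train).
`subject_wise` is the default everywhere because it is the stricter,
leakage-free protocol; the package's no-signal sanity property (chance
accuracy at `powerRatio = 1`) holds only under it.

**Metrics.**  Accuracy, precision, recall and F1 are computed one-vs-rest
per class with zero-denominator cases mapping to 0, and aggregated both by
support-weighted and macro averaging.  Weighted averaging is the reported
default: on balanced cohorts it makes precision numerically track
accuracy, which is the arithmetic signature visible in published tables of
this kind.  Metrics are computed at segment level by default;
`aggregate = "subject_vote"` pools segment predictions into a per-subject
majority vote (ties toward class 0), since whether published figures are
segment- or subject-level is typically unstated.

**Ablations.**  `runAblation()` trains every architecture variant —
embedding off, standard instead of depthwise-separable convolution, DAFM
off / 2 levels / 4 levels, CoT off, 1/2/3 rounds — under the identical
split, standardization and seeds, and emits a percentage table in the
canonical column layout (the `full`, `dafm_n2` and `rounds_2` rows
coincide with the canonical model but are kept as separate grid rows).

# Problem sizes used by the shipped tests

The test suite verifies operator correctness on ~100 random small inputs
per operator (8 channels, 6–12 samples), gradient correctness on a
4-channel, 32-sample model, and the end-to-end property at the reference
conditions above (2 000 segments); the no-signal chance-level property
uses 20 subjects/class × 10 segments over five seeds, and the ablation
grid runs two epochs on a 6-subjects/class set.  These sizes are the
package's own balance between statistical resolution and a test suite
that stays pleasant to run; all of them are parameters, not constants.

# Known limitations

* CPU-only, double precision; no GPU kernels and no mixed precision.
  Practical cohort sizes (hundreds of subjects) train in minutes, not
  seconds.
* The synthetic generator's realism limits, listed above, bound what green
  tests imply about clinical data.
* Only binary classification is wired through the metrics and ablation
  machinery, although the classifier head accepts `nClasses` > 2.
* No hyperparameter search, cross-validation, or significance testing
  between ablation variants is provided.
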