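---
title: "Methods: cross-modality apnea-hypopnea event segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modality apnea-hypopnea event segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sleep apnea-hypopnea syndrome is diagnosed from overnight polysomnography
(PSG): trained scorers mark intervals where airflow or respiratory effort
ceases (apnea) or is partially reduced (hypopnea) for at least 10 s. The
apnea-hypopnea index (AHI, events per hour) and its severity strata
(Normal/Mild/Moderate/Severe at cutoffs 5/15/30) are the clinical
endpoints. PSG is accurate but obtrusive; a frequency-modulated
continuous-wave (FMCW) radar can measure chest-wall micro-motion without
contact, at the cost of a substantial domain shift relative to effort
belts and very limited labeled data.

`apneaseg` implements a two-stage pipeline for this setting:

1. **Source-domain pre-training.** A 1D dense-segmentation network maps
   two-channel respiratory effort windows (thoracic + abdominal, 10 Hz,
   2048 samples) to per-sample event probabilities and is trained on
   PSG-style data.
2. **Target-domain fine-tuning.** The pre-trained weights initialize a
   radar model that is fine-tuned on radar-derived respiration waveforms
   with partial layer freezing and frozen batch normalization.

Because the clinical cohorts behind this design are not distributable, the
package ships a first-class synthetic-data module that emulates both
modalities with known ground truth; every downstream stage is tested
against it.

## Synthetic nights

`sim_params()` / `simulate_night()` generate two-channel quasi-periodic
respiration: a sinusoid at a breathing frequency in the physiological
0.15-0.4 Hz band whose instantaneous frequency and amplitude are slowly
modulated, plus slow baseline drift and white sensor noise. The abdominal
channel is an amplitude-scaled (default ratio 0.8), phase-lagged (default
0.4 rad) copy of the clean thoracic oscillation with independent noise.

Events are planned by `plan_events()`: the count is
`round(target_ahi * hours)`, durations are uniform within
`event_duration_range_s` (lower bound >= 10 s, the scoring minimum), and
inter-event gaps strictly exceed `min_gap_s = 8` s. The gap floor is
deliberately above the 6 s post-processing merge gap so that temporal
regularization in the evaluation chain cannot fuse two distinct true
events; harder regimes can be produced by lowering the stress parameters
explicitly. `inject_events()` realizes an event as a multiplicative
amplitude envelope: suppression to 5% of baseline for apneas (codes 1-3;
the clinical definition is near-complete cessation) and to
`1 - hypopnea_reduction` for hypopneas (code 4), with raised-cosine
onset/offset ramps of at most 2 s. Event morphology beyond amplitude
suppression is not specified by clinical scoring rules; the multiplicative
envelope is the minimal physiologically faithful choice, and the
simulator is a statistical stand-in, not a physiological model. In
particular it contains no body-movement artifacts, desaturation or arousal
channels, so passing tests demonstrate correctness of the pipeline
mechanics, not clinical performance on real recordings.

The radar forward model (`simulate_radar_cube()`) produces a complex
slow-time cube (50 Hz x 40 range bins by default): bin *b* carries
`g_b * exp(j * (4*pi/lambda) * d_b(t) + j*theta_b) + c_b` with
`d_b = mix_b * chest + (1 - mix_b) * abd` in meters, a static complex
clutter offset `c_b`, and Gaussian phase noise. The wavelength is always
derived from the 60 GHz carrier (`lambda = c/f_c`, about 5 mm).
Displacements are scaled to 0.8 mm peak by default, below the
`lambda/4` (about 1.25 mm) unwrapping-ambiguity bound; exceeding it
produces a warning, not an error. Clutter is static (DC) per bin, which is
exactly the component that per-bin mean removal cancels; dynamic clutter
is out of scope. All generators draw from named sub-streams derived from
one integer seed (`derive_seed()`), so each component is independently
reproducible, bit-for-bit.

## Radar respiration extraction

`phase_to_displacement()` subtracts the per-bin mean complex value, takes
the argument, unwraps it along time and scales by `lambda/(4*pi)`. One
numerical property deserves note: mean removal cancels the static clutter
exactly, but it also subtracts the (generally nonzero) temporal mean of
the oscillatory term `exp(j*phi(t))`, which perturbs the recovered phase
by up to roughly `|J0(beta)|` radians for a sinusoidal modulation of depth
`beta`. For realistic sub-millimeter amplitudes this bias is at the
micrometer scale and is immaterial after band-passing; the package's exact
(1e-9 m) round-trip checks use modulation depths at the first Bessel-J0
zero (about 0.96 mm at 60 GHz), where the oscillation's complex mean
vanishes and mean removal is unbiased.

The displacement matrix is band-passed per bin with a 4th-order
Butterworth filter applied forward and backward (zero phase). The
passband default is [0.1, 0.6] Hz, covering 6-36 breaths/min; it is a
package choice exposed in `ridge_config()`. The implementation initializes
each filtering pass in steady state and uses odd-symmetric reflection
padding sized to the low-edge time constant, so constant inputs map to
(numerically) zero and edge transients do not leak into the output.

Chest and abdomen waveforms are reconstructed from the 40-bin displacement
matrix by ridge regression (`w = argmin ||Xw - y||^2 + alpha ||w||^2`)
against the synchronized reference belts, with an orthogonality
refinement: the two weight vectors are alternately re-solved and projected
onto each other's orthogonal complement (`n_ortho_iters = 2`), which
decreases their cosine similarity and encourages disentanglement of the
two motion sources. `alpha = 1` on column-standardized predictors is the
scale-free default; the exact iteration schedule is not dictated by any
external constraint, and alternating projection was chosen as the simplest
scheme with a monotone orthogonality guarantee. Weights are estimated in
120 s windows with a 30 s stride and merged by overlap-add averaging
(per-sample mean over covering windows, with a tail window anchored at the
night's end so coverage is complete); nights shorter than one window fall
back to a single global fit. A reference-free mode that substitutes the
first two principal components of the filtered displacement matrix for
the belt targets is provided (`mode = "pca"`) but is a surrogate outside
the synchronized-reference design.

After reconstruction the signals are band-passed again, decimated from
50 Hz to 10 Hz (integer-factor decimation with zero-phase anti-aliasing;
factors above 10 are decomposed into stages for numerical stability), and
tail-trimmed to a common length with the label sequence — trimming is
always at the tail, preserving the shared t = 0 synchronization point.

## Labels and normalization

Annotations arrive as `(epoch, time, duration, event)` CSV rows, seconds
as units. The parser coerces numeric fields, drops invalid rows (counted),
and maps event strings through an explicit dictionary that accepts both
the `"Respiratory Event ..."` and `"RespEvent..."` prefixes; the codebook
is Normal 0, obstructive/central/mixed apnea 1/2/3, hypopnea 4, other
respiratory annotations 5 (bookkeeping only). Cleaning applies, in order:
midnight-wrap correction (+24 h when the recorded end precedes the start),
overlap resolution (apnea subtypes dominate hypopnea; equal priority keeps
the longer event), and merging of same-code neighbors separated by at most
3 s. Whether cross-code neighbors should merge is ambiguous; the package
merges same-code pairs only and leaves cross-code adjacency to the
priority rule.

Intervals are half-open and 0-based throughout; seconds map to samples as
`[floor(start*fs), ceiling(end*fs))` with a 1e-6-sample round-off guard.
The binary segmentation target marks codes 1-4 positive, 0 and 5 negative.

Per night and channel, `robust_normalize()` replaces NaN/Inf with zero,
centers by the median, clips to median +/- 4 IQR and scales by the IQR,
falling back to the standard deviation when the IQR is degenerate and to
all-zeros when both are (threshold: 1e-6 of the mean absolute deviation —
small enough never to trigger on physiological signals, large enough to
avoid division blow-up). Nights are then cut into 2048-sample windows
with a 300-sample stride (204.8 s and 30 s at 10 Hz).

## The segmentation network

`model_config()` describes a 1D residual U-Net: an encoder of `depth = 4`
stages (stride-2 convolutional downsampling, channels 32-64-128-256,
residual blocks with kernel 3 and dilations (1, 2), batch norm + swish,
dropout 0.2), an ASPP-lite bottleneck (parallel dilated branches with
rates (1, 2, 4, 8) at a quarter of the embedding width each, concatenated
and fused by a 1x1 convolution), sinusoidal positional encoding added at
the bottleneck, three pre-norm transformer blocks (4 heads, FFN multiplier
4) at the lowest temporal resolution (2048/2^4 = 128 samples), a decoder
that mirrors the encoder with nearest-neighbor upsampling + convolution
and skip-connection concatenation, a full-resolution smoothing convolution
with kernel 31 (3.1 s at 10 Hz) named `smooth_conv`, and a 1x1 sigmoid
head. The embedding width is tied to `base_filters * 2^(depth-1)` (256
for the defaults; the first encoder stage performs the 2-to-32 channel
lift together with the first downsampling). Skip fusion by concatenation
plus convolution, branch widths inside ASPP, and dropout placement (after
the first activation of each residual block and inside the FFN) are
conventional choices the architecture description leaves open; they are
fixed here and documented by the code. Ablation switches in the same
config build the comparison variants: `use_transformer`/`use_aspp` off
gives the plain base U-Net, `use_residual = FALSE` and
`downsample = "pool"` remove the residual and learnable-downsampling
refinements.

The network is implemented directly in R, with no deep-learning framework
dependency: layers, the forward pass and exact analytic gradients are
written on base-R arrays with BLAS matrix products (im2col convolutions,
batch norm, swish, dropout, max-pool, nearest upsampling, layer norm,
multi-head attention, dense layers). This keeps the whole computation
inspectable and the package's dependency surface minimal. Backpropagation is verified against central
finite differences for every layer type in the test suite (worst relative
error below 1e-3 at 1e-5 step size, i.e. at the resolution of the check).

## Training

The loss is `alpha * Dice + (1 - alpha) * weighted BCE` with
`alpha = 0.8`, positive weight 2.0, negative weight 1.0, Dice smoothing
1e-6 and BCE clipping 1e-7. Dice supplies overlap-sensitive gradients
under heavy class imbalance; the weighted BCE stabilizes early
optimization. Class imbalance is handled by the loss weights only — no
resampling. Optimization is Adam with global gradient-norm clipping at
1.0 and batch size 96; the reference learning rates are 1e-4 for
pre-training (up to 80 epochs) and 5e-5 for fine-tuning (up to 50
epochs). Model selection uses event-level F1 on validation nights,
computed after every epoch by full sliding-window fusion, post-processing
and interval matching; counts are pooled over nights (summed TP/FP/FN, not
a mean of per-night F1 values). Early stopping uses patience 3 with best
weights restored; the learning rate halves on validation-loss plateaus
(patience 2, floor 1e-6). Two selection criteria are defensible —
best validation loss and best validation event-F1; the package follows
event-F1 as primary (it is the clinically aligned criterion), logs both,
and exposes `select_metric` to switch.

For transfer, `finetune()` reconstructs the teacher's architecture from
the serialized configuration stored in its checkpoint (a mismatch with the
expected configuration is a hard error), loads the weights, and freezes
the first `floor(rho * L)` entries of the ordered layer list with
`rho = 0.6` by default. "Layer" granularity is the block definition order
— encoder stages, ASPP, transformer blocks, decoder stages, smoothing
conv, head (L = 14 at the reference depth) — so `rho = 0.6` freezes
exactly the encoder and bottleneck while the decoder and head adapt.
`rho = 0` is scratch training. With `bn_freeze = TRUE` every batch-norm
layer additionally becomes non-trainable and uses its stored running
statistics during training, avoiding unstable small-batch statistics under
domain shift. Cross-validation folds are severity-stratified: nights are
shuffled within each severity class and dealt round-robin, so per-class
counts differ by at most one across folds (e.g. 35 nights with severity
counts 17/12/3/3 split into 3 folds as 5/4/1/1 once and 6/4/1/1 twice).

## Post-processing and metrics

Window probabilities are fused into a full-night sequence by unbiased
averaging over covering windows. Fused probabilities are thresholded at
`tau` (>=), maximal positive runs become candidate events, gaps of at most
`g_min = 6` s are merged, and events shorter than `d_min = 10` s are
removed (the scoring convention's minimum duration). `tau = 0.5` is the
package default — the natural operating point of a calibrated sigmoid —
and is exposed in `postproc_config()` along with a sample-level ROC sweep
(`sample_roc_auc()`) for threshold studies.

Predicted and true events match one-to-one when their interval
intersection-over-union exceeds `theta = 0.1`; the matcher computes a
maximum-cardinality matching (augmenting-path search seeded greedily by
descending IoU with deterministic tie-breaks) and is tested for equality
against an exhaustive optimal matcher on all instances up to 8 events per
side. Unmatched predictions are false positives, unmatched truths false
negatives. Recording-level outputs are the AHI
(`N / (L / (3600 fs))`, with L the analyzed record length — no
sleep-staging correction, which is out of scope), its MAE/RMSE and
Pearson/Spearman correlations across recordings, the 4x4 severity
confusion at left-closed cutoffs 5/15/30, accuracy, Cohen's kappa
(`(po - pe)/(1 - pe)`), and Bland-Altman bias/limits as numbers.

## Domain-gap diagnostics

`extract_features()` mean-pools a named layer's activation per window
(canonically `smooth_conv`); `domain_gap_report()` quantifies the PSG-radar
feature discrepancy with a cross-validated linear probe AUC, RBF-kernel
MMD^2 (median-heuristic bandwidth, V-statistic so identical sets give
exactly zero), CORAL (squared Frobenius distance of covariances scaled by
`1/(4 d^2)`), and a k-NN opposite-domain mixing ratio. UMAP plots are
cosmetic and not reproduced; the metrics are.

## Desk-scale experiment sizes

The reference configuration (2048-sample windows, base 32, depth 4) is the
package default. The shipped experiments — the test suite's end-to-end
recovery test and `scripts/acceptance.R` — use the `tiny_model_config()`
preset (512-sample windows, base 8, depth 3, identical structure) on a
20-night source cohort of 40-minute nights (13 train / 2 validation /
5 held out, per-night target AHI uniform on [2, 45]) and a 9-night
distribution-shifted radar cohort of 30-minute nights (6 train /
3 validation; slower breathing, higher noise, different amplitude ratio
and hypopnea depth, full cube-to-waveform extraction). The desk-scale
profile trains with a larger learning rate (1e-3 pre-training, 5e-4
fine-tuning and scratch) because its epoch budget is an order of magnitude
smaller than the reference schedule; the transfer comparison gives
fine-tuning and scratch identical budgets, optimizer settings and seeds.
These sizes are the package's chosen desk-scale study conditions: large
enough for stable event statistics and a full severity spread, small
enough to run on a single CPU.

## Known limitations

* The simulator does not model body movement, posture changes, multipath
  dynamics, desaturation- or arousal-scored hypopneas; results on it bound
  pipeline correctness, not clinical accuracy.
* Mean-based DC removal carries the Bessel-mean phase bias discussed
  above; a circle-fitting clutter estimator would remove it but is not
  part of the reference processing chain.
* Range-bin selection from a full range profile is taken as given (the
  cube is the input); chirp-level simulation is out of scope.
* Event subtypes are preserved in the data model but scored only as the
  binary apnea/hypopnea-vs-normal task.
* Sleep staging (and therefore true sleep time in the AHI denominator) is
  out of scope; the analyzed record length is used.
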