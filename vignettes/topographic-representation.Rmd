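---
title: "A size-preserving topographic front end for raw-EEG classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A size-preserving topographic front end for raw-EEG classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

EEG decoders built on convolutional networks usually consume a raw epoch as
a C × TP matrix (channels by time points). The row order of that matrix is
arbitrary: adjacent rows need not be adjacent electrodes, so convolutions
over the channel axis cannot exploit the scalp geometry, and most
architectures compensate with a single global spatial filter. The
topographic representation module (TRM) implemented here makes the geometry
explicit while leaving the downstream architecture alone.

The module is the composition of four operations, all differentiable, so it
trains jointly with whatever network follows it:

1. **Mapping.** A montage table assigns each channel to one cell of an
   H × W grid (injectively; 0-based coordinates; row 0 frontal, column 0
   left). At each time point the epoch becomes an H × W image whose
   assigned cells carry the raw potentials unchanged and whose remaining
   H·W − C cells are exactly 0. No interpolation mode exists: zero filling
   is a deliberate part of the design, and the mapping is exactly
   invertible (`unmap_topomap(map_to_topomap(x, m), m)` is `x` bit for
   bit), which the tests exploit.
2. **Scheduled valid convolutions.** With base kernel k (3 or 5), each
   layer applies C kernels with stride 1 and no padding. While the running
   feature map (h, w) has h > k or w > k, the kernel is
   (min(k, h), min(k, w)); otherwise a single (h, w) kernel finishes the
   reduction. Every schedule therefore terminates at a 1 × 1 feature map —
   the suite verifies this exhaustively for all grids up to 32 × 32. On a
   7 × 9 grid this yields [(5,5), (3,5)] for k = 5 and
   [(3,3), (3,3), (3,3), (1,3)] for k = 3; on 7 × 7, [(5,5), (3,3)] and
   [(3,3), (3,3), (3,3)]. The first layer sees one input channel; all
   layers output C channels. Time never enters the kernels: the 2-D
   convolutions run per time slice, with time folded into the batch axis,
   which is what makes the module equivariant to time permutations.
3. **Normalization.** One affine batch normalization over the C output
   channels follows the full stack (statistics per channel over
   batch × time; running statistics are buffers, not parameters).
4. **Reshape.** The (C, 1, 1) per-time output is reassembled into C × TP.

Because the output shape equals the input shape, `embed()` composes the
module with any backbone declaring a (C, TP) input, and the combined
parameter count is exactly the sum of the parts.

## Parameter accounting and the default policy

Under the defaults — convolutions without additive bias, one affine
normalization after the stack — the trainable-parameter count is

\[
C k_{1h} k_{1w} \;+\; \sum_{l \ge 2} C^2 k_{lh} k_{lw} \;+\; 2C .
\]

This policy is the package's resolution of a genuinely open design point:
among the simple bias/normalization policies (per-layer biases, per-layer
affine normalization, final affine normalization), only the default
reproduces all four published totals for the two reference layouts —
46,860 and 64,130 for 55 channels on 7 × 9 (k = 5, 3) and 18,612 and
35,332 for 44 channels on 7 × 7. The alternatives remain selectable
(`conv_bias`, `norm_policy`) but are non-default. `count_parameters()` on a
spec evaluates the closed form; on a built module it enumerates the actual
trainable arrays; the tests require the two routes to agree on the
reference configurations and on randomized ones.

Similarly, "feature map larger than k × k" is read as *at least one
dimension strictly exceeds k*, with the kernel clamped per dimension to
(min(k, h), min(k, w)); this is the only reading consistent with the
published totals, which imply the asymmetric (3,5) and (1,3) kernels.

No nonlinearity sits between the convolutions by default (`activation =
"identity"`); a flag can insert one, without changing any count.

## Montages as data

The two shipped layouts, `ebdsdd-7x9` (55 channels) and `hgd-7x7` (44
channels, all central electrodes except the Cz reference), are YAML files
under `inst/extdata/`, not code. Their grid sizes and channel counts are
exact; the per-cell placements are documented approximations of the scalp
layout and can be edited freely — every verifiable contract (injectivity,
bounds, zero-fill, round trip, parameter counts) is independent of where a
particular electrode lands. Channel matching between epochs and montage is
always by name, never by position: positional matching would silently
scramble topographies when channel orders differ.

## The layer engine

No neural-network library is part of the package's dependency set; the
layers the module and backbones need (2-D convolution with stride, zero
padding and groups; batch normalization; ELU/square/log activations;
average and max pooling; dropout; linear; Adam; softmax cross-entropy) are
implemented directly on base-R arrays, with im2col gathers feeding BLAS
matrix products. Every backward pass is validated against central finite
differences in the test suite (tolerance 1e-6 on random instances of every
layer configuration in use). Weight initialization is the uniform fan-in
scheme, fully determined by an integer seed; identical seeds give
bit-identical modules and training trajectories, a contract the tests
assert end to end.

Numerical choices worth knowing: the safe log activation clamps its input
at 1e-6 (zero gradient below the clamp); batch-norm uses eps = 1e-5 and
momentum 0.1 with unbiased running variances; max pooling assumes
non-overlapping windows (asserted at construction); Adam uses the standard
bias-corrected moments with the L2 penalty added to the gradient.

## Backbones

The three evaluation backbones are minimal, contract-conforming
reimplementations of the standard shallow, deep and compact raw-EEG
convolutional designs, not bit-exact ports. Two deliberate deviations: the
compact net's "same"-padded temporal kernels are 63 and 15 wide (odd, so
zero padding stays symmetric) instead of 64 and 16; and the deep net, whose
nominal temporal kernels (width 10) and pools (width 3) do not fit short
epochs, shrinks each block's kernel and pool to the largest that fits,
deterministically from TP. Construction fails with the named minimum where
no cascade fits (the shallow net needs TP ≥ 99, the compact net TP ≥ 32).
Softmax lives in the loss, not the network: accuracies are argmax-invariant
either way. The compact design keeps at least an order of magnitude fewer
parameters than the other two at the 55 × 280 scale, which the suite
asserts as `10 * count(compact) <= count(other)`.

## Synthetic data: what it emulates and what it does not

The generator exists so the module's claimed spatial sensitivity is
testable without any external download. Each class owns a focus cell
(deterministically spread across the grid); a trial of that class contains
a Hann-windowed sinusoidal burst with per-trial uniform carrier frequency
(default 8–13 Hz) and phase, whose channel amplitudes decay as a Gaussian
in *grid-cell* distance from the focus (`spatial_spread`, default 1.5
cells — grid distance, not scalp arc length, because the grid is all the
module ever sees). Noise is 1/f-shaped (spectral exponent 1, shared across
channels at 30% amplitude as a crude common-mode term) plus independent
white noise; `snr` is defined as burst RMS at the focus channel over
per-channel noise RMS, and `snr = Inf` gives clean trials. Labels are
exactly balanced and everything is reproducible from one seed.

What it does not emulate: volume-conduction mixing beyond the Gaussian
profile, artifacts, nonstationarity, inter-subject variability, realistic
cross-channel covariance. Passing tests on this data therefore demonstrate
that the pipeline can learn spatially localized class structure through the
topographic representation — not that it reaches any particular accuracy
on real recordings.

The event-stream generator produces continuous records with
stimulus/response marker pairs (inter-stimulus gaps uniform in a
configurable range, default 20–40 s) over the same noise model, as a
fixture for the epoching operations.

## Preprocessing

Target epoching cuts one window per response marker (default −1300 ms to
+200 ms), subtracts the channelwise mean of the first 100 ms, and by
default *discards* that baseline span: at 200 Hz the 1500 ms window is 300
samples and the output is 280. The two stated ingredients — a 1500 ms
window and 280 output samples — are mutually inconsistent unless some
100 ms is dropped, and dropping the baseline span after correction is the
only reading that uses exactly the stated ingredients; `discard_baseline =
FALSE` keeps all 300. Nontarget epoching slides a 1500 ms window in 500 ms
steps over regions at least 3000 ms (symmetric) from every marker, with
the same baseline and channel handling, and can subsample (seeded) to the
target count. Window admissibility is tested against an independent
interval-arithmetic oracle on random marker layouts. Trialwise epoching
cuts fixed-duration segments (4 s at 250 Hz → 1000 points) without
baseline correction. The band-pass filter is a zero-phase
(forward–backward) Butterworth of order 4 — the filter family is a package
choice, recorded in the output metadata — followed by decimation or
polyphase resampling; a band edge above the post-resampling Nyquist is a
configuration error.

Continuous input arrives either from code or from the package's plain-text
array container (JSON header + CSV payload, for both records and epochs).
No reader for vendor formats is included.

## Training protocol

Splits are stratified by label in both modes. Rotating quarters: trials are
cut into four stratified quarters; fold i tests on quarter i and validates
on quarter (i mod 4) + 1 — the rotation itself is a fixed package choice
(any fixed rotation satisfies the 50/25/25 shape; determinism matters more
than which). Quarters are shuffled by default; contiguous-in-time quarters
are available via `shuffle = FALSE`. Fixed-test mode keeps the given test
indices untouched and redraws a stratified 80/20 train/validation split per
repeat.

Training uses Adam (step size 1e-3 — the optimizer default, deliberately
untouched — weight decay 1e-3), cross-entropy loss, batch size 32, and
minimum-validation-loss checkpointing: validation runs once per epoch after
the training pass, a checkpoint is saved only on strict improvement, and
the best checkpoint is restored before testing. A fold whose loss turns
non-finite is marked failed, reported loudly and excluded from the mean —
never imputed. `compare_paired()` implements the paired two-tailed t
statistic from its closed form (p = 2·P(T ≤ −|t|) on n − 1 degrees of
freedom); the suite checks it against `stats::t.test` to 1e-10. Identical
inputs give p = 1; zero-variance differences with nonzero mean are flagged
degenerate with undefined p.

On spatially structured synthetic data at moderate SNR one can expect the
TRM variants to match or beat their originals in checkpoint validation
loss on most seeds; this is a stochastic expectation, documented here
rather than enforced as a hard test gate.

## Problem sizes used by the suite

The test suite runs at deliberately small scales, chosen once: gradient
checks on 3–8-unit layers; exhaustive schedule sweeps to 32 × 32; mapping
properties on randomized montages up to 8 × 8; determinism checks on a
6-channel 3 × 3 montage with 40-point epochs and 2–3 training epochs; and
one full end-to-end run at the reference epoch shape (80 trials of
55 × 280, focus-channel SNR 10, 30 epochs, one fold), which reaches >90%
held-out accuracy in a few CPU-minutes. The published accuracy tables
themselves are out of scope: they require the original recordings and
GPU-scale training.

## Known limitations

- The engine is CPU-only and single-threaded beyond BLAS; it is sized for
  the package's protocol, not for large-scale experimentation.
- Montage cell placements are approximations; anyone reproducing a
  specific published layout should edit the YAML to match their figure of
  reference.
- Cross-subject transfer is explicitly out of scope, as is artifact
  rejection, re-referencing, and parsing vendor file formats.
- The compact backbone's even-to-odd kernel rounding and the deep net's
  cascade shrinking mean parameter counts for those two can differ from
  other implementations; the TRM's own counts are exact.
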