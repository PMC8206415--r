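---
title: "Delineating skin strata in RCM stacks with recurrent attention models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating skin strata in RCM stacks with recurrent attention models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Reflectance confocal microscopy (RCM) images thin en-face optical sections
of skin at cellular resolution. Before acquiring diagnostic mosaics, an
operator collects a *stack* — single-field images at one lateral position,
stepped in depth by a few micrometers — and must decide, slice by slice,
whether each image shows epidermis, the dermal-epidermal junction (DEJ), or
dermis. The DEJ matters most: the majority of melanocytic and
non-melanocytic cancers originate there, so mosaics are targeted around it.
Reading the grayscale reflectance texture well enough to do this reliably
takes substantial training, which motivates automating the per-slice
classification.

`rcmstrata` implements that automation as a two-stage recurrent
convolutional network (RCN): a convolutional encoder classifies single
slices and is then frozen as a per-slice feature extractor; a recurrent
model over the feature sequence assigns the final per-slice labels, using
the one piece of structure single-image models cannot see — skin strata are
depth-ordered, and legal label sequences are monotone in the ordinal coding
epidermis (0) < DEJ (1) < dermis (2).

## Model

**Slice encoder.** The default backbone (`tiny_cnn`) is four 3x3
convolution blocks with ReLU and 2x2 average pooling, global average
pooling, a 256-neuron fully connected embedding layer, and a 3-class
softmax head. After image-wise training, the head and the embedding-layer
non-linearity are removed, and the frozen linear 256-d activations serve as
slice features. Two-stage training (rather than end-to-end CNN+RNN) is the
only supported mode: batch-normalized CNNs are not well defined in a
time-distributed setting, and freezing the encoder also avoids recomputing
slice features for every sequence-model variant.

**Recurrent encoder.** A bidirectional GRU (64 units per direction, one
recurrent layer per direction) runs over the feature sequence and emits a
128-d encoding $h_n$ per slice.

**Attention.** A row-stochastic map $A$ turns encodings into contexts
$\tilde h_n = \sum_m A_{nm} h_m$:

* *Full-sequence*: $A = I$ (no mixing).
* *Global attention*: additive scoring
  $e_{nm} = v^\top \tanh(W_1 h_n + W_2 h_m)$, rows normalized with
  exponentials over unmasked slices. Every slice may attend anywhere in the
  stack.
* *Toeplitz attention*: a single learnable kernel $a$ of length $2D+1$
  with non-negative entries summing to one, placed on the band
  $|m-n| \le D$ of every row, so $A$ has constant diagonals and the context
  is a depth-invariant local convolution of the encodings. With $D = 0$ the
  map is the identity and the model reduces exactly to the full-sequence
  RCN — the package asserts this reduction numerically.

**Decoder.** Decoding runs shallow-to-deep; at slice $n$ the decoder input
is $\tilde h_n$ concatenated with the class probabilities emitted at slice
$n-1$ (zeros at the first slice). The Toeplitz and full-sequence variants
use a single fully connected softmax layer; global attention uses a GRU
followed by a fully connected layer. The previous-step probabilities are
the model's own outputs at both training and inference time (autoregressive),
which matches the test-time behavior; teacher forcing is available as a
configuration flag, since the reference recipe does not state which was
used. A `partial_seq` variant classifies the middle slice of a short
window (default 3 slices, terminal slices replicated at the edges) instead.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `gruHidden` | 64/direction | encoder capacity |
| `D` | 1 | Toeplitz attention half-width; support $2D+1$ slices |
| `epochs`, `batchStacks`, `lr` | 200, 4, 0.001 | sequence-model training recipe |
| `recurrentDropout` | 0.10 | variational dropout on recurrent connections |
| `l1Recurrent` | 0.05 | L1 penalty on recurrent weight matrices |
| `maxLen` | 71 | stacks longer than this are clipped to their first (shallowest) 71 slices |
| `axialStep` | per stack, µm | converts slice indices to physical depths; acquisition steps range 1.5–5 µm and are never inferred from files |

The convex Toeplitz kernel is parameterized as normalized exponentials of
free weights: the constraint (non-negative, sums to one) then holds for any
raw values and training stays unconstrained and differentiable. Rows whose
window is clipped by a stack edge or by padding are renormalized over the
surviving entries, preserving the convex-combiner contract; the kernel is
shared between interior and edge rows. The CNN stage's own recipe (Adam,
learning rate 2e-3, 25 epochs, batch 32, ±10° rotation and ±10%
zoom/shear/stretch plus flips for augmentation) is not specified by the
reference method and was chosen so the desk-scale encoder converges;
all magnitudes are configurable.

## Anatomical consistency and boundaries

Raw per-slice argmax labels can violate depth ordering. The post-processing
heuristic is two label-domain filters: a 3-slice median (removing isolated
outlier calls) followed by a causal max filter — an *inclusive* prefix
maximum. We read "the maximum of the predictions before it" inclusively
because a strictly exclusive reading leaves the first slice undefined and
discards every current prediction; the inclusive form is idempotent and
leaves correct (monotone) inputs unchanged. Median edges replicate the
terminal labels, which likewise keeps correct inputs fixed.

The composition guarantees a monotone output, hence none of the three
*decreasing* impossible transitions (DEJ→epidermis, dermis→epidermis,
dermis→DEJ) can survive. One caveat is structural: a monotone
epidermis→dermis *skip* can survive when two or more consecutive
dermis-labeled outliers defeat the 3-slice median (e.g. `0,2,2,0,…` →
`0,2,2,2,…`). A label-domain filter cannot invent the missing DEJ slice, so
such skips are left in place and are visible to `countInconsistencies()`;
they correspond to a zero-thickness DEJ in the boundary readout. Likewise,
a too-deep outlier at the very first slice survives the median (its window
is dominated by the replicated edge) and is then locked in by the running
maximum — the heuristic protects the interior of the stack, not slice 1.

Boundary depths are read off the enforced labels as the depth of the
*first* slice of the deeper stratum ("start point" convention):
epidermis-DEJ at the first label ≥ 1, DEJ-dermis at the first label 2, with
depth = origin + index × axial step. A stratum that never appears yields an
absent (`NA`) boundary, which is excluded pairwise from mean-absolute-error
summaries rather than guessed.

Consistency is evaluated on *raw* model outputs (post-processing trivially
monotonizes them), while boundary MAE is evaluated on *post-processed*
outputs — the two metrics answer different questions (did the model learn
the ordering? how well are the borders localized?).

## The synthetic stack simulator

Because the clinical dataset is only partially public and desk-scale
hardware cannot train the reference encoder, every claim in this package is
exercised on seeded synthetic stacks with known ground truth. The simulator
emulates:

* per-stack class fractions averaging 44% epidermis / 34% DEJ / 22% dermis,
  via boundary indices placed at the expected fractional depths plus
  Gaussian jitter (5% of stack length);
* stratum textures — isotropic band-pass "cellular blob" fields in the
  epidermis, fine anisotropic fibrous streaks in the dermis (white noise
  convolved with an isotropic or elongated oriented Gaussian, via circular
  FFT convolution), with the DEJ a linear mixture ramping from epidermal to
  dermal texture across its thickness;
* depth-dependent degradation: every slice below the epidermis is scaled by
  $\exp(-\lambda (i - b_1))$ (default $\lambda = 0.03$ per slice) before
  additive Gaussian sensor noise;
* subject structure: stacks are assigned to subjects and splits are
  stratified subject-wise, so no subject spans two splits.

Defaults are desk-scale: 60 stacks of 20–40 slices at 64x64 px and a 3 µm
axial step (the standard optical sectioning); stack lengths up to 101 are
supported. Pixels are quantized to the 16-bit grid so TIFF round-trips are
exact. The simulator does **not** emulate speckle physics, undulating 3-D
boundary surfaces within a slice, lesional morphology, or inter-site
acquisition differences — so green tests here demonstrate that the
machinery is correct and that the models exploit depth ordering on
separable textures, not clinical-grade accuracy.

## Numerical choices

* All network gradients (convolution, GRU, attention, autoregressive
  decoders) are hand-derived and checked against central differences in the
  test suite at ~1e-6 relative error.
* Optimization is Adam; a learning rate of zero performs no update, and
  the best-validation-accuracy snapshot (ties broken by lower validation
  loss) is what training returns.
* Argmax ties break to the lowest class index (the shallowest stratum) for
  determinism.
* Masked (padded) positions are excluded from the recurrence, attention
  normalization, and the loss; appending padding never changes unmasked
  predictions (asserted to 1e-6).
* All randomness flows from explicit integer seeds; equal seeds give
  bit-identical stacks, splits, and training runs.

## Problem sizes used in the checks

The end-to-end analysis trains on the default synthetic dataset (60 stacks,
64x64 slices; roughly 900 training slices), with 25 encoder epochs and 60
sequence-model epochs — sizes chosen so the whole loop runs in minutes on a
single CPU while leaving a clear gap between the single-slice baseline and
the sequence models. The exhaustive post-processing check enumerates all
3^8 (unit tests) and 3^10 (acceptance) label sequences; metric
implementations are compared against brute-force oracles on 1000 random
cases.

## Known limitations

* The reference encoder architecture (Inception-V3 scale) is not provided;
  the backbone is a small CNN, so absolute accuracies here are not
  comparable to clinical results.
* The global-attention scorer is the standard additive (length-agnostic)
  form; the reference description ("an MLP from $h_n$") does not fix the
  scorer's architecture, and a per-position MLP cannot emit variable-length
  rows.
* Post-processing operates on labels only; probability-aware smoothing
  (e.g. Viterbi over the class posteriors) is intentionally out of scope.
* The epidermis→dermis skip and first-slice caveats described above.
* On the default synthetic conditions, single-slice classification saturates
  below the sequence models no matter the backbone: the residual errors sit
  at the DEJ ramp ends, where a slice labeled DEJ is nearly pure neighbor
  texture and the discriminating information simply is not in the slice.
  That gap — closed only by depth context — is the phenomenon the sequence
  models exist to exploit, and the tests assert the ordering (sequence
  model ≥ single-slice baseline) rather than any absolute ceiling for the
  baseline.
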