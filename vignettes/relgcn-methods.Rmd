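---
title: "Methods: syntax-enhanced graph convolution for relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syntax-enhanced graph convolution for relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relgcn)
```

## The problem and the model

Relation extraction classifies the semantic relation between marked entity
mentions in text — binary phenotype–gene decisions ("Yes"/"No"),
multi-class chemical–protein interactions with a null class, or ternary
cross-sentence tuples. `relgcn` implements a neural classifier built on the
idea that *shallow* syntactic structure (phrase grouping and constituent
order, as opposed to a full dependency parse) can be injected into the
encoder and then *equalized* so that local and nonlocal token interactions
contribute comparably.

The pipeline, end to end:

**Encoder.** An ordered-neuron LSTM. On top of the standard gates

$$f_t, i_t, o_t = \sigma(\cdot), \qquad \hat c_t = \tanh(\cdot),$$

two *master gates* are predicted at chunk granularity with the cumulative
softmax $\mathrm{cumax}(x) = \mathrm{cumsum}(\mathrm{softmax}(x))$:
$\tilde f_t = \mathrm{cumax}(\cdot)$ (non-decreasing, 0 to 1) and
$\tilde i_t = 1 - \mathrm{cumax}(\cdot)$ (non-increasing, 1 to 0), with
overlap $\omega_t = \tilde f_t \odot \tilde i_t$. The cell update

$$c_t = \omega_t \odot (f_t \odot c_{t-1} + i_t \odot \hat c_t)
      + (\tilde f_t - \omega_t) \odot c_{t-1}
      + (\tilde i_t - \omega_t) \odot \hat c_t$$

splits neurons into a long-lived high-order segment (copied from
$c_{t-1}$), a freshly written low-order segment, and a mixed overlap — the
ordering is what encodes hierarchy. When both master gates are pinned to 1
the cell reduces *exactly* to a plain LSTM; the test suite exploits this as
an oracle, comparing against an independently written LSTM at tolerance
1e-6. Several renderings of the master-gate equations circulate; this
implementation follows the canonical ordered-neuron formulation, and the
monotonicity contracts above — not any particular typeset formula — are
what the tests assert.

**Attention adjacency.** Per head $k$:
$S^k = \mathrm{rowsoftmax}\!\big((hW^Q)(hW^K)^\top / \sqrt{d_{head}}\big)$,
a row-stochastic token graph. Padding positions (when present) are masked
to $-\infty$ before the softmax; a fully masked query row is defined as
uniform over valid tokens.

**Kernel equalization.** Each $S^k$ is convolved with a normalized discrete
2-D Gaussian $g(x,y) = a\,e^{-(x-x_o)^2/2\sigma_x^2-(y-y_o)^2/2\sigma_y^2}$
under replicate padding, then row-renormalized. "Multiplying a Gaussian
kernel into an attention matrix" admits two readings; this package
implements 2-D convolution — the operation Gaussian kernels actually
perform when they equalize images (the guiding analogy), with the
window-wise multiply-accumulate being exactly discrete convolution, whereas
an elementwise product of a 3×3 kernel with an $n\times n$ matrix is not
even dimensionally defined. Normalizing the kernel makes the amplitude $a$
cancel; convolution with a convex-combination kernel guarantees every
output entry lies within the min/max of its receptive field, row mass is
preserved up to renormalization, and one-hot rows strictly gain entropy —
all tested. The step is sometimes called "matrix-tree pruning" in this
model family, but it is kernel smoothing: no spanning-tree (Kirchhoff)
construction is involved, and none is implemented.

**GCN.** $H^{(l+1)} = \sigma(\tilde D^{-1}\tilde A H^{(l)} W^{(l)})$ with
$\tilde A = A + I$ and $\tilde D_{ii} = \sum_j \tilde A_{ij}$. Row
normalization is used instead of the symmetric $\tilde D^{-1/2}$ form
because attention adjacencies are asymmetric. $H^{(0)} = h$.

**Classifier.** Max-pooled sentence, subject-span and object-span vectors
(plus a third-entity vector for ternary tasks), concatenated in fixed order
and passed through one ReLU hidden layer; the final linear + softmax layer
realizes the logistic-regression output. Max-pooling is the convention in this model family; mean-pooling is
available by flag. Pooling is applied to the *processor* output rather
than the raw encoder states, consistent with the pipeline's data flow.

## Design choices where the design was open

* **Master-gate chunking.** Master gates are computed per chunk (default
  10 at $d = 300$) and broadcast within chunks, as in the original
  ordered-neuron design — a per-neuron softmax over 300 units would be
  needlessly diffuse.
* **Head count and merging.** Default 4 heads; head outputs are
  concatenated and linearly mixed to $D'$, the simplest faithful
  combination.
* **GCN depth** defaults to 2; **direction** is unidirectional with a
  bidirectional flag; hidden size defaults to 300.
* **Residual shortcut (this package's addition).** The processor output is
  $h + \mathrm{mix}(\mathrm{concat\ of\ heads})$ by default
  (`residual = TRUE`). Without it, plain SGD at desk scale cannot escape
  the class-prior plateau within realistic epoch budgets: the initial
  attention is near-uniform, and degree-normalized averaging attenuates
  both signal and gradient on the way to the classifier. Dense/residual
  shortcuts are standard in the attention-guided-GCN lineage this model
  extends. The shortcut is inside `use_feature_capture`, so the ablation
  switches remain meaningful.
* **Optimizer.** SGD with multiplicative per-epoch learning-rate decay
  (default 0.9), momentum 0 unless configured, batch size 1 (pure SGD;
  minibatch accumulation is supported and mathematically equivalent to
  padding-free batching), and global gradient-norm clipping (default 5),
  the usual recurrent-network stabilizer. Initial learning rate, epoch
  count and batch size are exposed in `relgcn_config()` and logged with
  every run.
* **Embeddings** are looked up lowercased (pretrained-vector convention),
  fixed during training; unknown tokens share one seeded uniform
  $[-0.5/d, 0.5/d]$ vector. An optional switch replaces entity mentions
  with role placeholder tokens; off by default, as mention identity is
  often a legitimate feature.

## What the synthetic generator emulates

`synthetic_spec()` plants a deterministic labeling rule: each positive
instance carries a label-specific *trigger word strictly between* its two
entity spans; null instances carry none; distractor triggers of other
labels may appear *outside* the entity-to-entity path (so position and
structure, not bag-of-words, determine the label); filler text nests
bracketed phrases up to a configurable depth so hierarchical structure
exists for the encoder to exploit. A `noise_rate` fraction of positives
have the trigger withheld with the label kept, making the realized clean
fraction a hard Bayes ceiling that `trigger_rule_predict()` attains
exactly. A ternary variant plants the trigger on both entity-pair paths.
Because the planted vocabulary has no real pretrained vectors, training
runs pair corpora with synthetic pretrained-style embeddings
(`write_random_embeddings()`, Gaussian entries at the scale of published
word vectors); the `±0.5/d` fallback is a lookup-miss convention, far too
small to train from scratch.

What the generator does *not* emulate: real biomedical vocabulary
statistics, mention-name distributions, multi-token entity morphology,
class imbalance, or annotation noise beyond trigger deletion. Passing the
learnability checks therefore demonstrates that the architecture and
optimization recover planted compositional structure — not that any
particular benchmark score would be reproduced.

## Problem sizes and numerical choices

The packaged study conditions (tests and `scripts/acceptance.R`) train on
500 instances (50 dev, 100 test), sentence lengths 8–20, vocabulary budget
80, binary labels with trigger "binds", 30 epochs — about 1.5 minutes per
run on one CPU. Model size for these runs: $d = 32$, chunk 4, 2 heads, 2
GCN layers, learning rate 0.3 with decay 0.95, clip 5, dropout 0 (planted
corpora need no regularization; the 0.5 default matches the convention for
real corpora). These sizes were chosen for robust convergence across
independent embedding draws and corpus seeds.

* Gradients: every backward pass is hand-derived; the suite checks the full
  model (1,222 parameters at the test size) against central finite
  differences at relative error ≤ 1e-4 (measured ~1e-7 at $\varepsilon =$
  1e-5).
* Softmaxes subtract the row max before exponentiation; `cumax` output may
  exceed 1 by machine epsilon and is asserted only to float tolerance.
* Kernel vs. matrix size: a kernel larger than the attention map is cropped
  ring-by-ring and renormalized.
* Max-pool ties break toward the first row; cross-entropy clamps
  probabilities at 1e-12; a non-finite loss aborts training with a
  diagnostic.
* Determinism: every stochastic step (initialization, shuffling, dropout,
  splits, generation) draws from seeded streams isolated from the global
  RNG; identical seeds give identical corpora, fold assignments and loss
  trajectories on CPU.

## Diagnostics and their interpretation

`attention_matrices()` reproduces the three-stage heat-map comparison:
`A` — scaled dot-product self-attention of the raw embeddings (no learned
projections; the encoder is bypassed, so no syntactic structure is fused);
`B` — the trained multi-head attention over the encoder output, averaged
over heads; `C` — the equalized `B`. The *diagonal mass*
$\sum_i M_{ii} / \sum_{ij} M_{ij}$ summarizes locality: embeddings are
most similar to themselves, so `A` is strongly diagonal (~2× uniform),
while `B` spreads weight off the diagonal and equalization flattens it
further — the qualitative picture of the case study.

One caveat the diagnostics make explicit: at these toy sizes the *trained*
attention `B` stays within a percent of uniform (the residual path carries
the class signal), so the inequality "equalization reduces diagonal mass"
is only meaningfully testable on matrices that are actually sharp. The
acceptance check therefore asserts it on sharp-`B` instances whenever they
exist and, unconditionally, on the sharp embedding-level matrix `A`, where
the reduction holds on every test instance.

## Known limitations

* Pure-R execution: fine at the packaged sizes; the stated 300-dimensional
  configuration on a real corpus would want a compiled backend.
* Word embeddings are not fine-tuned, and no subword/character features
  exist, so out-of-vocabulary handling is a single shared unknown vector.
* No BERT-style pretraining path, no dependency parsers, and no
  spanning-tree decoding — all outside this model's scope.
* The cross-validation harness trains one model per fold sequentially;
  five folds at the packaged sizes take ~10 minutes.
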