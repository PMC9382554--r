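# relgcn: syntax-enhanced graph convolutional networks for biomedical relation extraction

Biomedical relation extraction asks, for a sentence (or multi-sentence
passage) with marked entity mentions — a chemical and a protein, or a
phenotype and a gene — which semantic relation holds between them.
Dependency-parse-based neural models dominate the task but discard the
*shallow* syntactic signal (phrase grouping, constituent order) that
rule-based systems relied on. `relgcn` implements a classifier that puts
that signal back, for researchers who want a parse-free relation extractor
or a test bed for syntax-injection and attention-equalization ideas.

## The model

Four stages, trained end to end by SGD on the cross-entropy:

1. **Ordered-neuron LSTM encoder.** A standard LSTM (gates
   `f_t, i_t, o_t`, candidate `ĉ_t`) whose cell update is segmented by two
   *master gates* computed with the cumulative softmax
   `cumax(x) = cumsum(softmax(x))`:

   - master forget `f̃_t = cumax(·)` — non-decreasing from 0 to 1 along the
     neuron axis,
   - master input `ĩ_t = 1 − cumax(·)` — non-increasing from 1 to 0,
   - overlap `ω_t = f̃_t ⊙ ĩ_t`, and

   `c_t = ω_t ⊙ (f_t ⊙ c_{t−1} + i_t ⊙ ĉ_t) + (f̃_t − ω_t) ⊙ c_{t−1} +
   (ĩ_t − ω_t) ⊙ ĉ_t`.

   High-order neurons persist across many steps, so the hidden states carry
   hierarchical (shallow-syntactic) structure without any parser. Master
   gates operate at chunk granularity (`chunk_size` neurons per chunk).

2. **Attention adjacency.** Per head `k`,
   `S^k = row-softmax((hW^Q)(hW^K)ᵀ / √d_head)` — a row-stochastic
   token×token graph, a soft stand-in for a dependency structure.

3. **Gaussian-kernel equalization ("pruning").** Each `S^k` is convolved
   with a normalized 2-D Gaussian kernel
   `g(x,y) = a·exp(−(x−x_o)²/2σ_x² − (y−y_o)²/2σ_y²)` (replicate padding),
   then row-renormalized. As in image equalization, sharp local peaks are
   flattened and weight moves onto nonlocal token pairs.

4. **GCN + entity-aware classifier.** `H^(l+1) = σ(D̃⁻¹ Ã H^(l) W^(l))` with
   `Ã = A + I`, followed by max-pooled sentence/subject/object vectors fed
   through a feedforward network: `H_final = FFNN([H_sent; H_s; H_o])`,
   softmax on top. A residual shortcut from the encoder output around stages
   2–4 stabilizes SGD.

All forward *and backward* passes are hand-derived and implemented in base
R; the analytic gradients are verified against central finite differences in
the test suite (relative error below 1e-4; measured ~1e-7).

No external corpus is required: `synthetic_spec()` / `generate_corpus()`
produce relation corpora with a planted, fully learnable trigger rule (the
label is determined by which trigger word appears *between* the entity
spans), controllable label noise, off-path distractor triggers, and nested
bracket phrases. `trigger_rule_predict()` is the matching Bayes-ceiling
oracle.

## Worked example

```r
library(relgcn)

labels <- label_set(c("No", "Yes"), null_label = "No")
spec <- synthetic_spec(n_instances = 650, label_set = labels,
                       vocab_size = 80, length_range = c(8, 20),
                       trigger_map = list(Yes = "binds"),
                       noise_rate = 0, task = "binary", seed = 11)
corpus <- generate_corpus(spec)

emb <- tempfile(fileext = ".txt")   # synthetic pretrained-style vectors
write_random_embeddings(unlist(lapply(corpus, `[[`, "tokens")), emb,
                        dim = 32, seed = 99)
vocab <- build_vocabulary(corpus, embeddings_path = emb, dim = 32, seed = 1)

cfg <- relgcn_config(embedding_dim = 32, hidden_dim = 32, chunk_size = 4,
                     heads = 2, gcn_layers = 2, dropout = 0, lr = 0.3,
                     lr_decay = 0.95, epochs = 30, batch_size = 1,
                     patience = 99, seed = 7, task = "binary")
fit <- relgcn(corpus[1:500], dev = corpus[501:550], config = cfg,
              vocab = vocab, labels = labels)
fit
#> Syntax-enhanced GCN relation classifier
#>   encoder : ON-LSTM d=32 (chunks of 4)
#>   graph   : 2 attention head(s), 2 GCN layer(s), 3x3 Gaussian equalization
#>   labels  : No, Yes
#>   trained 30 epoch(s); best dev metric 1.000 at epoch 14

evaluate(fit, corpus[551:650])
#> relation-extraction evaluation on 100 instances
#>   accuracy  1.0000
#>   micro-F1  1.0000 (precision 1.0000, recall 1.0000; null class 'No' excluded)
#>   per class:
#>  label support precision recall f1
#>     No      53         1      1  1
#>    Yes      47         1      1  1
```

The model recovers the planted rule essentially perfectly (the rule oracle
scores 100% on a noise-free corpus, and the trained model matches it within
a few instances), even though distractor triggers outside the
entity-to-entity path make a bag-of-words solution impossible. With
`noise_rate = 0.2`, a fifth of the positive instances carry no trigger;
test accuracy then stays *below* the oracle ceiling `1 − realized noise`,
as it must.

`attention_matrices(fit, instance)` returns the three heat-map matrices of
the case study — `A` (embedding-level self-attention, strongly diagonal),
`B` (trained multi-head attention over the encoder output), `C` (the
equalized `B`) — with their diagonal-mass fractions;
`export_heatmaps()` writes them as text matrices and PNGs.

A thin CLI covering synthesis, training, evaluation, cross-validation and
heat-map export is installed at `inst/cli/relgcn.R`
(`Rscript relgcn.R {synth|train|eval|crossval|heatmap} ...`).

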