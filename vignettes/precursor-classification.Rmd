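---
title: "Neural classification of RiPP precursor peptides: models, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural classification of RiPP precursor peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ribosomally synthesized and post-translationally modified peptides
(RiPPs) are encoded as short precursor peptides (PPs) that tailoring
enzymes mature into the final natural product. Finding the precursor gene
is the hard part of mining genomes for RiPP biosynthetic gene clusters:
PPs are short (here, 20–120 residues), frequently unannotated, and most
class- or context-specific predictors only recognize precursors that
resemble the family they were trained on. `rippnet` approaches the
problem as plain binary sequence classification: given nothing but an
amino-acid sequence, estimate the probability that it is a precursor
peptide. That makes the classifier usable as a class-independent filter
between an ORF caller (which emits tens of candidate peptides per
cluster) and downstream curation.

## Input encoding

Sequences are mapped to a fixed 20 × 120 one-hot matrix: rows follow the
alphabetical amino-acid order `ACDEFGHIKLMNPQRSTVWY`, column *j* carries a
single 1 at the row of residue *j*, sequences longer than 120 residues
are truncated after the 120th, and shorter ones are padded with all-zero
columns. Two details are deliberate choices rather than forced ones:

* **Alphabet order.** Any fixed order works; the alphabetical one is used
  and serialized into every saved model's metadata so that weights and
  encoding can never drift apart.
* **Padding side.** Zero columns are appended after the sequence
  (C-terminal side), so residue *j* always sits in column *j* regardless
  of length. Leader-region signal — the N-terminal recognition motifs
  that make precursors learnable — therefore occupies a stable column
  range across the whole corpus.

Records containing non-canonical symbols (`X`, `B`, `Z`, `J`, `U`, `O`)
are excluded, never wildcarded: the encoding has no 21st symbol, and
inventing one would feed the network a residue distribution it never sees
in training. A trailing `*` is stripped before validation because ORF
callers commonly emit it.

## The five architectures

All architectures share the same head: a dense layer, a dropout layer
with rate 0.5, and a 2-unit classification layer normalized with a
softmax, read as (P(non-precursor), P(precursor)). The published
description of the head — independent sigmoids whose two outputs sum
to 1 — is internally inconsistent; a softmax is the construction that
actually satisfies the stated sum-to-one contract, and is what is
implemented here.

* **`lstm`** — one bidirectional LSTM with 60 cells per direction and
  0.15 recurrent dropout; the two final hidden states feed a 60-unit
  dense layer.
* **`cnn_linear`** — three successive convolutions (64, 128, 64 filters
  with kernels 7, 5, 3 by default), max-pooled in groups of 2, flattened
  into a 40-unit dense layer.
* **`cnn_parallel`** — three parallel branches with kernel sizes 3, 6
  and 9; each branch is two stacked convolutions (64 filters) with a
  width-2 max-pool between them. Branch outputs are concatenated along
  the channel axis, merged by a 150-filter kernel-3 convolution,
  max-pooled in groups of 3, and fed to a 60-unit dense layer.
* **`cnn_linear_lstm`** / **`cnn_parallel_lstm`** — the corresponding CNN
  with a 60-cell (unidirectional) LSTM inserted between the convolutional
  trunk and the dense layer; the dense width stays that of the parent CNN
  (40 and 60 respectively).

The linear CNN's filter/kernel sizes, the parallel branch kernels, and
the width-2 branch pool are artifact defaults — the sizes are exposed in
`model_spec()` and serialized with the weights, so a model is always
reconstructed exactly as trained. Whether the LSTM's "0.15 dropout"
denotes input or recurrent dropout is not derivable from its description;
it is implemented as recurrent (variational) dropout and is configurable.
The hybrid variants' LSTM uses no recurrent dropout.

The networks are implemented directly in vectorized R over BLAS: the
convolutions run as im2col matrix products, the LSTM as a per-timestep
batch recursion, and all gradients are hand-derived backpropagation
(verified against central finite differences to ~1e-8 relative error
during development). Numerical conventions, chosen once:

* convolutions use stride 1 and "same" zero padding, so stacked
  convolutions and pools never underflow the 120-column input;
* hidden activations are ReLU; initialization is Glorot-uniform with
  LSTM forget-gate biases starting at 1;
* the optimizer is Adam with step size 1e-3, momenta 0.9/0.999 and
  epsilon 1e-7; the loss is sparse (integer-label) cross-entropy;
* max-pooling is non-overlapping and drops a trailing remainder window;
* softmax and cross-entropy are computed with max-subtraction and a
  1e-12 probability floor.

## Training loop

Candidate corpora are heavily imbalanced (roughly 7 negatives per
positive in the reference corpus), so plain training would reward the
all-negative classifier, which already achieves
`majority_baseline(2726, 19224)` ≈ 87.6% total accuracy. The loop
counters this with subsampling rather than class weights:

1. At round 1 and every 5th round after, draw a fresh uniform subsample
   of 35% of the negatives (floor of the product: 19224 negatives yield
   6728, plus the full 2726-sequence positive set — a 9454-sequence
   cycle), and re-split the combined set 85/15, stratified by class.
2. Each round runs one epoch of minibatch Adam (batch 32) over the
   training partition, then measures total accuracy on the held-out 15%.
3. Weights are checkpointed iff the held-out accuracy strictly exceeds
   every earlier round's; ties neither checkpoint nor refresh patience.
4. Training stops after 50 rounds without improvement, or at round 200;
   the returned model carries the checkpointed weights, never the
   final-round ones.

A "round" is one full epoch over the current training partition — the
smallest unit after which evaluating held-out accuracy makes sense. When
the negatives are redrawn the 85/15 split is redrawn with them, but the
running best accuracy is retained across re-splits: there is a single
checkpoint sequence per run, and the partition in force at the best
checkpoint is recorded with the result so the stored accuracy can be
re-verified. The whole loop (subsampling, splitting, shuffling, dropout,
initialization) runs off a single seed, so a run is exactly reproducible
on the same machine; across machines, BLAS threading may reorder
floating-point sums, which is why the package's own checks assert
bounds and reproducibility, never bit-patterns of trained weights.

Evaluation always reports positive-set, negative-set and total accuracy
with their counts: on imbalanced data the per-class numbers, not the
total, carry the information.

## Classification and enrichment

`classify_fasta()` validates candidates the same way the training data
are validated, skips (and counts) records that fail, and writes a TSV of
per-sequence probability pairs. A sequence is called `precursor` when its
positive probability strictly exceeds the threshold (default 0.5); an
exact tie resolves to `non-precursor`, the conservative choice for a
discovery filter.

When an external per-sequence binary annotation is available — in
practice, hits against profile HMMs of known precursor families —
`enrichment_report()` compares the hit rate among predicted precursors
with the hit rate of the whole candidate set. The ratio of the two is the
fold enrichment; a value well above 1 means the classifier concentrates
independently-supported candidates. The hit flags are supplied as a
two-column TSV rather than computed in-process, which keeps the package
free of external binaries while preserving the computation. A zero
overall hit rate makes the ratio undefined, which is reported as such
(never as infinity); calling every sequence positive gives exactly 1.

## The synthetic corpus

Real training corpora are collated from many external databases and
tools, so the package carries a generator that emulates their learnable
structure at desk scale:

* positives are i.i.d. background sequences (uniform over the 20
  residues by default), 20–120 residues long, with a 10-mer
  Glu/Leu-rich motif (`ELSAEELKAV`) embedded at positions 3–12 — a
  leader-like recognition window — where each motif position is
  substituted with probability 0.1;
* negatives are sampled from the *empirical residue composition of the
  generated positives*, motif residues included, and any negative
  containing an exact motif copy is redrawn.

Composition matching is the important property: it removes amino-acid
frequency as a usable signal, so a classifier that separates the classes
must have learned positional structure, which is precisely the claim
made for these architectures. With substitution probability 0 an exact
sliding-window scan separates the classes perfectly, giving a ground
truth; at 0.1 the Bayes decision on the leader window (identity ≥ 5/10,
from the binomial likelihood ratio of a 90% match rate against the
~5.5% background coincidence rate) is the reference the trained network
is compared against. That bound holds in expectation, so the package's
checks allow one held-out sequence of sampling slack.

What the generator does **not** emulate: the class diversity of real
RiPP families, leader/core cleavage structure, phylogenetic correlation
between sequences, and length–composition dependence. Passing the
synthetic checks therefore demonstrates that the encoder, architectures
and training loop work as specified and can extract positional motif
signal — it does not certify accuracy figures on real corpora.

## Problem sizes used by the checks

The packaged tests and the acceptance script run a full study on 300
positives at 7:1 imbalance (2100 negatives) with the parallel CNN —
the architecture the training-set comparison singles out as most
accurate — at a round budget of 40 with patience 20. Those sizes were
chosen so a complete run takes a few minutes on one CPU while leaving
the loop's behavior (resampling cadence, checkpointing, stopping)
fully exercised; the memorization checks use a 50-sequence noise-free
corpus. All other defaults during these runs are the package defaults
described above.

## Known limitations

* Training is CPU-bound R; corpora of tens of thousands of sequences
  train in hours, not minutes. The architecture defaults were validated
  at desk scale.
* Only the canonical 20-letter alphabet is supported; selenoproteins and
  ambiguity codes are excluded by design.
* The classifier inherits the biases of whatever positive corpus it is
  trained on; class-independent does not mean bias-free.
* Exact reproducibility is per-machine (fixed BLAS threading); histories
  are byte-identical across runs on one machine, not across BLAS builds.

## A minimal session

```{r example}
library(rippnet)

sets <- generate_imbalanced(synthetic_spec(300, 300, seed = 1), ratio = 7)
cfg <- training_config(max_rounds = 40, patience = 20, seed = 1)
model <- build_model(model_spec("cnn_parallel"), seed = 1)
run <- train_model(model, sets$positives, sets$negatives, cfg)
run

full <- peptide_set(c(sets$positives$id, sets$negatives$id),
                    c(sets$positives$sequence, sets$negatives$sequence),
                    label = c(sets$positives$label, sets$negatives$label))
evaluate_model(run$model, encode_batch(full))

save_model(run$model, "my_model")
res <- classify_fasta("candidates.fasta", "my_model")
write_predictions(res$predictions, "predictions.tsv")
```
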