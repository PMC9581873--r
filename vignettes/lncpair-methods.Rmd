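---
title: "Methods: sequence-pair classification with region-restricted fixed lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-pair classification with region-restricted fixed lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpair)
```

## The problem

Long non-coding RNAs (lncRNAs, > 200 nt) regulate gene expression partly by
interacting with micro-RNAs (miRNAs, 17–25 nt) and proteins. Predicting
which (lncRNA, partner) pairs interact, from raw sequence alone, is a binary
classification problem whose main practical obstacle is length: lncRNAs in
real interaction corpora span two orders of magnitude (hundreds to tens of
thousands of residues), while recurrent classifiers require a fixed-length
input. `lncpair` implements a lightweight recurrent classifier for this
problem together with the preprocessing idea that makes it work: instead of
padding or truncating whole lncRNAs, keep only a short *positional
sub-sequence* — the first X residues, the last Y, or both — and let the
classifier decide the pair label from that window plus the full (short)
partner sequence.

## Fixed-length policies

Six policies are supported, all acting on the *end* of sequences (the
dominant convention for padding and truncation):

* `max_pad` — pad every sequence to the training-corpus maximum with a
  reserved symbol (`-` by default, outside every residue alphabet);
* `min_trunc` — truncate every sequence to the corpus minimum;
* `avg_hybrid` — pad shorter and truncate longer sequences to the
  round-half-up corpus mean (the rounding rule is ours; "average" alone
  does not fix one);
* `start`, `end`, `start_end` — keep the first X, last Y, or first-X plus
  last-Y residues.

Corpus statistics (min/mean/max) are always computed on the training split
only; held-out sequences outside the training range are padded/truncated to
the same target, so every emitted instance has the same length — the
fixed-length contract that the tokenizer and model rely on. Sub-sequence
budgets larger than a sequence are legal: the window is end-padded to the
exact budget, and for `start_end` the two windows may overlap (with a
warning). These cases do not arise for real lncRNA–miRNA corpora (minimum
lncRNA ≈ 213 nt versus budgets ≤ 50) but do for lncRNA–protein sets whose
lncRNAs go down to 15 nt.

Coordinates are 1-based inclusive in documentation and logs; internal
slicing is half-open.

## Tokenization

Fixed-length sequences are decomposed into *higher-order residues*: k-mers
produced by a window of size `k` sliding with stride `s` (overlapping when
`s < k`). The token count is exactly `floor((L - k)/s) + 1`. The vocabulary
enumerates all `|alphabet|^k` k-mers (4^k for RNA) in lexicographic order —
full enumeration keeps indices corpus-independent — plus two reserved
indices: `PAD` (0) for any k-mer overlapping the padding region and `UNK`
(1) for any k-mer containing an ambiguity symbol (`N`/`X`). Pairs are
tokenized *segment-wise*: the lncRNA window and the partner are tokenized
separately and concatenated as token sequences, so no chimeric k-mer spans
the junction (such tokens would be artifacts of concatenation, not
biology). Mixed-alphabet tasks use one vocabulary per segment, offset into
a single index space behind one embedding table. Defaults follow the
reported grid-search optima: `k = 5`, stride 1 for RNA–RNA; `k = 1` for
RNA–protein.

## The classifier

Each tokenized pair flows through:

1. **Learned embeddings** (`n_embedding = 120`): a `vocab × 120` table
   initialized from a standard normal (PAD row zero), with two dropout
   schemes during training — whole token vectors dropped with probability
   0.004 and individual entries with probability 0.005.
2. **A single-layer LSTM** (`H = 120`) with the standard gate equations
   (`i/f/o` sigmoid gates, tanh candidate, `c_t = f_t ⊙ c_{t-1} + i_t ⊙
   ĉ_t`, `h_t = o_t ⊙ tanh c_t`), regularized by **DropConnect**: a single
   Bernoulli(0.004) mask zeroes entries of the hidden-to-hidden matrices
   for an entire forward/backward pass, so a dropped weight contributes at
   no time step.
3. **Triple pooling**: elementwise max over time, mean over time, and the
   last hidden state, concatenated in that order into a `3H = 360` vector.
4. **Batch normalization → dropout(0.1) → dense 360→50 (sigmoid) → batch
   normalization → dropout → dense 50→2 → softmax**, trained with
   categorical cross-entropy.

The two batch-norm layers are distinct (separate statistics). All dropout
layers use the inverted convention (scale by `1/(1-p)` at train time), so
eval mode is deterministic; the classical test-time `(1-p)` scaling is
mathematically equivalent in expectation and available via
`scale_at_test`. Gate biases are included by default (forget-gate bias
initialized to 1, standard LSTM practice) with `use_bias = FALSE` for the
literal bias-free equations. The hidden state is reset per instance
(`h_0 = c_0 = 0`): for independent pair classification over shuffled
batches, statefulness across batches has no meaning. PAD positions are
embedded (zero-initialized but trainable) and included in pooling.

One printed source of the design gives the LSTM width as 2^4 units while
repeatedly describing a 360-dimensional pooled vector entering a 360→50
dense layer; these are irreconcilable, and we follow the 3 × 120 = 360
reading, exposing `n_hidden` for anything else.

### Training

AdamW with *decoupled* weight decay: moments are computed on the raw
gradient and the decay term `-lr·λ·w` is applied directly in the update, so
the penalty is not rescaled by the adaptive denominator (folding `2λw` into
the gradient — L2 regularization — provably differs whenever second moments
differ across parameters; the test suite constructs such a counterexample).
Defaults: learning rate 0.01, λ = 0.02, batch size 64 (0.05 / 0.01 /
dropout 0.4 for the protein task). The learning rate decays by ×0.95 per
epoch (the schedule's existence is part of the design; its factor is ours).
Early stopping monitors validation loss with patience 5; the best
validation checkpoint is returned. Batch-norm training statistics need at
least two instances, so a trailing batch of size 1 is skipped. Everything —
shuffling, initialization, every dropout mask — derives from one integer
seed, making two same-seed runs bitwise identical.

### Numerical choices

Batch normalization uses biased batch variance, ε = 1e-5 and running-stat
momentum 0.1. Softmax subtracts the row maximum before exponentiation;
cross-entropy clamps probabilities at 1e-12. Max-pooling ties resolve to
the earliest time step. Backpropagation is analytic throughout and verified
against central finite differences (relative error < 1e-4 on a toy batch
with stochastic layers disabled, typically ~1e-6).

## Evaluation

`compute_metrics()` reports confusion counts at a 0.5 threshold plus ACC,
specificity, sensitivity, precision, F1, MCC and AUROC. MCC uses the
standard formula `(TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; AUROC
is the Mann–Whitney rank statistic with midranks, which handles ties
exactly (a trapezoid over thresholds does not). Ratios with zero
denominators are reported as 0 and flagged in an `undefined` column rather
than raising, so large sweeps survive degenerate folds. Cross-validation is
label-stratified (stratification keeps per-fold metrics stable; a flag
disables it) with 10% of each training split — 10% of *pairs*, since pairs
are the instances — tagged for validation. Reported CV metrics are
unweighted fold averages; pooling over folds is the obvious alternative and
per-fold rows are returned so either can be computed.

## The synthetic corpus generator

Real benchmark corpora (lncRNASNP2/GENCODE/miRBase-derived pairs; the
RP1369 protein set) are not deposited with accessions, so the package ships
a generator that emulates their *structure*: uniform-background sequences
with lncRNA lengths 200–2,000 nt by default (a log-uniform option imitates
the heavy right tail of real corpora, mean ≈ 1,400 ≪ max ≈ 22,700), short
partners (17–25 nt RNA, or proteins), and a planted, optionally mutated and
jittered motif at a configurable region (start/end/middle/none) of the
lncRNAs in interactive pairs. Defaults — a fixed 10-mer motif, offset
jitter 5, substitution rate 0.05 — were chosen once as a plausibly noisy
but recoverable signal.

The signal model is deliberately minimal: coordinated motif planting rather
than hybridization thermodynamics, because it makes "which lncRNA region is
informative" a recoverable ground truth while remaining cheap. Two
consequences matter for interpreting tests. First, every sequence occurs in
exactly one pair — positives get fresh planted sequences, and negatives are
a one-to-one random matching (two independent Knuth–Durstenfeld shuffles)
of fresh unplanted background sequences. Real corpora instead reuse
partners heavily; we keep usage symmetric across classes because any
asymmetric reuse lets a classifier exploit sequence identity across folds,
which would contaminate the null (`motif_region = "none"`) calibration.
Second, the partner side carries no label signal by default
(`partner_tag = NULL`); planting a coordinated partner tag is supported,
but then *any* region setting can classify through the always-complete
partner segment, and the region contrast is no longer identified. Passing
region-recovery tests on this generator therefore demonstrates that the
pipeline recovers positional signal placement — not that it reaches any
particular accuracy on real corpora.

For generating negatives on *real* corpora, `generate_negatives()`
implements the published scheme as stated: shuffle both id lists 10 times
(Knuth–Durstenfeld), then draw random pairs with replacement, rejecting
collisions with positives — and, additionally, duplicate negatives
(otherwise label counts are ill-defined), capping rejection at 100·n
attempts.

## Experiment scales

The packaged experiments are desk-scale by design and state their sizes
explicitly: `region_recovery_experiment()` uses 2,000-pair corpora, a
10-residue start motif, X = Y = 20, stratified 5-fold CV and three seeds,
with a small model configuration (3-mers, 32-dimensional embeddings and
hidden units, ≤ 6 epochs) — the region *contrast*, not the accuracy
ceiling, is the quantity of interest, and it is insensitive to model width
here. `null_calibration_experiment()` trains the same configuration on
1,000 exchangeable pairs and checks that held-out AUROC sits near 0.5.
Published-scale corpora (15k+ pairs, 120-dimensional models, full 5–50
budget sweeps via `region_sweep()`) run with the same code, just longer.

## Known limitations

* Uniform background sequences have no composition structure (GC bias,
  repeats, secondary structure); real discriminative signal is unlikely to
  be a single contiguous motif.
* Padding tokens are embedded and pooled (faithful to the design it
  implements); a masking flag exists for ablation but is not the default.
* The de-duplication status of pairs sharing identical sequences under
  different ids in the original benchmark is unknown; loaders enforce
  unique `(a_id, b_id)` keys only.
* Pure-R matrix code is fast enough for desk-scale corpora (minutes) but
  not for GPU-scale hyperparameter searches.
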