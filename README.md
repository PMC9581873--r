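# lncpair

Sequence-based prediction of long non-coding RNA (lncRNA) interactions with
short partner molecules — miRNAs (17–25 nt) or proteins — using a
lightweight recurrent classifier and, crucially, *region-restricted
fixed-length preprocessing*: instead of padding or truncating wildly
variable lncRNAs (hundreds to tens of thousands of residues), only the
first X residues, the last Y, or both are kept as the lncRNA's
representation.

The classifier is a single-head network over tokenized (lncRNA, partner)
pairs:

```
k-mer ids ──▶ learned embeddings (vocab × 120, dual dropout)
          ──▶ single-layer LSTM, H = 120, DropConnect on U matrices
          ──▶ [max ‖ mean ‖ last] pooling  →  3H = 360 features
          ──▶ batch norm → dropout(0.1) → dense 360→50 (σ)
          ──▶ batch norm → dropout → dense 50→2 → softmax
```

with the standard gate equations `i_t = σ(Wⁱx_t + Uⁱh_{t−1} + bⁱ)`, …,
`c_t = f_t ⊙ c_{t−1} + i_t ⊙ ĉ_t`, `h_t = o_t ⊙ tanh c_t`, trained by AdamW
(decoupled weight decay: `w ← w − lr·m̂/(√v̂+ε) − lr·λ·w`), per-epoch
learning-rate decay and early stopping. Evaluation reports ACC, SPE, SEN,
PRE, F1, `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and
rank-based AUROC. The embedding/LSTM/batch-norm stack, its analytic
backpropagation and the AdamW optimizer are implemented in plain R matrix
code inside the package.

Everything is testable offline: a seeded synthetic-corpus generator plants
region-localized motifs in interactive pairs, making "which lncRNA region
carries the signal" a recoverable ground truth.

## Worked example

```r
library(lncpair)

# a 600-pair corpus with a 10-nt motif planted at the start of
# interactive lncRNAs (lengths 200-2000 nt; miRNA-like partners)
corpus <- generate_corpus(synthetic_config(n_pos = 300, n_neg = 300, seed = 1))
corpus
#> <paired_corpus> 600 lncRNAs, 600 partners (RNA), 600 pairs (300+/300-)

# 5-fold CV reading only the FIRST 20 lncRNA residues
cv_start <- cross_validate(
  corpus, length_policy("start", X = 20), kmer = 3,
  model_args = list(n_embedding = 32, n_hidden = 32),
  train = train_config(max_epochs = 6), seed = 1)
glance(cv_start)
#> # A tibble: 1 × 7
#>     ACC   SPE   SEN   PRE    F1   MCC AUROC
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.948 0.963 0.933 0.962 0.948 0.897 0.989

# the LAST 20 residues carry no signal: chance-level performance
cv_end <- cross_validate(
  corpus, length_policy("end", Y = 20), kmer = 3,
  model_args = list(n_embedding = 32, n_hidden = 32),
  train = train_config(max_epochs = 6), seed = 1)
round(glance(cv_end)$ACC, 3)
#> [1] 0.477
```

The contrast is the point: ~0.95 accuracy from the first 20 residues
versus chance from the last 20 shows the pipeline recovers where the
interaction signal lives. `region_sweep()` produces the full
setting × budget table (budgets 5–50 in steps of 5) and
`autoplot()` draws it; `grid_search()` ranks hyperparameter candidates on a
validation split; `tidy()`/`glance()` return per-fold and summary tibbles.

A thin command-line wrapper (`inst/cli/lncpair.R`) exposes
`simulate / preprocess / train / evaluate / predict / sweep` with
`--config` (YAML), `--seed` and `--out`; every artifact directory records
the resolved configuration and seed.

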