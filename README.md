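# neoimm

Neoantigen immunogenicity prediction from peptide–MHC features, in R.

Tumor-specific peptides (neoantigens) arising from somatic mutations can be
presented on MHC class I molecules and recognized by CD8+ T cells. Binding
affinity alone is a poor predictor of whether a presented peptide actually
elicits a T-cell response, so `neoimm` models immunogenicity directly: a
two-branch convolutional neural network reads the one-hot encoded peptide
(8–11-mers, padded to 11×21) and the MHC allele's 33-residue pseudo-sequence
(33×21), fuses the two branch representations with min–max-normalized
binding affinity (IC50, nM) and TAP transport efficiency, and outputs a
sigmoid immunogenicity score in [0, 1]. The package is aimed at
computational immunologists building neoantigen prioritization pipelines on
top of standard upstream predictors (binding affinity, TAP score, expression).

## The model

Each branch applies two consecutive convolutional layers (16 then 32
filters, kernel 3 over sequence positions) followed by three dense layers,
flattening to a 256-dimensional vector. The two 256-vectors are concatenated
with the two feature scalars and passed through two fusion dense layers
(64, 32) to the sigmoid output. Training minimizes class-weighted binary
cross-entropy with Adam (learning rate 0.001, batch size 64, at most 200
epochs) under dual early stopping — patience 15 on training loss, patience
20 on validation loss — restoring the best validation-loss weights. The
class weight for class *c* with *S_c* of *T* training instances is

    w_c = (1 / S_c) · (T / 2)

so each class contributes equal total weight. Data are split 70/20/10 into
train/test/validation. The whole training stack (convolutions as shifted
BLAS matrix products, batch normalization, dropout, Adam, backpropagation)
is implemented in the package itself; training at the reference study size
(2,000 records) takes about a minute on one CPU core.

Around the network the package provides:

* **Curation** — the filter chain that turns raw T-cell assay tables into a
  labelled dataset: keep only ELISPOT / 51 Chromium / ICS /
  multimer–tetramer / ELISA assays, require 4-digit HLA alleles and
  8–11-mer peptides, drop duplicates and negative records with fewer than
  four test subjects, and collapse conflicting labels in favor of the
  positive.
* **Baselines** — logistic regression (L2, C = 2.21), RBF SVM
  (gamma = 0.1, C = 10), gradient-boosted trees, random forest and
  extremely randomized trees on the identical flattened features.
* **Ranking** — the candidate selection rule TAP > 0, IC50 ≤ 500 nM,
  TPM > 0, immunogenicity > 0.5, followed by deterministic ranking.
* **Synthetic data** — a seeded generator of assay/feature tables with a
  planted, learnable immunogenicity rule and known Bayes-optimal scores, so
  the whole pipeline is testable without any external download.

## Worked example

```r
library(neoimm)

sim <- simulate_assays(simulation_config(n_records = 2000, seed = 7))
curated <- assign_splits(curate(sim$assays), seed = 1)
print(curated)
#> Curated immunogenicity dataset: 2000 (peptide, allele) pairs, 786 positive / 1214 negative
#> records removed per stage: assay_filter=0, allele_filter=0, exact_duplicates=0,
#>   length_filter=0, thin_negatives=0, pair_collapse=0
#> splits: test=400, train=1400, validation=200

model <- train_cnn(curated, sim$features, sim$pseudo_table,
                   cnn_config(seed = 1, ic50_scale = "log"))
test <- merge(curated[curated$split == "test"], sim$features,
              by = c("peptide", "allele"))
scores <- predict(model, test)

auroc(scores, test$label)
#> [1] 0.946601
cor(scores, oracle_scores(sim$truth, test), method = "spearman")
#> [1] 0.9231973
```

Held-out AUROC 0.947 against a Bayes-optimal ceiling of ~0.98, and rank
correlation 0.92 with the generator's true latent probabilities: the network
recovers most of the planted rule. Scored candidates are then filtered and
ranked:

```r
test$immunogenicity <- scores
ranked <- rank_candidates(filter_candidates(test))
head(ranked[, c("peptide", "allele", "immunogenicity", "rank", "rank_percentage")])
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `curate`, `train`, `predict`, `rank`, `compare`, `evaluate`,
`run`) lives at `system.file("cli", "neoimm.R", package = "neoimm")`.

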