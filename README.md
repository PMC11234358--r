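# fusedta

Multi-dimensional embedding fusion for drug–target binding affinity
prediction.

Predicting how strongly a small molecule binds a protein — a pKd in
roughly [5, 10] on DAVIS-style kinase panels, a composite score in roughly
[9, 16] on KIBA-style data — is a regression problem at the heart of
computational drug discovery. `fusedta` is for researchers who want a
self-contained, fully reproducible implementation of a *late-fusion*
approach to that problem: drugs and proteins are each embedded at three
levels of structural resolution, and a trainable network fuses all six
views into one affinity prediction.

## The model

Each entity gets up to three fixed-width embeddings:

| slot | drug (width) | protein (width) |
|---|---|---|
| 1D | substructure skip-gram, 100 | k-mer skip-gram, 100 |
| 2D | GIN graph message passing, 300 | multi-head self-attention encoder, 768 |
| 3D | distance-featured (E(3)-invariant) message passing over a conformer, 512 | precomputed-embedding file adapter, 1280 |

Every embedding x is L2-normalized and passed through its own dense block
ReLU(W x + b) with 1024 units; block outputs are concatenated (drug
1D/2D/3D, then protein 1D/2D/3D) and fed to the prediction head

    a = FC1(1024) -> dropout -> FC2(1024) -> dropout -> FC3(512) -> dropout -> linear(1)

trained with Adam (learning rate 1e-4, batch 64, at most 500 epochs, early
stopping on validation MSE) to minimize the mean squared error between
predicted and measured affinity. Evaluation uses the four metrics standard
in this literature — MSE, concordance index (CI), r_m², and AUPR after
binarizing at a dataset threshold (7 for pKd, 12.1 for KIBA scores) — plus
McNemar tests for paired classifier comparisons, and two ablation
harnesses: leave-one-embedding-out and single-dimension pairwise
concatenation without fusion blocks.

A synthetic benchmark generator plants a bilinear latent signal (affinity
= drug-latent · protein-latent, rescaled and noised) in any chosen subset
of the six embeddings, so every claim — signal recovery, ablation
ordering, chance-level behavior — is testable offline with no downloads
and no pretrained weights.

## Worked example

Generate a small fully informative benchmark, train a reduced-width
fusion model, and evaluate on held-out pairs:

```r
library(fusedta)

spec <- synthetic_spec(n_drugs = 60, n_proteins = 40, density = 0.5,
                       informativeness = 1, noise_sd = 0.25,
                       widths = list(drug_1D = 32, drug_2D = 48, drug_3D = 64,
                                     protein_1D = 32, protein_2D = 48,
                                     protein_3D = 64),
                       seed = 1)
gen <- generate_embeddings_and_affinity(spec)
#> Interaction table: 1189 pairs, 60 drugs, 40 proteins, scale=pKd

sp <- split_data(gen$table, split_spec(test_fraction = 0.2, n_folds = 5,
                                       seed = 1))
#> Split: 951 train / 238 test rows, 5 folds, seed 1, unit 'pair'

fold  <- sp$folds[[1]]
train <- sp$train[fold$train, ]
val   <- sp$train[fold$validation, ]

cfg <- fusion_config(block_dense_width = 64, head_widths = c(128, 64, 32),
                     dropout = 0, learning_rate = 3e-3, max_epochs = 60,
                     early_stop_patience = 10, seed = 1)
widths <- c(setNames(lapply(gen$drug, `[[`, "width"),
                     paste0("drug_", names(gen$drug))),
            setNames(lapply(gen$protein, `[[`, "width"),
                     paste0("protein_", names(gen$protein))))
model <- build_fusion_model(cfg, widths)
#> Fusion model: dims [drug_1D, drug_2D, drug_3D, protein_1D, protein_2D,
#>   protein_3D], 64-unit blocks, head 128/64/32, 78465 parameters

model <- train_fusion_model(
  model,
  assemble_inputs(train, gen$drug, gen$protein, cfg), train$affinity,
  assemble_inputs(val, gen$drug, gen$protein, cfg), val$affinity)

yhat <- predict(model, assemble_inputs(sp$test, gen$drug, gen$protein, cfg))
evaluate_predictions(sp$test$affinity, yhat, threshold = 7)
#> Evaluation report
#>   n         238
#>   threshold 7
#>   MSE       0.2332
#>   CI        0.8671
#>   r_m^2     0.6610
#>   AUPR      0.9647
```

An MSE of 0.23 against an injected noise variance of 0.0625 and a CI of
0.87 say the small network recovers most, but not all, of the planted
bilinear signal at this data size; the full acceptance benchmark below
uses five times as many pairs and a wider network and reaches CI > 0.9
with MSE under twice the noise variance. The AUPR of 0.96 reflects how
easy the binarized task (threshold 7 = the range midpoint) is once ranking
is mostly right.

The ablation harnesses run the same way from an embedding bundle:

```r
study <- run_exclusion_study(gen, cfg, split_spec(seed = 1), threshold = 7)
```

gives one row per excluded embedding plus the full model, on an identical
split, mirroring the leave-one-out protocol; `run_pairwise_study()` covers
the nine single-dimension drug+protein combinations with fusion blocks
bypassed.

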