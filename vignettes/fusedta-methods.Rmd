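---
title: "Multi-dimensional embedding fusion for binding affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dimensional embedding fusion for binding affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Drug–target affinity (DTA) prediction is a regression task: given a small
molecule and a protein, predict a continuous binding strength — a pKd in
roughly [5, 10] for DAVIS-style kinase panels, or a composite KIBA score in
roughly [9, 16]. `fusedta` implements a late-fusion architecture for this
task: drugs and proteins are each represented at three "dimensions" of
structural resolution, every representation is L2-normalized and passed
through its own dense block, and the concatenated block outputs feed a
three-layer regression head.

The package is deliberately self-contained. It does not download benchmark
data and does not depend on GPU-scale pretrained encoders; the slots that a
production pipeline would fill with large pretrained embeddings are served
either by small self-trained encoders or by the precomputed-embedding file
adapter (`load_embeddings()`), and a synthetic benchmark generator exercises
every claim end to end.

# Representations

**Drug 1D — substructure skip-gram.** A molecule is tokenized into circular
atom environments (`tokenize_substructures()`): the radius-0 token encodes
element and degree, the radius-r token appends the sorted multiset of
(bond order, neighbor token at r−1). This is an iterated Weisfeiler–Lehman
relabeling, so two atoms share a token exactly when their environments up
to that radius agree. A skip-gram model with negative sampling
(`train_skipgram()`) embeds tokens; a molecule embeds as the sum of its
token vectors (width 100). Sum aggregation makes the embedding additive
over token multisets — a property the tests exploit — and unknown tokens
contribute zero rather than erroring, because a deployment molecule can
contain environments never seen in training.

**Drug 2D — GIN message passing.** The molecular graph (heavy atoms as
nodes, bonds as edges, element/degree one-hots as node attributes, bond
orders as edge attributes) is embedded by graph-isomorphism-network layers:
`h_i ← MLP((1 + ε) h_i + Σ_{j∈N(i)} h_j)`, followed by a sum readout and a
linear map to width 300. Sum aggregation with a (1+ε) self-weight is the
maximally discriminative choice among standard neighborhood aggregators and
is exactly permutation invariant. In place of large-scale unsupervised
pretraining the package uses random frozen parameters under a fixed seed
(`gin_init_params()`); random message-passing features still separate
non-isomorphic graphs, and the fusion head downstream is the trained
component.

**Drug 3D — distance-featured message passing.** Coordinates enter messages
only through squared interatomic distances, so the embedding (width 512) is
invariant under rotations, reflections and translations by construction
while remaining sensitive to bond lengths and conformer geometry — the
testable contract that matters to the fusion head, which consumes a single
invariant vector per molecule. `generate_conformer()` supplies coordinates
as a classical-MDS embedding of graph shortest-path distances (bond length
1.5 units) plus a small seeded jitter that breaks planar degeneracies. This
is a deterministic geometric layout, not an energy-minimized conformer; it
was chosen over force-field generators because seed-exact reproducibility
is a package-level guarantee and conformer search tools do not offer it.

**Protein 1D — k-mer skip-gram.** Overlapping 3-mers (the conventional
protein "word" size) are embedded by the same skip-gram machinery and
summed (width 100).

**Protein 2D — small attention encoder.** A deliberately minimal
transformer-style encoder (`attention_encode()`): residue embeddings plus
sinusoidal positions, stacked multi-head scaled dot-product attention
layers (softmax(QK'/√d)V, heads concatenated and mixed by W_o), mean
pooling, and a linear projection to width 768. There are no residual
connections or feed-forward sublayers — with zeroed query/key weights the
encoder reduces exactly to a value-projection mean, which the tests verify
by hand. Sequences longer than 2,600 residues (above the longest benchmark
sequence) are tail-truncated with a warning.

**Protein 3D — file adapter.** Structure-aware embeddings of width 1280 are
loaded from the columnar text format; the package does not attempt
structure prediction. Any fixed-width vector source works — the fusion
architecture only requires consistent widths and ids.

# The fusion model and training protocol

Each selected dimension's vectors are L2-normalized (zero vectors pass
through unchanged with a warning, since an all-unknown-token molecule
legitimately embeds to zero), pass through an independent
dense(1024)+ReLU block, and are concatenated in the fixed order drug
1D/2D/3D then protein 1D/2D/3D — the order is arbitrary but frozen for
reproducibility. The head is FC1(1024) → dropout → FC2(1024) → dropout →
FC3(512) → dropout → linear(1); dropout is 0.3 and is applied in the head
only (a `block_dropout` flag extends it to the blocks). Training minimizes
MSE with Adam at learning rate 1e-4, batch size 64, for at most 500 epochs
with early stopping; the monitor is validation MSE with patience 20 and
best-weights restoration — the patience and monitor are package choices
where the protocol only says "early stopping". Weights are initialized by
a fan-in uniform scheme under the config seed; every random stream (init,
batch order, dropout) derives a private sub-seed via `derive_seed()`, so
changing one stage never perturbs another.

Splits are random over interaction rows: 80% train / 20% test, with 5-fold
cross-validation inside the training rows for validation and fold-wise
metric standard deviations. Cold-drug and cold-protein splits are provided
as an optional stricter mode but are not the default protocol.

# Metrics

* **MSE** on the continuous affinities.
* **CI** (concordance index): fraction of correctly ranked pairs among
  pairs with distinct true affinity; prediction ties count 0.5, truth ties
  are excluded from the denominator (the dominant convention). Invariant
  under strictly increasing transforms of the predictions.
* **r_m²** = r²(1 − √|r² − r0²|), the single (non-averaged) variant, with
  r0² the through-origin coefficient of determination of predictions on
  observations. The |r² − r0²| gap is clamped to zero below 1e-12 before
  the square root, which otherwise amplifies rounding noise at perfect
  agreement.
* **AUPR** by average precision (step summation, no interpolation — the
  interpolated trapezoid is optimistically biased), after binarizing
  affinities at a dataset threshold: 7 for pKd data, 12.1 for KIBA scores.
  Values equal to the threshold are positive; the boundary rule is a
  package decision (`positive_if = "ge"`).
* **McNemar** on two classifiers' discordant counts: exact two-sided
  binomial below 25 discordant pairs, continuity-corrected chi-square
  above; zero discordance degenerates to p = 1 with a warning. It applies
  to binarized predictions only — the package takes no position on how a
  paired test should be formed from continuous regression errors.

# The synthetic benchmark

`synthetic_spec()` defines the study conditions. Each drug i and protein j
carries a standard-normal latent (width 4 by default — affinity matrices
are approximately low-rank, and a small latent keeps the ground truth
within reach of a desk-scale network); the true affinity is the dot product
u_i·v_j, with its mean ± 2 sd band mapped affinely onto the affinity range
(default [5, 10]) and saturated at the bounds — emulating the censoring
that piles DAVIS affinities up at the pKd = 5 floor — plus Gaussian noise
(default sd 0.25, a plausible inter-assay error on the pKd scale). A
bilinear target is the point: it is learnable by the fusion network but not
linear in any single embedding nor in their concatenation.

Each of the six embeddings is `w·([latent, 1] P) + (1 − w)·noise` for a
fixed random projection P and informativeness weight w. The appended
constant coordinate matters: the pipeline L2-normalizes every embedding,
and without a fixed-scale coordinate normalization would discard the latent
magnitude, capping even a Bayes-optimal predictor's concordance near 0.89
under the default noise. With it, normalization is information-preserving.
Per-dimension noise is independent across dimensions so that exclusion
ablations have a well-defined expected ordering.

What the generator does **not** emulate: real chemistry (drugs are drawn
from a small pool of valid toy SMILES), real sequence statistics (proteins
are uniform random 200–1500-mers), assay heteroscedasticity, and the
cold-start structure of real benchmarks. Passing tests on this generator
demonstrates that the architecture, training loop, metrics and ablation
harnesses are correct and that the model recovers a planted cross-modal
signal — not that the package reproduces published benchmark numbers,
which require the original data sets and GPU-scale pretrained encoders.

# Ablation harnesses

`run_exclusion_study()` trains the full model plus the six
leave-one-embedding-out variants; `run_pairwise_study()` trains the nine
single-dimension (drug dim, protein dim) pairs with the fusion blocks
bypassed — raw normalized embeddings concatenated straight into the head —
plus the full reference. All variants share the split and seeds, so rows
are comparable; the block width is held fixed when a dimension is excluded
(the head input simply shrinks), since capacity matching is not part of the
protocol. Pair variants normalize before concatenation for comparability
across widths; a flag disables this.

# Desk-scale study sizes and training settings

The bundled acceptance analyses run on one CPU at reduced widths; the
sizes below are the package's own reproducibility conditions:

* **Signal recovery**: 200 drugs × 100 proteins at density 0.3 (~6,000
  pairs), informativeness 1, noise sd 0.25, generator seed 7; blocks of
  width 128 with a 256/128/64 head, learning rate 1e-3, dropout 0, up to
  200 epochs with patience 25. At 1/64 of the full-scale capacity the
  full-scale regularization is counterproductive: dropout tuned for
  1024-wide blocks under-fits a 128-wide network, so the desk-scale runs
  rely on early stopping alone, and the learning rate is raised one order
  to converge within the epoch budget. Expected outcome: test CI ≥ 0.90
  and test MSE within twice the injected noise variance (0.0625).
* **Ablation ordering**: signal placed only in the two 3D slots; 80 drugs
  × 50 proteins at density 0.4, small widths. Excluding either 3D
  embedding removes the only copy of one side's latent and must produce
  the two worst exclusion MSEs; the 3D+3D pair must win the pairwise
  study.
* **Chance-level control**: informativeness 0 everywhere; the trained
  model's test CI must average ≈ 0.5 over 10 seeds — a guard against
  leakage anywhere in the split/training path.

# Numerical and degenerate-input choices

* The concordance index is computed by an O(n²) pair comparison, chunked
  to bound memory; an independent brute-force loop serves as its oracle in
  the tests.
* Score ties in average precision are broken by input order; random-score
  tests avoid ties by construction.
* `kd_to_pkd()` requires strictly positive Kd (nM) and inverts through
  `pkd_to_kd()` to 1e-9 relative tolerance across fifteen decades.
* Empty inputs: `binarize_affinity()` maps empty to empty; an empty
  interaction table refuses to split.
* Skip-gram training visits sentences in corpus order with a fixed context
  window (no window subsampling) so results are bit-reproducible; the
  negative-sampling distribution is the unigram count to the 3/4 power.
* `smiles_to_graphs()` parses in batch; unparseable SMILES either abort
  with the drug id (default) or are dropped with a warning (featurization
  CLI policy, so one bad molecule cannot kill a batch).

# Known limitations

* The 2D/3D drug encoders and the attention encoder are untrained feature
  extractors under fixed seeds unless embedded in end-to-end training;
  they are reproducible and structurally faithful, but their features are
  not semantically pretrained.
* The 3D route uses a single MDS-layout conformer per molecule; multiple
  conformers, energy minimization and stereochemistry are out of scope.
* McNemar comparisons of continuous metrics are not defined here; only
  binarized-prediction comparisons are offered.
* The synthetic generator's monotone-informativeness property holds for
  the bilinear target only when the partner side carries signal — with
  every other dimension at zero informativeness no method can rank pairs,
  which is exactly what the chance-level control verifies.
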