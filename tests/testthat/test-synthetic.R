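# The oracle regressor used here fits a linear model on the outer products
# of low-rank PCA scores of the drug and protein embedding matrices — an
# independent route to the bilinear latent signal that never touches the
# fusion network.
oracle_bilinear_ci <- function(gen, drug_dim = "3D", protein_dim = "3D",
                               rank = 6L, test_frac = 0.2, seed = 99L) {
  demb <- gen$drug[[drug_dim]]$vectors
  pemb <- gen$protein[[protein_dim]]$vectors
  dsc <- svd(scale(demb, scale = FALSE), nu = rank, nv = 0L)$u
  psc <- svd(scale(pemb, scale = FALSE), nu = rank, nv = 0L)$u
  rownames(dsc) <- rownames(demb); rownames(psc) <- rownames(pemb)
  tab <- gen$table
  # main effects plus all products: centering the embeddings turns the
  # latent dot product into bilinear-plus-linear structure
  feats <- t(vapply(seq_len(nrow(tab)), function(r) {
    d <- dsc[tab$drug_id[r], ]; p <- psc[tab$protein_id[r], ]
    c(d, p, as.numeric(outer(d, p)))
  }, numeric(2L * rank + rank * rank)))
  set.seed(seed)
  te <- sample.int(nrow(tab), round(test_frac * nrow(tab)))
  df <- data.frame(y = tab$affinity, feats)
  # censoring-aware: fit on rows away from the saturated range bounds
  rng <- gen$spec$affinity_range
  interior <- tab$affinity > rng[1L] + 1e-9 & tab$affinity < rng[2L] - 1e-9
  fit <- lm(y ~ ., data = df[setdiff(which(interior), te), ])
  concordance_index(tab$affinity[te], predict(fit, df[te, ]))
}

small_widths <- list(drug_1D = 16L, drug_2D = 20L, drug_3D = 24L,
                     protein_1D = 16L, protein_2D = 20L, protein_3D = 24L)

test_that("generated entities are reproducible, valid and shaped to spec", {
  spec <- synthetic_spec(n_drugs = 10L, n_proteins = 8L, seed = 5L)
  e1 <- generate_entities(spec)
  e2 <- generate_entities(spec)
  expect_identical(e1$drugs, e2$drugs)
  expect_identical(e1$proteins, e2$proteins)
  expect_equal(nrow(e1$drugs), 10L)
  # every emitted SMILES parsed into a graph
  expect_length(e1$graphs, 10L)
  expect_true(all(vapply(e1$graphs, inherits, TRUE, "molecular_graph")))
  lens <- nchar(e1$proteins$sequence)
  expect_true(all(lens >= 200L & lens <= 1500L))
})

test_that("a dense DAVIS-shaped spec emits the full interaction grid", {
  spec <- synthetic_spec(n_drugs = 68L, n_proteins = 442L, density = 1,
                         seed = 1L)
  gen <- generate_embeddings_and_affinity(spec)
  expect_equal(nrow(gen$table), 68L * 442L)   # 30,056 pairs
  expect_equal(gen$drug[["3D"]]$width, 512L)
  expect_equal(gen$protein[["3D"]]$width, 1280L)
})

test_that("affinities stay in range and noise does not touch embeddings", {
  spec <- synthetic_spec(n_drugs = 40L, n_proteins = 30L, noise_sd = 0.25,
                         widths = small_widths, seed = 11L)
  gen <- generate_embeddings_and_affinity(spec)
  lo <- spec$affinity_range[1L] - 3 * spec$noise_sd
  hi <- spec$affinity_range[2L] + 3 * spec$noise_sd
  inside <- mean(gen$table$affinity >= lo & gen$table$affinity <= hi)
  expect_gte(inside, 0.99)

  spec2 <- synthetic_spec(n_drugs = 40L, n_proteins = 30L, noise_sd = 0.5,
                          widths = small_widths, seed = 11L)
  gen2 <- generate_embeddings_and_affinity(spec2)
  expect_identical(gen$drug[["2D"]]$vectors, gen2$drug[["2D"]]$vectors)
  expect_identical(gen$protein[["1D"]]$vectors, gen2$protein[["1D"]]$vectors)
  expect_false(identical(gen$table$affinity, gen2$table$affinity))

  # bit-identical regeneration
  gen3 <- generate_embeddings_and_affinity(spec)
  expect_identical(gen3$table$affinity, gen$table$affinity)
})

test_that("a noiseless fully informative benchmark is learnable by the
           bilinear oracle", {
  spec <- synthetic_spec(n_drugs = 60L, n_proteins = 40L, noise_sd = 0,
                         informativeness = 1, widths = small_widths,
                         seed = 3L)
  gen <- generate_embeddings_and_affinity(spec)
  expect_gt(oracle_bilinear_ci(gen), 0.99)
})

test_that("raising a dimension's informativeness monotonically improves the
           oracle's concordance", {
  # signal is bilinear, so the partner side (protein 3D) stays informative
  # while the drug 3D informativeness is swept
  cis <- vapply(c(0.2, 0.5, 1.0), function(w) {
    inf <- setNames(c(0, 0, w, 0, 0, 1),
                    c("drug_1D", "drug_2D", "drug_3D",
                      "protein_1D", "protein_2D", "protein_3D"))
    spec <- synthetic_spec(n_drugs = 60L, n_proteins = 40L, noise_sd = 0,
                           informativeness = inf, widths = small_widths,
                           seed = 13L)
    oracle_bilinear_ci(generate_embeddings_and_affinity(spec))
  }, 0)
  expect_true(all(diff(cis) > 0))
})

test_that("write_fixture_dir emits a complete, loadable fixture", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_drugs = 6L, n_proteins = 5L,
                         widths = small_widths, seed = 2L)
  write_fixture_dir(spec, dir)
  expect_true(all(file.exists(file.path(dir,
    c("drugs.smi", "proteins.fasta", "interactions.csv", "drug_1D.tsv",
      "protein_3D.tsv", "manifest.json")))))
  emb <- load_embedding_dir(dir)
  gen <- generate_embeddings_and_affinity(spec)
  expect_equal(emb$drug[["1D"]]$vectors, gen$drug[["1D"]]$vectors,
               tolerance = 1e-12)
  tab <- read_interaction_table(file.path(dir, "interactions.csv"))
  expect_equal(nrow(tab), nrow(gen$table))
})
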