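test_that("substructure tokenization reflects atom environments", {
  eth <- smiles_to_graph("CC")
  tok0 <- tokenize_substructures(eth, radius = 0L)
  expect_length(tok0, 2L)
  expect_equal(tok0[1L], tok0[2L])       # symmetric carbons share a token

  # deterministic: same molecule, same tokens
  expect_identical(tokenize_substructures(eth, radius = 1L),
                   tokenize_substructures(smiles_to_graph("CC"), radius = 1L))

  co <- smiles_to_graph("CO")
  tok1 <- tokenize_substructures(co, radius = 1L)
  expect_length(tok1, 4L)                # 2 atoms x radii {0, 1}
  # carbon and oxygen environments differ at every radius
  expect_false(tok1[1L] == tok1[3L])
  expect_false(tok1[2L] == tok1[4L])

  # radius-1 tokens distinguish terminal from middle carbon in propane
  prop <- smiles_to_graph("CCC")
  t1 <- tokenize_substructures(prop, radius = 1L)
  expect_equal(t1[2L], t1[6L])           # the two terminal carbons
  expect_false(t1[2L] == t1[4L])         # terminal vs middle
})

test_that("embed_1d is additive over token multisets", {
  graphs <- lapply(c("CC", "CCO", "C1CC1", "CCN"), smiles_to_graph)
  corpus <- lapply(graphs, tokenize_substructures, radius = 1L)
  m <- train_skipgram(corpus, width = 12L, epochs = 2L, seed = 2L)
  e <- embed_1d(graphs[[1L]], m)
  expect_length(e, 12L)
  # ethane = two identical carbon environments; embedding is 2x one token
  tok <- tokenize_substructures(graphs[[1L]], radius = 1L)
  expect_equal(e, 2 * embed_tokens(tok[1:2], m) )
})

test_that("gin_embed matches a hand computation on a 2-node path", {
  # width-2 features, one layer, mlp_depth 1, identity-ish weights
  A <- matrix(c(0, 1, 1, 0), 2L)
  X <- matrix(c(1, 0, 0, 2), 2L, byrow = TRUE)
  E <- array(0, c(2L, 2L, 1L)); E[1, 2, 1] <- E[2, 1, 1] <- 1
  g <- molecular_graph(A, X, E)
  eps <- 0.5
  cfg <- gin_config(n_layers = 1L, hidden_width = 2L, epsilon = eps,
                    mlp_depth = 1L, output_width = 2L)
  W1 <- matrix(c(1, 0, 0, 1), 2L)
  params <- list(layers = list(list(eps = eps, W1 = W1, b1 = c(0, 0))),
                 W_out = diag(2L), b_out = c(0, 0))
  got <- gin_embed(g, cfg, params)
  # by hand: z_i = (1 + eps) x_i + x_j, relu is identity here, sum readout
  z1 <- (1 + eps) * X[1L, ] + X[2L, ]
  z2 <- (1 + eps) * X[2L, ] + X[1L, ]
  expect_equal(got, z1 + z2)
})

test_that("single isolated node with identity MLP embeds to its features", {
  A <- matrix(0, 1L, 1L)
  X <- matrix(c(3, 7), 1L)
  E <- array(0, c(1L, 1L, 1L))
  g <- molecular_graph(A, X, E)
  cfg <- gin_config(n_layers = 1L, hidden_width = 2L, epsilon = 0,
                    mlp_depth = 1L, output_width = 2L)
  params <- list(layers = list(list(eps = 0, W1 = diag(2L), b1 = c(0, 0))),
                 W_out = diag(2L), b_out = c(0, 0))
  expect_equal(gin_embed(g, cfg, params), c(3, 7))
})

test_that("gin_embed is invariant to node permutation", {
  cfg <- gin_config(n_layers = 2L, hidden_width = 16L, output_width = 24L)
  params <- gin_init_params(cfg, in_width = 5L, seed = 3L)
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(3:12, 1L)
    g <- random_test_graph(n)
    perm <- sample.int(n)
    e1 <- gin_embed(g, cfg, params)
    e2 <- gin_embed(permute_graph(g, perm), cfg, params)
    expect_equal(e1, e2, tolerance = 1e-10)
  }
  # width mismatch between params and graph is a configuration error
  bad <- random_test_graph(4L, d_attr = 7L)
  expect_error(gin_embed(bad, cfg, params), class = "fusedta_config_error")
})

test_that("embed_3d requires coordinates and is rigid-motion invariant", {
  cfg <- egnn_config(n_layers = 2L, hidden_width = 16L, output_width = 20L)
  g <- smiles_to_graph("C1CC1")
  params <- egnn_init_params(cfg, in_width = ncol(g$X), seed = 2L)
  expect_error(embed_3d(g, cfg, params), "conformer",
               class = "fusedta_featurization_error")
  g <- generate_conformer(g, seed = 1L)
  e0 <- embed_3d(g, cfg, params)
  expect_length(e0, 20L)
  set.seed(55)
  for (rep in 1:20) {
    Q <- random_rotation()
    shift <- rnorm(3L, sd = 5)
    g2 <- g
    g2$R <- g$R %*% Q + matrix(shift, g$n_atoms, 3L, byrow = TRUE)
    expect_equal(embed_3d(g2, cfg, params), e0, tolerance = 1e-6)
  }
})

test_that("3D embedding is sensitive to bond-length changes", {
  cfg <- egnn_config(n_layers = 1L, hidden_width = 8L, output_width = 8L)
  g <- generate_conformer(smiles_to_graph("C1CC1"), seed = 1L)
  params <- egnn_init_params(cfg, in_width = ncol(g$X), seed = 9L)
  relaxed <- embed_3d(g, cfg, params)
  stretched <- g
  stretched$R <- g$R * 1.7           # same topology, longer bonds
  expect_false(isTRUE(all.equal(embed_3d(stretched, cfg, params), relaxed)))
})

test_that("featurizers are deterministic given input, params and seed", {
  g <- generate_conformer(smiles_to_graph("CCO"), seed = 4L)
  gcfg <- gin_config(output_width = 16L)
  gpar <- gin_init_params(gcfg, ncol(g$X), seed = 5L)
  expect_identical(gin_embed(g, gcfg, gpar), gin_embed(g, gcfg, gpar))
  ecfg <- egnn_config(output_width = 16L)
  epar <- egnn_init_params(ecfg, ncol(g$X), seed = 5L)
  expect_identical(embed_3d(g, ecfg, epar), embed_3d(g, ecfg, epar))
  # same seed, same init
  expect_identical(gpar, gin_init_params(gcfg, ncol(g$X), seed = 5L))
})
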