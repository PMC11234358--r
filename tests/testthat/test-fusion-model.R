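test_that("l2_normalize maps to unit vectors and preserves direction", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 0, 0)
  expect_equal(l2_normalize(u), u)
  expect_warning(z <- l2_normalize(c(0, 0)),
                 class = "fusedta_zero_vector_warning")
  expect_equal(z, c(0, 0))
  set.seed(19)
  m <- matrix(rnorm(5000), 500L, 10L)
  nm <- l2_normalize(m)
  expect_equal(rowSums(nm^2), rep(1, 500L), tolerance = 1e-12)
  expect_equal(nm[1L, ] * sqrt(sum(m[1L, ]^2)), m[1L, ])  # direction kept
})

test_that("model shapes follow the architecture", {
  widths <- list(drug_1D = 100, drug_2D = 300, drug_3D = 512,
                 protein_1D = 100, protein_2D = 768, protein_3D = 1280)
  cfg <- fusion_config(seed = 1L)
  m <- build_fusion_model(cfg, widths)
  # six 1024-unit blocks feed a 6144-wide head input
  expect_equal(nrow(m$params[["head.W1"]]), 6L * 1024L)
  expect_equal(dim(m$params[["block.drug_3D.W"]]), c(512L, 1024L))

  cfg2 <- fusion_config(drug_dims = "1D", protein_dims = "1D", seed = 1L)
  m2 <- build_fusion_model(cfg2, widths[c("drug_1D", "protein_1D")])
  expect_equal(nrow(m2$params[["head.W1"]]), 2048L)

  # closed-form trainable parameter count
  bw <- 1024L; hw <- c(1024L, 1024L, 512L)
  w <- unlist(widths)
  expected <- sum(w * bw + bw) +                       # six blocks
    6L * bw * hw[1L] + hw[1L] +                        # FC1
    hw[1L] * hw[2L] + hw[2L] +                         # FC2
    hw[2L] * hw[3L] + hw[3L] +                         # FC3
    hw[3L] + 1L                                        # linear output
  expect_equal(n_parameters(m), expected)

  expect_error(build_fusion_model(cfg, widths[-3L]), "drug_3D",
               class = "fusedta_config_error")
})

test_that("predict is deterministic, affine in the output layer, and
           order-insensitive in the input list", {
  widths <- list(drug_1D = 8, protein_1D = 6)
  cfg <- fusion_config(drug_dims = "1D", protein_dims = "1D",
                       block_dense_width = 4L, head_widths = c(5L, 4L, 3L),
                       seed = 2L)
  m <- build_fusion_model(cfg, widths)
  set.seed(3)
  x <- list(drug_1D = matrix(rnorm(40), 5L, 8L),
            protein_1D = matrix(rnorm(30), 5L, 6L))
  p1 <- predict(m, x)
  expect_length(p1, 5L)
  expect_identical(p1, predict(m, x))                 # dropout off
  expect_identical(p1, predict(m, rev(x)))            # storage order free

  # zeroed weights leave only the output bias
  m0 <- m
  m0$params <- lapply(m0$params, function(p) p * 0)
  m0$params[["head.bo"]] <- 2.5
  expect_equal(predict(m0, x), rep(2.5, 5L))

  bad <- x
  bad$protein_1D <- cbind(bad$protein_1D, 0)
  expect_error(predict(m, bad), "protein_1D",
               class = "fusedta_shape_error")
})

test_that("assemble_inputs normalizes rows and names missing ids", {
  t <- toy_table(3L, 2L)
  demb <- list("1D" = toy_embeddings(unique(t$drug_id), 7L, "drug", "1D"))
  pemb <- list("1D" = toy_embeddings(unique(t$protein_id), 5L, "protein",
                                     "1D", seed = 2L))
  cfg <- fusion_config(drug_dims = "1D", protein_dims = "1D")
  x <- assemble_inputs(t, demb, pemb, cfg)
  expect_equal(unname(rowSums(x$drug_1D^2)), rep(1, nrow(t)),
               tolerance = 1e-12)

  t2 <- interaction_table(c("d1", "dX"), c("p1", "p1"), c(5, 6))
  expect_error(assemble_inputs(t2, demb, pemb, cfg), "dX",
               class = "fusedta_lookup_error")
})

test_that("training reduces MSE on a learnable target and is reproducible", {
  set.seed(21)
  n <- 300L
  xd <- matrix(rnorm(n * 6L), n, 6L)
  xp <- matrix(rnorm(n * 4L), n, 4L)
  y <- xd %*% c(1, -1, 0.5, 0, 0, 0.2) + xp %*% c(0.7, -0.3, 0, 1)
  y <- as.numeric(y)
  x <- list(drug_1D = xd, protein_1D = xp)
  cfg <- fusion_config(drug_dims = "1D", protein_dims = "1D",
                       block_dense_width = 16L, head_widths = c(16L, 8L, 8L),
                       dropout = 0, learning_rate = 3e-3, batch_size = 32L,
                       max_epochs = 30L, seed = 5L)
  m <- build_fusion_model(cfg, list(drug_1D = 6, protein_1D = 4))
  fit <- train_fusion_model(m, x, y)
  expect_lt(tail(fit$history$train_mse, 1L), fit$history$train_mse[1L])

  fit2 <- train_fusion_model(m, x, y)
  expect_identical(fit$params, fit2$params)           # same seed, same fit
})

test_that("early stopping halts on a validation plateau and restores the
           best epoch", {
  set.seed(33)
  n <- 120L
  x <- list(drug_1D = matrix(rnorm(n * 4L), n, 4L),
            protein_1D = matrix(rnorm(n * 3L), n, 3L))
  y <- rnorm(n)                      # pure noise: validation cannot improve
  xv <- list(drug_1D = matrix(rnorm(40L * 4L), 40L, 4L),
             protein_1D = matrix(rnorm(40L * 3L), 40L, 3L))
  yv <- rnorm(40L)
  cfg <- fusion_config(drug_dims = "1D", protein_dims = "1D",
                       block_dense_width = 8L, head_widths = c(8L, 8L, 4L),
                       dropout = 0, learning_rate = 1e-2, batch_size = 32L,
                       max_epochs = 400L, early_stop_patience = 5L,
                       seed = 9L)
  m <- build_fusion_model(cfg, list(drug_1D = 4, protein_1D = 3))
  fit <- train_fusion_model(m, x, y, xv, yv)
  expect_lt(nrow(fit$history), 400L)
  expect_equal(min(fit$history$val_mse), fit$history$val_mse[fit$best_epoch])
})
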