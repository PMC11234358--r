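# The fusion network: per-dimension dense blocks, concatenation, and a
# three-layer prediction head trained with Adam on mean squared error.

#' L2-normalize a vector (or the rows of a matrix)
#'
#' Scales every non-zero vector to unit Euclidean norm, preserving direction.
#' Zero vectors are returned unchanged with a warning rather than an error:
#' an entity whose tokens are all unknown legitimately featurizes to zero.
#'
#' @param v Numeric vector, or a matrix normalized row-wise.
#' @return Object of the same shape with unit-norm (or zero) rows.
#' @export
l2_normalize <- function(v) {
  if (is.matrix(v)) {
    nrm <- sqrt(rowSums(v^2))
    zero <- nrm == 0
    if (any(zero))
      fdta_warn(sprintf("%d zero vector(s) left unnormalized", sum(zero)),
                "fusedta_zero_vector_warning")
    nrm[zero] <- 1
    return(v / nrm)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    fdta_warn("zero vector left unnormalized", "fusedta_zero_vector_warning")
    return(v)
  }
  v / nrm
}

#' Fusion model configuration
#'
#' Defaults follow the reference training protocol: 1024-unit fusion blocks,
#' a 1024/1024/512 head, dropout 0.3 after each head layer, Adam at learning
#' rate 1e-4, batch size 64, at most 500 epochs with early stopping on
#' validation MSE (patience 20, best weights restored).
#'
#' @param drug_dims,protein_dims Non-empty subsets of `c("1D","2D","3D")`.
#' @param block_dense_width Units in each per-dimension fusion block.
#' @param head_widths Integer triple: units of FC1, FC2, FC3.
#' @param dropout Dropout rate in `[0, 1)` applied after each head layer.
#' @param block_dropout Also apply dropout after each fusion block
#'   (default `FALSE`; the head-only placement is the reference reading).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param use_blocks If `FALSE`, fusion blocks are bypassed and the raw
#'   (normalized) embeddings are concatenated straight into the head — the
#'   "simple concatenation" variant used by the pairwise ablation.
#' @param normalize L2-normalize embeddings on assembly (default `TRUE`).
#' @param seed Integer seed governing initialization, batching and dropout.
#' @export
fusion_config <- function(drug_dims = c("1D", "2D", "3D"),
                          protein_dims = c("1D", "2D", "3D"),
                          block_dense_width = 1024L,
                          head_widths = c(1024L, 1024L, 512L),
                          dropout = 0.3, block_dropout = FALSE,
                          learning_rate = 1e-4, batch_size = 64L,
                          max_epochs = 500L, early_stop_patience = 20L,
                          use_blocks = TRUE, normalize = TRUE, seed = 1L) {
  drug_dims <- match.arg(drug_dims, DIM_TAGS, several.ok = TRUE)
  protein_dims <- match.arg(protein_dims, DIM_TAGS, several.ok = TRUE)
  if (!length(drug_dims) || !length(protein_dims))
    fdta_stop("select at least one drug and one protein dimension",
              "fusedta_config_error")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    fdta_stop("dropout must be in [0, 1)", "fusedta_config_error")
  if (length(head_widths) != 3L || !all(head_widths >= 1))
    fdta_stop("head_widths must be three positive integers",
              "fusedta_config_error")
  structure(list(drug_dims = drug_dims, protein_dims = protein_dims,
                 block_dense_width = as.integer(block_dense_width),
                 head_widths = as.integer(head_widths),
                 dropout = dropout, block_dropout = isTRUE(block_dropout),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 use_blocks = isTRUE(use_blocks),
                 normalize = isTRUE(normalize),
                 seed = as.integer(seed)),
            class = "fusion_config")
}

# canonical input order: drug 1D,2D,3D then protein 1D,2D,3D
dim_keys <- function(config) {
  c(paste0("drug_", config$drug_dims), paste0("protein_", config$protein_dims))
}

#' Build an untrained fusion model
#'
#' One independent dense(`block_dense_width`)+ReLU block per selected
#' dimension; block outputs are concatenated (drug dims first, then protein
#' dims) and fed to the FC1 -> dropout -> FC2 -> dropout -> FC3 -> dropout ->
#' linear(1) head. Weights use a fan-in uniform scheme under the config seed.
#'
#' @param config A [fusion_config()].
#' @param widths Named list/vector of input widths, one per selected
#'   dimension, keys like `drug_1D`, `protein_3D`.
#' @return An object of class `fusion_model`.
#' @export
build_fusion_model <- function(config, widths) {
  stopifnot(inherits(config, "fusion_config"))
  keys <- dim_keys(config)
  missing <- setdiff(keys, names(widths))
  if (length(missing))
    fdta_stop(sprintf("no input width given for dimension '%s'", missing[1L]),
              "fusedta_config_error")
  widths <- vapply(widths[keys], as.integer, 0L)
  params <- list()
  with_seed(derive_seed(config$seed, "init"), {
    if (config$use_blocks) {
      for (k in keys) {
        params[[paste0("block.", k, ".W")]] <-
          init_matrix(widths[[k]], config$block_dense_width)
        params[[paste0("block.", k, ".b")]] <-
          numeric(config$block_dense_width)
      }
      h0 <- length(keys) * config$block_dense_width
    } else {
      h0 <- sum(widths)
    }
    hw <- config$head_widths
    params[["head.W1"]] <- init_matrix(h0, hw[1L])
    params[["head.b1"]] <- numeric(hw[1L])
    params[["head.W2"]] <- init_matrix(hw[1L], hw[2L])
    params[["head.b2"]] <- numeric(hw[2L])
    params[["head.W3"]] <- init_matrix(hw[2L], hw[3L])
    params[["head.b3"]] <- numeric(hw[3L])
    params[["head.Wo"]] <- init_matrix(hw[3L], 1L)
    params[["head.bo"]] <- 0
  })
  structure(list(config = config, widths = widths, params = params,
                 history = NULL, best_epoch = NA_integer_),
            class = "fusion_model")
}

#' Count trainable parameters of a fusion model
#' @param model A [build_fusion_model()] model.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  sum(vapply(model$params, length, 0L))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("Fusion model: dims [%s], %s%d-unit blocks, head %s, %d parameters\n",
              paste(dim_keys(x$config), collapse = ", "),
              if (x$config$use_blocks) "" else "no blocks (simple concatenation), ",
              x$config$block_dense_width,
              paste(x$config$head_widths, collapse = "/"),
              n_parameters(x)))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (best %s)\n", nrow(x$history),
                x$best_epoch))
  invisible(x)
}

#' Assemble per-dimension input matrices for a table of pairs
#'
#' Looks up (and by default L2-normalizes) the embedding of every drug and
#' protein in the table, per selected dimension, returning matrices aligned
#' with the table rows. A missing id raises a lookup error naming the id and
#' dimension.
#'
#' @param table An [interaction_table()] (or data.frame with `drug_id`,
#'   `protein_id`).
#' @param drug_embeddings,protein_embeddings Named lists of
#'   [embedding_set()]s keyed by dim tag (`"1D"`, `"2D"`, `"3D"`).
#' @param config A [fusion_config()] selecting the dimensions.
#' @return Named list of numeric matrices keyed as `drug_1D`, ...
#' @export
assemble_inputs <- function(table, drug_embeddings, protein_embeddings,
                            config) {
  out <- list()
  for (d in config$drug_dims) {
    set <- drug_embeddings[[d]]
    if (is.null(set))
      fdta_stop(sprintf("no drug embedding set for dimension %s", d),
                "fusedta_config_error")
    m <- embedding_vectors(set, table$drug_id)
    out[[paste0("drug_", d)]] <- if (config$normalize)
      suppressWarnings(l2_normalize(m)) else m
  }
  for (d in config$protein_dims) {
    set <- protein_embeddings[[d]]
    if (is.null(set))
      fdta_stop(sprintf("no protein embedding set for dimension %s", d),
                "fusedta_config_error")
    m <- embedding_vectors(set, table$protein_id)
    out[[paste0("protein_", d)]] <- if (config$normalize)
      suppressWarnings(l2_normalize(m)) else m
  }
  out
}

check_input_widths <- function(model, inputs) {
  keys <- dim_keys(model$config)
  for (k in keys) {
    if (is.null(inputs[[k]]))
      fdta_stop(sprintf("missing input matrix for dimension '%s'", k),
                "fusedta_shape_error")
    if (ncol(inputs[[k]]) != model$widths[[k]])
      fdta_stop(sprintf("input width %d for dimension '%s' does not match model width %d",
                        ncol(inputs[[k]]), k, model$widths[[k]]),
                "fusedta_shape_error")
  }
  inputs[keys]
}

# forward pass; when train=TRUE, dropout masks are drawn from the current RNG
# and the full activation cache is returned for backprop
fusion_forward <- function(model, inputs, train = FALSE) {
  cfg <- model$config
  p <- model$params
  keys <- dim_keys(cfg)
  drop_rate <- if (train) cfg$dropout else 0
  mk_mask <- function(nr, nc) {
    if (drop_rate == 0) NULL
    else matrix((stats::runif(nr * nc) >= drop_rate) / (1 - drop_rate), nr, nc)
  }
  nb <- nrow(inputs[[1L]])
  cache <- list(inputs = inputs)
  if (cfg$use_blocks) {
    Z <- vector("list", length(keys)); names(Z) <- keys
    bmask <- vector("list", length(keys)); names(bmask) <- keys
    for (k in keys) {
      Zk <- relu(sweep(inputs[[k]] %*% p[[paste0("block.", k, ".W")]], 2L,
                       p[[paste0("block.", k, ".b")]], `+`))
      if (cfg$block_dropout && drop_rate > 0) {
        bmask[[k]] <- mk_mask(nb, ncol(Zk))
        Zk <- Zk * bmask[[k]]
      }
      Z[[k]] <- Zk
    }
    H0 <- do.call(cbind, Z)
    cache$Z <- Z; cache$bmask <- bmask
  } else {
    H0 <- do.call(cbind, inputs[keys])
  }
  A1 <- relu(sweep(H0 %*% p$head.W1, 2L, p$head.b1, `+`))
  M1 <- mk_mask(nb, ncol(A1)); D1 <- if (is.null(M1)) A1 else A1 * M1
  A2 <- relu(sweep(D1 %*% p$head.W2, 2L, p$head.b2, `+`))
  M2 <- mk_mask(nb, ncol(A2)); D2 <- if (is.null(M2)) A2 else A2 * M2
  A3 <- relu(sweep(D2 %*% p$head.W3, 2L, p$head.b3, `+`))
  M3 <- mk_mask(nb, ncol(A3)); D3 <- if (is.null(M3)) A3 else A3 * M3
  yhat <- drop(D3 %*% p$head.Wo) + p$head.bo
  c(cache, list(H0 = H0, A1 = A1, M1 = M1, D1 = D1, A2 = A2, M2 = M2,
                D2 = D2, A3 = A3, M3 = M3, D3 = D3, yhat = yhat))
}

fusion_backward <- function(model, cache, y) {
  cfg <- model$config
  p <- model$params
  keys <- dim_keys(cfg)
  nb <- length(y)
  g <- list()
  g_yhat <- matrix(2 * (cache$yhat - y) / nb, ncol = 1L)
  g[["head.Wo"]] <- crossprod(cache$D3, g_yhat)
  g[["head.bo"]] <- sum(g_yhat)
  gD3 <- g_yhat %*% t(p$head.Wo)
  gA3 <- if (is.null(cache$M3)) gD3 else gD3 * cache$M3
  gS3 <- gA3 * (cache$A3 > 0)
  g[["head.W3"]] <- crossprod(cache$D2, gS3)
  g[["head.b3"]] <- colSums(gS3)
  gD2 <- gS3 %*% t(p$head.W3)
  gA2 <- if (is.null(cache$M2)) gD2 else gD2 * cache$M2
  gS2 <- gA2 * (cache$A2 > 0)
  g[["head.W2"]] <- crossprod(cache$D1, gS2)
  g[["head.b2"]] <- colSums(gS2)
  gD1 <- gS2 %*% t(p$head.W2)
  gA1 <- if (is.null(cache$M1)) gD1 else gD1 * cache$M1
  gS1 <- gA1 * (cache$A1 > 0)
  g[["head.W1"]] <- crossprod(cache$H0, gS1)
  g[["head.b1"]] <- colSums(gS1)
  if (cfg$use_blocks) {
    gH0 <- gS1 %*% t(p$head.W1)
    off <- 0L
    for (k in keys) {
      w <- ncol(cache$Z[[k]])
      gZ <- gH0[, (off + 1L):(off + w), drop = FALSE]
      off <- off + w
      if (!is.null(cache$bmask[[k]])) gZ <- gZ * cache$bmask[[k]]
      # Z stores post-dropout values; recover the pre-dropout sign pattern
      gS <- gZ * (cache$Z[[k]] > 0)
      g[[paste0("block.", k, ".W")]] <- crossprod(cache$inputs[[k]], gS)
      g[[paste0("block.", k, ".b")]] <- colSums(gS)
    }
  }
  g
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Predict affinities for assembled inputs
#'
#' Inference mode: dropout disabled, output deterministic.
#'
#' @param object A trained (or freshly built) `fusion_model`.
#' @param inputs Named list of per-dimension input matrices as produced by
#'   [assemble_inputs()].
#' @param ... Unused.
#' @return Numeric vector of predicted affinities, one per row.
#' @export
predict.fusion_model <- function(object, inputs, ...) {
  inputs <- check_input_widths(object, inputs)
  fusion_forward(object, inputs, train = FALSE)$yhat
}

#' Train a fusion model with Adam on mean squared error
#'
#' Minibatch gradient descent (Adam) on the MSE between predicted and true
#' affinities. Every training row appears in exactly one batch per epoch.
#' When validation data is supplied, training stops once validation MSE has
#' not improved for `early_stop_patience` epochs and the best weights are
#' restored. Fully reproducible given the config seed.
#'
#' @param model A [build_fusion_model()] model.
#' @param inputs Named list of per-dimension training matrices.
#' @param y Numeric vector of training affinities.
#' @param val_inputs,val_y Optional validation data for early stopping.
#' @return The trained model, with `$history` (per-epoch train/validation
#'   MSE) and `$best_epoch`.
#' @export
train_fusion_model <- function(model, inputs, y,
                               val_inputs = NULL, val_y = NULL) {
  stopifnot(inherits(model, "fusion_model"))
  cfg <- model$config
  inputs <- check_input_widths(model, inputs)
  if (nrow(inputs[[1L]]) != length(y))
    fdta_stop("number of rows in inputs does not match length(y)",
              "fusedta_shape_error")
  has_val <- !is.null(val_inputs) && !is.null(val_y)
  if (has_val) val_inputs <- check_input_widths(model, val_inputs)
  n <- length(y)
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  best <- list(mse = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist_train <- hist_val <- numeric(0)
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        rows <- ord[s:min(n, s + cfg$batch_size - 1L)]
        xb <- lapply(inputs, function(m) m[rows, , drop = FALSE])
        model$params <- params
        cache <- fusion_forward(model, xb, train = cfg$dropout > 0)
        grads <- fusion_backward(model, cache, y[rows])
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      model$params <- params
      hist_train[epoch] <- mse(y, fusion_forward(model, inputs)$yhat)
      if (has_val) {
        vm <- mse(val_y, fusion_forward(model, val_inputs)$yhat)
        hist_val[epoch] <- vm
        if (vm < best$mse - 1e-12) {
          best <- list(mse = vm, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$early_stop_patience) break
        }
      }
    }
  })
  if (has_val) {
    model$params <- best$params
    model$best_epoch <- best$epoch
  } else {
    model$params <- params
    model$best_epoch <- length(hist_train)
  }
  model$history <- data.frame(
    epoch = seq_along(hist_train),
    train_mse = hist_train,
    val_mse = if (has_val) hist_val else NA_real_)
  model
}
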