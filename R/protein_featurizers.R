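# Protein featurizers: k-mer tokens (1D), small multi-head self-attention
# encoder (2D); 3D embeddings enter through the precomputed-file adapter.

#' Tokenize a protein sequence into overlapping k-mers
#'
#' @param sequence Amino-acid sequence (single string).
#' @param k k-mer length (default 3, the conventional protein word size).
#' @return Character vector of `nchar(sequence) - k + 1` overlapping k-mers.
#' @export
protein_tokenize <- function(sequence, k = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < k)
    fdta_stop(sprintf("sequence length %d is shorter than k = %d", n, k),
              "fusedta_featurization_error")
  substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' 1D protein embedding: aggregated k-mer vectors
#'
#' @param sequence Amino-acid sequence.
#' @param model A [train_skipgram()] model trained on a k-mer corpus.
#' @param k k-mer length used at training time.
#' @param aggregate `"sum"` (default) or `"mean"`. Under sum aggregation the
#'   embedding depends only on the k-mer multiset, not their order.
#' @return Numeric vector of length `model$width` (100 by default).
#' @export
protvec_embed <- function(sequence, model, k = 3L,
                          aggregate = c("sum", "mean")) {
  embed_tokens(protein_tokenize(sequence, k), model,
               aggregate = match.arg(aggregate))
}

#' Attention encoder configuration
#'
#' A deliberately small transformer-style encoder: residues are embedded,
#' optionally given sinusoidal positional signals, passed through stacked
#' multi-head scaled dot-product attention layers (no residual connections or
#' feed-forward sublayers), pooled, and projected to `output_width`. It
#' provides a self-contained sequence encoder for the 2D protein slot; it is
#' not a reproduction of any large pretrained language model.
#'
#' @param n_heads Number of attention heads; must divide `model_width`.
#' @param model_width Latent width per position.
#' @param n_layers Number of attention layers.
#' @param output_width Pooled output width (default 768).
#' @param pooling `"mean"` over positions (default) or `"first"` token.
#' @param max_length Sequences longer than this are tail-truncated with a
#'   warning (default 2600, above the longest benchmark sequence).
#' @param positional Add sinusoidal position encodings (default `TRUE`).
#' @export
attention_config <- function(n_heads = 4L, model_width = 64L, n_layers = 2L,
                             output_width = 768L,
                             pooling = c("mean", "first"),
                             max_length = 2600L, positional = TRUE) {
  pooling <- match.arg(pooling)
  if (model_width %% n_heads != 0L)
    fdta_stop("model_width must be divisible by n_heads",
              "fusedta_config_error")
  if (!is_count(output_width))
    fdta_stop("output_width must be > 0", "fusedta_config_error")
  structure(list(n_heads = as.integer(n_heads),
                 model_width = as.integer(model_width),
                 n_layers = as.integer(n_layers),
                 key_width = as.integer(model_width / n_heads),
                 output_width = as.integer(output_width),
                 pooling = pooling, max_length = as.integer(max_length),
                 positional = isTRUE(positional)),
            class = "attention_config")
}

#' Initialize attention encoder parameters
#' @param config An [attention_config()].
#' @param seed Integer seed.
#' @return Parameter list consumed by [attention_encode()].
#' @export
attention_init_params <- function(config, seed = 1L) {
  stopifnot(inherits(config, "attention_config"))
  mw <- config$model_width
  with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) list(
      W_q = init_matrix(mw, mw), W_k = init_matrix(mw, mw),
      W_v = init_matrix(mw, mw), W_o = init_matrix(mw, mw)))
    list(embedding = init_matrix(length(AA_ALPHABET), mw),
         layers = layers,
         W_out = init_matrix(mw, config$output_width),
         b_out = numeric(config$output_width))
  })
}

sinusoidal_positions <- function(n, width) {
  pos <- seq_len(n) - 1L
  dim_i <- seq_len(width)
  angle <- outer(pos, 10000^(-2 * (ceiling(dim_i / 2) - 1) / width))
  even <- dim_i %% 2L == 0L
  angle[, !even] <- sin(angle[, !even, drop = FALSE])
  angle[, even] <- cos(angle[, even, drop = FALSE])
  angle
}

#' 2D protein embedding via multi-head self-attention
#'
#' Per layer and head, attention weights are `softmax(Q K' / sqrt(d_k))`
#' (each row sums to one); head outputs are concatenated and mixed by `W_o`.
#' The final latents are pooled and linearly projected to the configured
#' output width.
#'
#' @param sequence Amino-acid sequence.
#' @param config An [attention_config()].
#' @param params Parameters from [attention_init_params()].
#' @param return_attention If `TRUE`, also return the per-layer, per-head
#'   attention matrices.
#' @return Numeric vector of length `config$output_width`, or a list
#'   `list(embedding=, attention=)` when `return_attention = TRUE`.
#' @export
attention_encode <- function(sequence, config, params,
                             return_attention = FALSE) {
  stopifnot(inherits(config, "attention_config"))
  if (nchar(sequence) > config$max_length) {
    fdta_warn(sprintf("sequence of length %d truncated to max_length %d",
                      nchar(sequence), config$max_length),
              "fusedta_truncation_warning")
    sequence <- substr(sequence, 1L, config$max_length)
  }
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], AA_ALPHABET)
  idx[is.na(idx)] <- match("X", AA_ALPHABET)
  X <- params$embedding[idx, , drop = FALSE]
  if (config$positional)
    X <- X + sinusoidal_positions(nrow(X), config$model_width)
  heads <- config$n_heads
  dk <- config$key_width
  attn_out <- list()
  for (li in seq_along(params$layers)) {
    layer <- params$layers[[li]]
    Q <- X %*% layer$W_q; K <- X %*% layer$W_k; V <- X %*% layer$W_v
    H <- matrix(0, nrow(X), config$model_width)
    attn_layer <- list()
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                   K[, cols, drop = FALSE]) / sqrt(dk))
      H[, cols] <- A %*% V[, cols, drop = FALSE]
      if (return_attention) attn_layer[[h]] <- A
    }
    X <- H %*% layer$W_o
    if (return_attention) attn_out[[li]] <- attn_layer
  }
  pooled <- if (config$pooling == "mean") colMeans(X) else X[1L, ]
  emb <- drop(pooled %*% params$W_out) + params$b_out
  if (return_attention) list(embedding = emb, attention = attn_out) else emb
}
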