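# Skip-gram with negative sampling: the shared 1D embedder for drug
# substructure tokens (Mol2Vec-style) and protein k-mers (ProtVec-style).

#' Train a skip-gram token embedding model
#'
#' Learns one vector per token by predicting context tokens from a center
#' token (skip-gram with negative sampling, unigram^0.75 noise distribution).
#' The context window is fixed (not subsampled) and sentences are visited in
#' corpus order, so training is fully reproducible from the seed.
#'
#' @param corpus List of token sequences (character vectors).
#' @param width Embedding width (default 100, the conventional 1D width).
#' @param window Context half-window size.
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per (center, context) pair.
#' @param learning_rate Initial SGD learning rate; decays linearly to 1e-4 of
#'   its starting value over training.
#' @param min_count Discard tokens seen fewer times than this.
#' @param seed Integer seed.
#' @return An object of class `skipgram_model` with elements `vocabulary`
#'   (named index vector), `vectors` (|V| x width matrix, rownames = tokens),
#'   `counts`, `window`, `width`, `seed`.
#' @export
train_skipgram <- function(corpus, width = 100L, window = 5L, epochs = 5L,
                           negative = 5L, learning_rate = 0.025,
                           min_count = 1L, seed = 1L) {
  if (!length(corpus) || !sum(lengths(corpus)))
    fdta_stop("corpus is empty", "fusedta_config_error")
  if (!is_count(width)) fdta_stop("width must be a positive integer",
                                  "fusedta_config_error")
  tokens <- unlist(corpus, use.names = FALSE)
  counts <- table(factor(tokens, levels = unique(tokens)))
  counts <- counts[counts >= min_count]
  if (!length(counts))
    fdta_stop("no token reaches min_count", "fusedta_config_error")
  vocab <- stats::setNames(seq_along(counts), names(counts))
  sentences <- lapply(corpus, function(s) unname(vocab[s[s %in% names(vocab)]]))
  sentences <- sentences[lengths(sentences) > 0L]
  neg_prob <- as.numeric(counts)^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  V <- length(vocab)
  with_seed(seed, {
    W <- matrix(stats::runif(V * width, -0.5, 0.5) / width, V, width)
    C <- matrix(0, V, width)
    total <- max(1L, length(sentences) * epochs)
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (sent in sentences) {
        lr <- learning_rate * max(1e-4, 1 - step / total)
        step <- step + 1L
        n <- length(sent)
        for (t in seq_len(n)) {
          lo <- max(1L, t - window); hi <- min(n, t + window)
          ctxs <- sent[setdiff(lo:hi, t)]
          if (!length(ctxs)) next
          center <- sent[t]
          vc <- W[center, ]
          for (ctx in ctxs) {
            targets <- c(ctx, sample.int(V, negative, replace = TRUE,
                                         prob = neg_prob))
            labels <- c(1, numeric(negative))
            U <- C[targets, , drop = FALSE]
            s <- 1 / (1 + exp(-drop(U %*% vc)))
            g <- lr * (labels - s)
            grad_vc <- drop(crossprod(U, g))
            for (k in seq_along(targets))
              C[targets[k], ] <- C[targets[k], ] + g[k] * vc
            vc <- vc + grad_vc
          }
          W[center, ] <- vc
        }
      }
    }
    rownames(W) <- names(vocab)
    structure(list(vocabulary = vocab, vectors = W,
                   counts = as.integer(counts), window = window,
                   width = as.integer(width), seed = as.integer(seed)),
              class = "skipgram_model")
  })
}

#' @export
print.skipgram_model <- function(x, ...) {
  cat(sprintf("Skip-gram model: %d tokens, width %d, window %d\n",
              length(x$vocabulary), x$width, x$window))
  invisible(x)
}

#' Aggregate token vectors into a single entity embedding
#'
#' Sums (default) or averages the model vectors of the given tokens. Unknown
#' tokens contribute nothing; if no token is known the zero vector is
#' returned with a warning, not an error.
#'
#' @param tokens Character vector of tokens.
#' @param model A [train_skipgram()] model.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return Numeric vector of length `model$width`.
#' @export
embed_tokens <- function(tokens, model, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(model, "skipgram_model"))
  known <- tokens[tokens %in% rownames(model$vectors)]
  if (!length(known)) {
    fdta_warn("no known tokens; returning the zero vector",
              "fusedta_unknown_tokens_warning")
    return(numeric(model$width))
  }
  m <- model$vectors[known, , drop = FALSE]
  if (aggregate == "sum") colSums(m) else colMeans(m)
}

#' Cosine similarity between two vectors
#' @param a,b Numeric vectors of equal length.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
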