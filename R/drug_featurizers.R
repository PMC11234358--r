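# Drug featurizers: substructure tokens (1D), GIN graph embedding (2D),
# distance-featured 3D embedding.

#' Tokenize a molecule into circular substructure identifiers
#'
#' Emits one token per atom per radius 0..`radius`, in parser atom order.
#' Tokens are canonical strings built by iterated Weisfeiler-Lehman style
#' relabeling: radius 0 encodes element and degree, radius r appends the
#' sorted multiset of (bond order, neighbor label at r-1). Two atoms share a
#' token exactly when their circular environments up to that radius match.
#'
#' @param graph A [molecular_graph()].
#' @param radius Maximum environment radius (default 1).
#' @return Character vector of tokens, atom-major then radius-major.
#' @export
tokenize_substructures <- function(graph, radius = 1L) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- graph$n_atoms
  elements <- graph$atoms %||%
    ELEMENT_VOCAB[apply(graph$X[, seq_along(ELEMENT_VOCAB), drop = FALSE],
                        1L, which.max)]
  degrees <- rowSums(graph$A)
  labels <- paste0(elements, "#", degrees)
  per_radius <- list(labels)
  bond_ord <- function(i, j) which(graph$E[i, j, ] != 0)[1L]
  for (r in seq_len(radius)) {
    new <- character(n)
    for (i in seq_len(n)) {
      nb <- which(graph$A[i, ] == 1)
      if (length(nb)) {
        parts <- sort(vapply(nb, function(j)
          paste0(bond_ord(i, j), "-", labels[j]), ""))
        new[i] <- paste0(labels[i], "(", paste(parts, collapse = ","), ")")
      } else {
        new[i] <- paste0(labels[i], "()")
      }
    }
    labels <- new
    per_radius[[r + 1L]] <- labels
  }
  unlist(lapply(seq_len(n), function(i)
    vapply(per_radius, `[`, "", i)), use.names = FALSE)
}

#' 1D drug embedding: aggregated substructure token vectors
#'
#' Looks up each substructure token of the molecule in a trained skip-gram
#' model and aggregates (sum by default). Unknown tokens contribute zero; a
#' molecule with no known tokens embeds to the zero vector with a warning.
#'
#' @param graph A [molecular_graph()].
#' @param model A [train_skipgram()] model trained on substructure tokens.
#' @param radius Tokenization radius (must match the training corpus).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return Numeric vector of length `model$width`.
#' @export
embed_1d <- function(graph, model, radius = 1L, aggregate = c("sum", "mean")) {
  embed_tokens(tokenize_substructures(graph, radius), model,
               aggregate = match.arg(aggregate))
}

#' GIN configuration
#'
#' @param n_layers Number of message-passing layers (>= 1).
#' @param hidden_width Node state width.
#' @param epsilon Initial value of the per-layer self-loop weight.
#' @param mlp_depth Per-layer MLP depth: 1 (single linear+ReLU) or 2.
#' @param readout `"sum"` (default, permutation invariant and
#'   size-sensitive) or `"mean"`.
#' @param output_width Final graph embedding width (default 300).
#' @export
gin_config <- function(n_layers = 3L, hidden_width = 64L, epsilon = 0,
                       mlp_depth = 2L, readout = c("sum", "mean"),
                       output_width = 300L) {
  readout <- match.arg(readout)
  if (!is_count(n_layers)) fdta_stop("n_layers must be >= 1",
                                     "fusedta_config_error")
  if (!is_count(output_width)) fdta_stop("output_width must be > 0",
                                         "fusedta_config_error")
  if (!mlp_depth %in% 1:2) fdta_stop("mlp_depth must be 1 or 2",
                                     "fusedta_config_error")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_width = as.integer(hidden_width),
                 epsilon = epsilon, mlp_depth = as.integer(mlp_depth),
                 readout = readout, output_width = as.integer(output_width)),
            class = "gin_config")
}

#' Initialize (random frozen) GIN parameters
#'
#' In place of large-scale unsupervised pretraining, parameters are drawn
#' once from a fan-in uniform scheme under a fixed seed and frozen; random
#' message-passing features of this kind still separate non-isomorphic
#' graphs and are fully reproducible.
#'
#' @param config A [gin_config()].
#' @param in_width Atom attribute width (`ncol(X)` of the graphs).
#' @param seed Integer seed.
#' @return Parameter list consumed by [gin_embed()].
#' @export
gin_init_params <- function(config, in_width, seed = 1L) {
  stopifnot(inherits(config, "gin_config"))
  with_seed(seed, {
    layers <- vector("list", config$n_layers)
    w_in <- in_width
    for (l in seq_len(config$n_layers)) {
      layer <- list(eps = config$epsilon,
                    W1 = init_matrix(w_in, config$hidden_width),
                    b1 = numeric(config$hidden_width))
      if (config$mlp_depth == 2L) {
        layer$W2 <- init_matrix(config$hidden_width, config$hidden_width)
        layer$b2 <- numeric(config$hidden_width)
      }
      layers[[l]] <- layer
      w_in <- config$hidden_width
    }
    list(layers = layers,
         W_out = init_matrix(config$hidden_width, config$output_width),
         b_out = numeric(config$output_width))
  })
}

#' 2D drug embedding via graph isomorphism network message passing
#'
#' Each layer updates node states as
#' `h_i <- MLP((1 + eps) * h_i + sum over neighbors j of h_j)`; after the
#' last layer node states are aggregated (sum/mean readout) and passed
#' through a final linear map to `output_width`. Sum aggregation makes the
#' embedding exactly invariant to node relabeling.
#'
#' @param graph A [molecular_graph()].
#' @param config A [gin_config()].
#' @param params Parameters from [gin_init_params()] (or trained elsewhere).
#' @return Numeric vector of length `config$output_width`.
#' @export
gin_embed <- function(graph, config, params) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(config, "gin_config"))
  h <- graph$X
  if (ncol(h) != nrow(params$layers[[1L]]$W1))
    fdta_stop(sprintf("atom attribute width %d does not match parameters (%d)",
                      ncol(h), nrow(params$layers[[1L]]$W1)),
              "fusedta_config_error")
  for (layer in params$layers) {
    z <- (1 + layer$eps) * h + graph$A %*% h
    h <- relu(sweep(z %*% layer$W1, 2L, layer$b1, `+`))
    if (!is.null(layer$W2))
      h <- sweep(h %*% layer$W2, 2L, layer$b2, `+`)
  }
  g <- if (config$readout == "sum") colSums(h) else colMeans(h)
  drop(g %*% params$W_out) + params$b_out
}

#' 3D embedder configuration
#' @param n_layers Message-passing layers.
#' @param hidden_width Node state width.
#' @param output_width Final embedding width (default 512).
#' @export
egnn_config <- function(n_layers = 2L, hidden_width = 64L,
                        output_width = 512L) {
  if (!is_count(n_layers) || !is_count(output_width))
    fdta_stop("n_layers and output_width must be positive integers",
              "fusedta_config_error")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_width = as.integer(hidden_width),
                 output_width = as.integer(output_width)),
            class = "egnn_config")
}

#' Initialize (random frozen) parameters for the 3D embedder
#' @param config An [egnn_config()].
#' @param in_width Atom attribute width.
#' @param seed Integer seed.
#' @export
egnn_init_params <- function(config, in_width, seed = 1L) {
  stopifnot(inherits(config, "egnn_config"))
  h <- config$hidden_width
  with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) list(
      W_msg = init_matrix(2L * h + 1L, h), b_msg = numeric(h),
      W_upd = init_matrix(2L * h, h),      b_upd = numeric(h)))
    list(W_in = init_matrix(in_width, h), b_in = numeric(h),
         layers = layers,
         W_out = init_matrix(h, config$output_width),
         b_out = numeric(config$output_width))
  })
}

#' 3D drug embedding via distance-featured message passing
#'
#' Messages along bonds are functions of the two node states and the squared
#' interatomic distance only, so the embedding is exactly invariant under
#' rigid rotations, reflections and translations of the conformer while
#' remaining sensitive to bond lengths and overall geometry.
#'
#' @param graph A [molecular_graph()] with coordinates `R` present (see
#'   [generate_conformer()]).
#' @param config An [egnn_config()].
#' @param params Parameters from [egnn_init_params()].
#' @return Numeric vector of length `config$output_width`.
#' @export
embed_3d <- function(graph, config, params) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(config, "egnn_config"))
  if (is.null(graph$R))
    fdta_stop(sprintf("graph%s has no 3D coordinates; run generate_conformer() first",
                      if (is.null(graph$id)) "" else paste0(" '", graph$id, "'")),
              "fusedta_featurization_error")
  n <- graph$n_atoms
  h <- relu(sweep(graph$X %*% params$W_in, 2L, params$b_in, `+`))
  edges <- which(graph$A == 1, arr.ind = TRUE)   # both directions
  for (layer in params$layers) {
    agg <- matrix(0, n, ncol(h))
    if (nrow(edges)) {
      i <- edges[, 1L]; j <- edges[, 2L]
      d2 <- rowSums((graph$R[i, , drop = FALSE] -
                     graph$R[j, , drop = FALSE])^2)
      msg <- relu(sweep(cbind(h[i, , drop = FALSE], h[j, , drop = FALSE], d2) %*%
                          layer$W_msg, 2L, layer$b_msg, `+`))
      s <- rowsum(msg, group = i)
      agg[as.integer(rownames(s)), ] <- s
    }
    h <- relu(sweep(cbind(h, agg) %*% layer$W_upd, 2L, layer$b_upd, `+`))
  }
  drop(colSums(h) %*% params$W_out) + params$b_out
}
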