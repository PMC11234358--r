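# Molecular graphs: construction from SMILES and deterministic 3D layout.

ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
MAX_DEGREE <- 6L          # degrees 1..5 one-hot, 6+ pooled
N_BOND_TYPES <- 4L        # single, double, triple, aromatic/other

#' Construct a molecular graph
#'
#' The graph container used by the 2D (GIN) and 3D (distance-featured)
#' embedders: `A` is the symmetric heavy-atom adjacency matrix, `X` the atom
#' attribute matrix (element one-hot over `C,N,O,S,P,F,Cl,Br,I,other` plus
#' degree one-hot), `E` the `n x n x 4` bond-order one-hot tensor (single,
#' double, triple, aromatic), and `R` optional `n x 3` coordinates.
#'
#' @param A n x n symmetric 0/1 adjacency with zero diagonal.
#' @param X n x K numeric atom attribute matrix.
#' @param E n x n x D numeric bond attribute array, nonzero only on edges.
#' @param R Optional n x 3 coordinate matrix.
#' @param atoms Optional character vector of element symbols.
#' @param id Optional drug id carried for error messages.
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(A, X, E, R = NULL, atoms = NULL, id = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n || !all(A %in% c(0, 1)) || any(diag(A) != 0) ||
      !isTRUE(all.equal(A, t(A))))
    fdta_stop("A must be a symmetric 0/1 matrix with zero diagonal",
              "fusedta_format_error")
  if (!is.matrix(X) || nrow(X) != n)
    fdta_stop("X must have one row per atom", "fusedta_format_error")
  if (length(dim(E)) != 3L || any(dim(E)[1:2] != n))
    fdta_stop("E must be an n x n x D array", "fusedta_format_error")
  off <- which(A == 0)
  for (d in seq_len(dim(E)[3L]))
    if (any(E[, , d][off] != 0))
      fdta_stop("E may be nonzero only where A is 1", "fusedta_format_error")
  if (!is.null(R)) {
    R <- as.matrix(R)
    if (nrow(R) != n || ncol(R) != 3L)
      fdta_stop("R must be an n x 3 coordinate matrix", "fusedta_format_error")
  }
  structure(list(n_atoms = n, A = A, X = X, E = E, R = R,
                 atoms = atoms, id = id),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("Molecular graph%s: %d atoms, %d bonds%s\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              x$n_atoms, sum(x$A) / 2,
              if (is.null(x$R)) "" else ", 3D coordinates"))
  invisible(x)
}

atom_features <- function(elements, degrees) {
  elem <- match(elements, ELEMENT_VOCAB, nomatch = length(ELEMENT_VOCAB))
  X <- matrix(0, length(elements), length(ELEMENT_VOCAB) + MAX_DEGREE)
  X[cbind(seq_along(elements), elem)] <- 1
  dg <- pmin(pmax(degrees, 1L), MAX_DEGREE)
  X[cbind(seq_along(elements), length(ELEMENT_VOCAB) + dg)] <- 1
  X
}

sdf_to_graph <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  A <- matrix(0, n, n)
  E <- array(0, c(n, n, N_BOND_TYPES))
  bb <- ChemmineR::bondblock(sdf)
  if (!is.null(bb) && nrow(bb)) {
    for (r in seq_len(nrow(bb))) {
      i <- bb[r, 1L]; j <- bb[r, 2L]
      ord <- min(max(bb[r, 3L], 1L), N_BOND_TYPES)
      A[i, j] <- A[j, i] <- 1
      E[i, j, ord] <- E[j, i, ord] <- 1
    }
  }
  X <- atom_features(elements, rowSums(A))
  molecular_graph(A, X, E, atoms = elements, id = id)
}

#' Parse SMILES strings into molecular graphs
#'
#' Uses the OpenBabel-backed SMILES parser; hydrogens stay implicit, so nodes
#' are heavy atoms and edges are heavy-atom bonds.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Character vector of drug ids (defaults to names of `smiles` or
#'   `drug1..drugN`).
#' @param on_error `"stop"` (default) raises on the first unparseable SMILES,
#'   naming the drug id; `"warn"` drops failures with a warning.
#' @return Named list of [molecular_graph()] objects.
#' @export
smiles_to_graphs <- function(smiles, ids = NULL, on_error = c("stop", "warn")) {
  on_error <- match.arg(on_error)
  ids <- ids %||% names(smiles) %||% paste0("drug", seq_along(smiles))
  if (any(!nzchar(smiles)))
    fdta_stop(sprintf("empty SMILES for drug '%s'", ids[!nzchar(smiles)][1L]),
              "fusedta_featurization_error")
  sml <- stats::setNames(as.character(smiles), ids)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(sml))
  ok <- suppressWarnings(ChemmineR::validSDF(sdf))
  # an atom block of all-zero coordinates with no bonds signals a parse failure
  # for multi-atom inputs; validSDF flags structurally broken records
  if (any(!ok)) {
    bad <- ids[!ok]
    msg <- sprintf("unparseable SMILES for drug '%s'", bad[1L])
    if (on_error == "stop") fdta_stop(msg, "fusedta_featurization_error")
    fdta_warn(msg, "fusedta_featurization_warning")
  }
  out <- vector("list", sum(ok))
  names(out) <- ids[ok]
  kept <- which(ok)
  for (k in seq_along(kept))
    out[[k]] <- sdf_to_graph(sdf[[kept[k]]], ids[kept[k]])
  out
}

#' Parse a single SMILES string
#' @param smiles A SMILES string.
#' @param id Drug id used in error messages.
#' @return A [molecular_graph()].
#' @export
smiles_to_graph <- function(smiles, id = "drug") {
  smiles_to_graphs(smiles, ids = id)[[1L]]
}

#' Generate deterministic 3D coordinates for a molecular graph
#'
#' Embeds the graph in 3D by classical multidimensional scaling of
#' shortest-path distances (scaled to a 1.5 length-unit bond), plus a small
#' seeded jitter that breaks planar/collinear degeneracies. The layout is a
#' pure function of the graph and the seed — it is a geometric embedding for
#' the distance-featured 3D encoder, not an energy-minimized conformer.
#'
#' @param graph A [molecular_graph()].
#' @param seed Integer seed.
#' @param bond_length Target length per graph edge (arbitrary units).
#' @return The graph with `R` filled in.
#' @export
generate_conformer <- function(graph, seed = 1L, bond_length = 1.5) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- graph$n_atoms
  with_seed(seed, {
    if (n == 1L) {
      R <- matrix(0, 1L, 3L)
    } else {
      g <- igraph::graph_from_adjacency_matrix(graph$A, mode = "undirected")
      D <- igraph::distances(g)
      if (any(!is.finite(D)))
        D[!is.finite(D)] <- max(D[is.finite(D)]) + 1
      D <- D * bond_length
      k <- min(3L, n - 1L)
      Y <- stats::cmdscale(D, k = k)
      R <- cbind(Y, matrix(0, n, 3L - k))
    }
    R <- R + matrix(stats::rnorm(n * 3L, sd = 0.05 * bond_length), n, 3L)
    graph$R <- unname(R)
    graph
  })
}
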