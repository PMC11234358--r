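# Independent oracle implementations used to cross-check the package's
# metric code, plus small fixture builders. Oracles are deliberately naive
# (explicit loops, lm-based fits) and share no code with R/.

# concordance index by exhaustive pair enumeration
oracle_ci <- function(y_true, y_pred) {
  n <- length(y_true)
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (y_true[i] == y_true[j]) next
      hi <- if (y_true[i] > y_true[j]) i else j
      lo <- i + j - hi
      den <- den + 1
      if (y_pred[hi] > y_pred[lo]) num <- num + 1
      else if (y_pred[hi] == y_pred[lo]) num <- num + 0.5
    }
  }
  num / den
}

# average precision by walking the ranked list and recording the
# precision at every positive hit
oracle_aupr <- function(labels, scores) {
  ord <- order(-scores)
  tp <- 0; hits <- numeric(0)
  for (r in seq_along(ord)) {
    if (labels[ord[r]] == 1) {
      tp <- tp + 1
      hits <- c(hits, tp / r)
    }
  }
  mean(hits)
}

# r_m^2 via lm(): with-intercept squared correlation and the
# through-origin coefficient of determination of predictions on truth
oracle_rm2 <- function(y_true, y_pred) {
  r2 <- summary(stats::lm(y_pred ~ y_true))$r.squared
  fit0 <- stats::lm(y_pred ~ 0 + y_true)
  r02 <- 1 - sum(stats::residuals(fit0)^2) / sum((y_pred - mean(y_pred))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

# exact two-sided McNemar p from the binomial distribution
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  min(1, 2 * min(pbinom(min(b, c), n, 0.5), 1 - pbinom(min(b, c) - 1, n, 0.5)))
}

# random connected-ish molecular-style graph with one-hot features
random_test_graph <- function(n, p_edge = 0.4, d_attr = 5L) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) A[i, i + 1L] <- A[i + 1L, i] <- 1  # spine
  extra <- matrix(runif(n * n) < p_edge, n, n)
  extra[lower.tri(extra, diag = TRUE)] <- FALSE
  A[extra] <- 1
  A <- pmax(A, t(A))
  X <- diag(d_attr)[sample.int(d_attr, n, replace = TRUE), , drop = FALSE]
  E <- array(0, c(n, n, 2L))
  E[, , 1L] <- A
  molecular_graph(A, X, E)
}

permute_graph <- function(graph, perm) {
  E2 <- graph$E[perm, perm, , drop = FALSE]
  molecular_graph(graph$A[perm, perm], graph$X[perm, , drop = FALSE], E2,
                  R = if (is.null(graph$R)) NULL
                      else graph$R[perm, , drop = FALSE])
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3L, 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# minimal interaction table fixture
toy_table <- function(n_drugs = 4L, n_proteins = 3L) {
  g <- expand.grid(d = sprintf("d%d", seq_len(n_drugs)),
                   p = sprintf("p%d", seq_len(n_proteins)),
                   stringsAsFactors = FALSE)
  interaction_table(g$d, g$p, seq_len(nrow(g)) / nrow(g) + 5, scale = "pKd")
}

# small random embedding set
toy_embeddings <- function(ids, width, kind = "drug", tag = "1D", seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(length(ids) * width), length(ids), width)
  rownames(m) <- ids
  embedding_set(m, kind, tag)
}
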