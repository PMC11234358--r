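# Interaction tables, affinity transforms, labels and reproducible splits.

AFFINITY_SCALES <- c("Kd_nM", "pKd", "KIBA_score", "arbitrary")

#' Construct a validated drug-target interaction table
#'
#' The central regression-target container: one row per (drug, protein) pair
#' with a continuous affinity and a declared affinity scale. The scale is
#' carried as metadata and never auto-detected; `Kd_nM` is a raw dissociation
#' constant in nanomolar, `pKd` its negative molar log10 (see [kd_to_pkd()]),
#' `KIBA_score` the composite kinase-inhibitor score.
#'
#' @param drug_id,protein_id Character vectors of entity identifiers.
#' @param affinity Numeric vector of affinities, all finite.
#' @param scale One of `"Kd_nM"`, `"pKd"`, `"KIBA_score"`, `"arbitrary"`.
#' @return A `data.frame` of class `interaction_table` with attribute `scale`.
#' @export
interaction_table <- function(drug_id, protein_id, affinity,
                              scale = "arbitrary") {
  scale <- match.arg(scale, AFFINITY_SCALES)
  drug_id <- as.character(drug_id)
  protein_id <- as.character(protein_id)
  if (length(drug_id) != length(protein_id) || length(drug_id) != length(affinity))
    fdta_stop("drug_id, protein_id and affinity must have equal length",
              "fusedta_format_error")
  if (!all(is.finite(affinity)))
    fdta_stop("all affinities must be finite", "fusedta_format_error")
  key <- paste(drug_id, protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    fdta_stop(sprintf("duplicate (drug_id, protein_id) pair: (%s)",
                      gsub("\r", ", ", d, fixed = TRUE)),
              "fusedta_duplicate_error")
  }
  if (scale == "Kd_nM" && any(affinity <= 0))
    fdta_stop("Kd_nM affinities must be strictly positive", "fusedta_domain_error")
  out <- data.frame(drug_id = drug_id, protein_id = protein_id,
                    affinity = as.numeric(affinity), stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' @export
`[.interaction_table` <- function(x, ...) {
  sc <- attr(x, "scale")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "scale") <- sc
    class(out) <- c("interaction_table", "data.frame")
  }
  out
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("Interaction table: %d pairs, %d drugs, %d proteins, scale=%s\n",
              nrow(x), length(unique(x$drug_id)), length(unique(x$protein_id)),
              attr(x, "scale")))
  NextMethod()
}

#' Read an interaction table from CSV/TSV
#'
#' The file must have a header with columns `drug_id`, `protein_id` and
#' `affinity`; the separator (comma or tab) is detected from the header line.
#' Decimal points only, no locale-specific commas.
#'
#' @param path Path to the file.
#' @inheritParams interaction_table
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path, scale = "arbitrary") {
  if (!file.exists(path))
    fdta_stop(sprintf("no such file: %s", path), "fusedta_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  for (col in c("drug_id", "protein_id", "affinity"))
    if (!col %in% names(df))
      fdta_stop(sprintf("missing required column '%s' in %s", col, path),
                "fusedta_format_error")
  aff <- suppressWarnings(as.numeric(df$affinity))
  bad <- which(is.na(aff) | !is.finite(aff))
  if (length(bad))
    fdta_stop(sprintf("non-numeric affinity '%s' on line %d of %s",
                      df$affinity[bad[1L]], bad[1L] + 1L, path),
              "fusedta_parse_error")
  interaction_table(df$drug_id, df$protein_id, aff, scale = scale)
}

#' Write an interaction table to CSV
#' @param table An [interaction_table()].
#' @param path Output path.
#' @export
write_interaction_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("drug_id", "protein_id", "affinity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a dissociation constant in nM to pKd
#'
#' `pKd = -log10(Kd / 1e9)`, i.e. the negative log10 of the molar Kd. The map
#' is strictly decreasing: tighter binders (smaller Kd) get larger pKd. On the
#' DAVIS benchmark this lands affinities in roughly \[5, 10\].
#'
#' @param kd Numeric vector of Kd values in nanomolar, all `> 0`.
#' @return pKd values.
#' @seealso [pkd_to_kd()] for the inverse.
#' @export
kd_to_pkd <- function(kd) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0))
    fdta_stop("kd must be finite and > 0 (nM)", "fusedta_domain_error")
  -log10(kd / 1e9)
}

#' Inverse of [kd_to_pkd()]: pKd back to Kd in nM
#' @param pkd Numeric vector of pKd values.
#' @export
pkd_to_kd <- function(pkd) {
  if (!is.numeric(pkd) || any(!is.finite(pkd)))
    fdta_stop("pkd must be finite", "fusedta_domain_error")
  1e9 * 10^(-pkd)
}

#' Binarize continuous affinities at a threshold
#'
#' Used to derive classification labels for AUPR and McNemar comparisons; the
#' conventional thresholds are 7 (pKd, DAVIS) and 12.1 (KIBA score). Values
#' equal to the threshold are labeled positive by default.
#'
#' @param values Numeric vector of affinities.
#' @param threshold Finite cut point.
#' @param positive_if `"ge"` (default) labels `value >= threshold` positive;
#'   `"gt"` requires a strict inequality.
#' @return Integer vector of 0/1 labels, same length as `values`.
#' @export
binarize_affinity <- function(values, threshold, positive_if = c("ge", "gt")) {
  positive_if <- match.arg(positive_if)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    fdta_stop("threshold must be a single finite number", "fusedta_domain_error")
  if (!length(values)) return(integer(0))
  if (positive_if == "ge") as.integer(values >= threshold)
  else as.integer(values > threshold)
}

#' Specify a train/test and cross-validation split
#'
#' @param test_fraction Fraction of rows held out for the test set (default
#'   0.2, the benchmark convention).
#' @param n_folds Number of cross-validation folds over the training rows
#'   (default 5).
#' @param seed Integer seed; identical seeds give byte-identical splits.
#' @param unit `"pair"` (default) splits interaction rows at random;
#'   `"cold_drug"` / `"cold_protein"` put all rows of held-out entities in the
#'   test set (optional stricter protocols, not the benchmark default).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, n_folds = 5L, seed = 1L,
                       unit = c("pair", "cold_drug", "cold_protein")) {
  unit <- match.arg(unit)
  if (!is_prob(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    fdta_stop("test_fraction must be in (0, 1)", "fusedta_config_error")
  if (!is_count(n_folds, min = 2L))
    fdta_stop("n_folds must be an integer >= 2", "fusedta_config_error")
  if (!is_count(seed, min = 0L))
    fdta_stop("seed must be a non-negative integer", "fusedta_config_error")
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), unit = unit),
            class = "split_spec")
}

#' Split an interaction table into train/test plus cross-validation folds
#'
#' Rows are partitioned into a training and a test set
#' (`|test| = round(test_fraction * N)`), and the training rows are further
#' partitioned into `n_folds` disjoint validation folds. The split is a pure
#' function of the table and the spec seed.
#'
#' @param table An [interaction_table()].
#' @param spec A [split_spec()].
#' @return A list of class `dta_split` with elements `train`, `test`
#'   (interaction tables), `folds` (list of `list(train=, validation=)` index
#'   vectors into `train`), and `spec`.
#' @export
split_data <- function(table, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(table)
  if (!n) fdta_stop("cannot split an empty table", "fusedta_config_error")
  with_seed(spec$seed, {
    if (spec$unit == "pair") {
      n_test <- round(spec$test_fraction * n)
      test_idx <- sort(sample.int(n, n_test))
    } else {
      col <- if (spec$unit == "cold_drug") "drug_id" else "protein_id"
      ids <- unique(table[[col]])
      n_hold <- max(1L, round(spec$test_fraction * length(ids)))
      hold <- sample(ids, n_hold)
      test_idx <- which(table[[col]] %in% hold)
    }
    train_idx <- setdiff(seq_len(n), test_idx)
    if (spec$n_folds > length(train_idx))
      fdta_stop(sprintf("n_folds (%d) exceeds training rows (%d)",
                        spec$n_folds, length(train_idx)),
                "fusedta_config_error")
    fold_of <- sample(rep_len(seq_len(spec$n_folds), length(train_idx)))
    folds <- lapply(seq_len(spec$n_folds), function(k) {
      list(train = which(fold_of != k), validation = which(fold_of == k))
    })
    structure(list(train = table[train_idx, , drop = FALSE],
                   test = table[test_idx, , drop = FALSE],
                   train_index = train_idx, test_index = test_idx,
                   folds = folds, spec = spec),
              class = "dta_split")
  })
}

#' @export
print.dta_split <- function(x, ...) {
  cat(sprintf("Split: %d train / %d test rows, %d folds, seed %d, unit '%s'\n",
              nrow(x$train), nrow(x$test), length(x$folds), x$spec$seed,
              x$spec$unit))
  invisible(x)
}
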