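# Synthetic benchmark generator: toy molecules, random protein sequences,
# per-dimension embeddings with controllable cross-modal signal, and
# affinity tables with a bilinear latent ground truth.

# small, structurally varied molecules; all parse with the SMILES parser
SMILES_POOL <- c(
  "C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CC(C)(C)C",
  "CCO", "CCCO", "CCN", "CCCN", "CCOC", "CC(=O)O", "CC(=O)N", "CC=O",
  "C=CC", "C#CC", "CCS", "CS",
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1",
  "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "c1ccncc1", "c1ccoc1", "c1ccsc1", "CCc1ccccc1",
  "ClCC", "BrCC", "FC(F)C", "CC(N)C(=O)O", "OCC(O)CO")

EMB_KEYS <- c("drug_1D", "drug_2D", "drug_3D",
              "protein_1D", "protein_2D", "protein_3D")

#' Specify a synthetic drug-target benchmark
#'
#' The generator draws a latent vector per drug and per protein; the true
#' affinity of a pair is the latent dot product, affinely rescaled into
#' `affinity_range` plus Gaussian noise — a bilinear ground truth that no
#' single embedding sees linearly, which is exactly what a fusion model is
#' for. Each of the six per-dimension embeddings mixes a random linear image
#' of the latent (weight = its informativeness) with independent noise
#' (weight = 1 - informativeness), so signal can be placed in, or withheld
#' from, any dimension.
#'
#' @param n_drugs,n_proteins Entity counts (>= 2). A DAVIS-shaped benchmark
#'   is 68 x 442 at density 1; KIBA-shaped data is larger and sparse.
#' @param latent_width Latent dimensionality of the bilinear ground truth.
#' @param informativeness Either a single value in `[0, 1]` or a named
#'   6-vector over `drug_1D..protein_3D`.
#' @param noise_sd Gaussian noise added to affinities (affinity units).
#' @param affinity_range Length-2 numeric, low < high; default `c(5, 10)`,
#'   the pKd range of DAVIS-like data.
#' @param density Fraction of the drug x protein grid emitted, in (0, 1].
#' @param widths Named widths per embedding, defaulting to 100/300/512
#'   (drug) and 100/768/1280 (protein).
#' @param seed Master integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 68L, n_proteins = 442L,
                           latent_width = 4L, informativeness = 1,
                           noise_sd = 0.25, affinity_range = c(5, 10),
                           density = 1, seed = 1L, widths = NULL) {
  if (!is_count(n_drugs, 2L) || !is_count(n_proteins, 2L))
    fdta_stop("n_drugs and n_proteins must be integers >= 2",
              "fusedta_config_error")
  if (length(informativeness) == 1L)
    informativeness <- stats::setNames(rep(informativeness, 6L), EMB_KEYS)
  if (!all(EMB_KEYS %in% names(informativeness)))
    fdta_stop("informativeness must be a scalar or named over drug_1D..protein_3D",
              "fusedta_config_error")
  informativeness <- informativeness[EMB_KEYS]
  if (any(informativeness < 0 | informativeness > 1))
    fdta_stop("informativeness values must lie in [0, 1]",
              "fusedta_config_error")
  if (length(affinity_range) != 2L || affinity_range[1L] >= affinity_range[2L])
    fdta_stop("affinity_range must be (low, high) with low < high",
              "fusedta_config_error")
  if (noise_sd < 0) fdta_stop("noise_sd must be >= 0", "fusedta_config_error")
  if (density <= 0 || density > 1)
    fdta_stop("density must be in (0, 1]", "fusedta_config_error")
  dflt <- stats::setNames(c(DEFAULT_WIDTHS$drug, DEFAULT_WIDTHS$protein),
                          EMB_KEYS)
  if (!is.null(widths)) dflt[names(widths)] <- unlist(widths)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 latent_width = as.integer(latent_width),
                 informativeness = informativeness,
                 noise_sd = noise_sd,
                 affinity_range = as.numeric(affinity_range),
                 density = density, widths = dflt,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic drugs, proteins and molecular graphs
#'
#' Drugs are drawn (with replacement) from a fixed pool of small valid
#' SMILES; proteins are random sequences over the 20-letter amino-acid
#' alphabet with lengths uniform in \[200, 1500\]. Ids and draws are a pure
#' function of the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param graphs Also parse each drug into a [molecular_graph()]
#'   (default `TRUE`).
#' @return List with `drugs` (id, smiles), `proteins` (id, sequence) and
#'   `graphs` (named list, one per drug; `NULL` if `graphs = FALSE`).
#' @export
generate_entities <- function(spec, graphs = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drugs <- with_seed(derive_seed(spec$seed, "drugs"), {
    data.frame(id = sprintf("D%04d", seq_len(spec$n_drugs)),
               smiles = sample(SMILES_POOL, spec$n_drugs, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  proteins <- with_seed(derive_seed(spec$seed, "proteins"), {
    lens <- sample(200:1500, spec$n_proteins, replace = TRUE)
    data.frame(id = sprintf("P%04d", seq_len(spec$n_proteins)),
               sequence = vapply(lens, function(L)
                 paste(sample(AA_ALPHABET[1:20], L, replace = TRUE),
                       collapse = ""), ""),
               stringsAsFactors = FALSE)
  })
  graph_list <- NULL
  if (graphs) {
    uniq <- unique(drugs$smiles)
    parsed <- smiles_to_graphs(uniq, ids = uniq)
    graph_list <- lapply(seq_len(nrow(drugs)), function(i) {
      g <- parsed[[drugs$smiles[i]]]
      g$id <- drugs$id[i]
      g
    })
    names(graph_list) <- drugs$id
  }
  list(drugs = drugs, proteins = proteins, graphs = graph_list)
}

#' Generate the six embedding sets and the affinity table
#'
#' Latents are standard normal. Each per-dimension embedding is
#' `w * [latent, 1] P + (1 - w) * noise`, where `P` is a fixed random
#' projection and `w` the dimension's informativeness; the appended constant
#' coordinate keeps the latent magnitude recoverable after the pipeline's
#' L2 normalization. Affinities are the latent dot products with the
#' population mean +/- 2 sd band mapped affinely onto `affinity_range`, plus
#' Gaussian noise. Each random stream is seeded independently, so changing
#' `noise_sd` alone never changes the embeddings.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `drug` and `protein` (named lists of [embedding_set()]s
#'   by dim tag), `table` (an [interaction_table()]), `latents`
#'   (`list(drug=, protein=)`), and `spec`.
#' @export
generate_embeddings_and_affinity <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$latent_width
  U <- with_seed(derive_seed(spec$seed, "latent_drug"),
                 matrix(stats::rnorm(spec$n_drugs * k), spec$n_drugs, k))
  V <- with_seed(derive_seed(spec$seed, "latent_protein"),
                 matrix(stats::rnorm(spec$n_proteins * k), spec$n_proteins, k))
  rownames(U) <- sprintf("D%04d", seq_len(spec$n_drugs))
  rownames(V) <- sprintf("P%04d", seq_len(spec$n_proteins))
  make_set <- function(key, latent, kind, tag) {
    w <- spec$widths[[key]]
    inf <- spec$informativeness[[key]]
    P <- with_seed(derive_seed(spec$seed, paste0("proj_", key)),
                   matrix(stats::rnorm((k + 1L) * w, sd = 1 / sqrt(k + 1)),
                          k + 1L, w))
    noise <- with_seed(derive_seed(spec$seed, paste0("noise_", key)),
                       matrix(stats::rnorm(nrow(latent) * w),
                              nrow(latent), w))
    m <- inf * (cbind(latent, 1) %*% P) + (1 - inf) * noise
    rownames(m) <- rownames(latent)
    embedding_set(m, kind, tag)
  }
  drug_sets <- stats::setNames(
    lapply(DIM_TAGS, function(tg) make_set(paste0("drug_", tg), U, "drug", tg)),
    DIM_TAGS)
  protein_sets <- stats::setNames(
    lapply(DIM_TAGS, function(tg) make_set(paste0("protein_", tg), V,
                                           "protein", tg)),
    DIM_TAGS)
  S <- U %*% t(V)
  lo <- spec$affinity_range[1L]; hi <- spec$affinity_range[2L]
  # map the +/- 2 sd band of the dot product onto the range, then saturate
  # at the bounds the way affinity assays censor at their measurement limits
  # (cf. the pile-up of DAVIS affinities at the pKd = 5 floor)
  signal <- (lo + hi) / 2 + S * (hi - lo) / (4 * sqrt(k))
  signal <- pmin(pmax(signal, lo), hi)
  pairs <- expand.grid(protein = seq_len(spec$n_proteins),
                       drug = seq_len(spec$n_drugs))[, c("drug", "protein")]
  if (spec$density < 1) {
    keep <- with_seed(derive_seed(spec$seed, "pairs"),
                      stats::runif(nrow(pairs)) < spec$density)
    pairs <- pairs[keep, , drop = FALSE]
  }
  aff <- signal[cbind(pairs$drug, pairs$protein)]
  if (spec$noise_sd > 0)
    aff <- aff + with_seed(derive_seed(spec$seed, "affinity_noise"),
                           stats::rnorm(length(aff), sd = spec$noise_sd))
  scale <- if (isTRUE(all.equal(spec$affinity_range, c(5, 10))))
    "pKd" else "arbitrary"
  table <- interaction_table(rownames(U)[pairs$drug],
                             rownames(V)[pairs$protein], aff, scale = scale)
  list(drug = drug_sets, protein = protein_sets, table = table,
       latents = list(drug = U, protein = V), spec = spec)
}

#' Write a complete synthetic fixture directory
#'
#' Emits `drugs.smi`, `proteins.fasta`, `interactions.csv`, the six
#' embedding files (`drug_1D.tsv`, ..., `protein_3D.tsv`) and a
#' `manifest.json` recording the spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ent <- generate_entities(spec, graphs = FALSE)
  gen <- generate_embeddings_and_affinity(spec)
  write_smiles_file(ent$drugs, file.path(dir, "drugs.smi"))
  write_protein_fasta(ent$proteins, file.path(dir, "proteins.fasta"))
  write_interaction_table(gen$table, file.path(dir, "interactions.csv"))
  for (kind in c("drug", "protein"))
    for (tg in DIM_TAGS)
      write_embeddings(gen[[kind]][[tg]],
                       file.path(dir, sprintf("%s_%s.tsv", kind, tg)))
  manifest <- c(list(generator = "fusedta synthetic benchmark"),
                unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
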