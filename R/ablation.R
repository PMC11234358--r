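# Ablation harnesses: leave-one-embedding-out and single-dimension pairwise
# concatenation. All variants in a study share the same split and seeds.

fit_and_score <- function(data, config, split, threshold) {
  fold <- split$folds[[1L]]
  tr <- split$train[fold$train, , drop = FALSE]
  va <- split$train[fold$validation, , drop = FALSE]
  widths <- c(
    stats::setNames(lapply(config$drug_dims,
                           function(d) data$drug[[d]]$width),
                    paste0("drug_", config$drug_dims)),
    stats::setNames(lapply(config$protein_dims,
                           function(d) data$protein[[d]]$width),
                    paste0("protein_", config$protein_dims)))
  model <- build_fusion_model(config, widths)
  x_tr <- assemble_inputs(tr, data$drug, data$protein, config)
  x_va <- assemble_inputs(va, data$drug, data$protein, config)
  model <- train_fusion_model(model, x_tr, tr$affinity, x_va, va$affinity)
  x_te <- assemble_inputs(split$test, data$drug, data$protein, config)
  report <- evaluate_predictions(split$test$affinity,
                                 predict(model, x_te), threshold)
  list(model = model, report = report)
}

study_result <- function(rows, split, threshold, study) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(variant = r$variant, mse = r$report$mse, ci = r$report$ci,
               rm2 = r$report$rm2, aupr = r$report$aupr,
               best_epoch = r$model$best_epoch, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "split") <- split
  attr(df, "threshold") <- threshold
  attr(df, "study") <- study
  class(df) <- c("ablation_study", "data.frame")
  df
}

#' @export
print.ablation_study <- function(x, ...) {
  cat(sprintf("Ablation study (%s), %d variants, threshold %.4g\n",
              attr(x, "study"), nrow(x), attr(x, "threshold")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Leave-one-embedding-out ablation study
#'
#' Trains and evaluates the full six-dimension fusion model plus one variant
#' per single excluded embedding (6 exclusions), all under identical splits
#' and seeds, and reports MSE/CI/r_m^2/AUPR per variant. The drop in
#' performance when a dimension is excluded measures that embedding's unique
#' contribution.
#'
#' @param data List with `table` (an [interaction_table()]) and `drug`,
#'   `protein` (named lists of [embedding_set()]s by dim tag), as returned
#'   by [generate_embeddings_and_affinity()].
#' @param config Base [fusion_config()] with all three dims on both sides.
#' @param split A [split_spec()] shared by every variant.
#' @param threshold Binarization threshold for AUPR.
#' @return A 7-row `ablation_study` data.frame (`full` + 6 exclusions).
#' @export
run_exclusion_study <- function(data, config = fusion_config(),
                                split = split_spec(), threshold = 7) {
  for (tg in DIM_TAGS) {
    if (is.null(data$drug[[tg]]) || is.null(data$protein[[tg]]))
      fdta_stop(sprintf("exclusion study needs all six embedding sets (missing %s)",
                        tg),
                "fusedta_config_error")
  }
  sp <- split_data(data$table, split)
  variants <- c(list(list(label = "full", drug = DIM_TAGS,
                          protein = DIM_TAGS)),
                lapply(DIM_TAGS, function(d)
                  list(label = paste0("exclude:drug-", d),
                       drug = setdiff(DIM_TAGS, d), protein = DIM_TAGS)),
                lapply(DIM_TAGS, function(d)
                  list(label = paste0("exclude:protein-", d),
                       drug = DIM_TAGS, protein = setdiff(DIM_TAGS, d))))
  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$drug_dims <- v$drug
    cfg$protein_dims <- v$protein
    r <- fit_and_score(data, cfg, sp, threshold)
    r$variant <- v$label
    r
  })
  study_result(rows, sp, threshold, "exclusion")
}

#' Pairwise single-dimension ablation study
#'
#' For each of the 9 (drug dim, protein dim) pairs, bypasses the fusion
#' blocks entirely: the two normalized embeddings are concatenated and fed
#' straight into the three-layer head ("simple concatenation"). The full
#' fusion model is evaluated alongside as the reference, on the identical
#' split.
#'
#' @inheritParams run_exclusion_study
#' @param normalize_pairs L2-normalize embeddings before concatenation in
#'   the pair variants (default `TRUE`, for comparability across widths).
#' @return A 10-row `ablation_study` data.frame (9 pairs + `full`).
#' @export
run_pairwise_study <- function(data, config = fusion_config(),
                               split = split_spec(), threshold = 7,
                               normalize_pairs = TRUE) {
  sp <- split_data(data$table, split)
  rows <- list()
  for (d in DIM_TAGS) {
    for (p in DIM_TAGS) {
      cfg <- config
      cfg$drug_dims <- d
      cfg$protein_dims <- p
      cfg$use_blocks <- FALSE
      cfg$normalize <- normalize_pairs
      r <- fit_and_score(data, cfg, sp, threshold)
      r$variant <- paste0("pair:", d, "+", p)
      rows[[length(rows) + 1L]] <- r
    }
  }
  full_cfg <- config
  full_cfg$drug_dims <- DIM_TAGS
  full_cfg$protein_dims <- DIM_TAGS
  r <- fit_and_score(data, full_cfg, sp, threshold)
  r$variant <- "full"
  rows[[length(rows) + 1L]] <- r
  study_result(rows, sp, threshold, "pairwise")
}

#' Write an ablation study as CSV
#' @param study An `ablation_study`.
#' @param path Output path.
#' @export
write_ablation_csv <- function(study, path) {
  utils::write.csv(as.data.frame(study), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
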