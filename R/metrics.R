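# Evaluation metrics: MSE, concordance index, r_m^2, AUPR, McNemar.

#' Mean squared error
#' @param y_true,y_pred Numeric vectors of equal nonzero length.
#' @export
mse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    fdta_stop("y_true and y_pred must have equal nonzero length",
              "fusedta_shape_error")
  mean((y_true - y_pred)^2)
}

#' Concordance index for continuous affinity predictions
#'
#' Over all pairs `(i, j)` with `y_true_i > y_true_j`, scores 1 when
#' `y_pred_i > y_pred_j`, 0.5 on a prediction tie, 0 otherwise, and averages.
#' Pairs tied in the true affinity are excluded from the denominator. The
#' index is invariant under any strictly increasing transform of the
#' predictions; 0.5 is chance level, 1 a perfect ranking.
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 2), with at
#'   least two distinct `y_true` values.
#' @return A number in `[0, 1]`.
#' @export
concordance_index <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    fdta_stop("y_true and y_pred must have equal length", "fusedta_shape_error")
  n <- length(y_true)
  if (n < 2L || length(unique(y_true)) < 2L)
    fdta_stop("concordance index undefined: need >= 2 distinct true values",
              "fusedta_undefined_metric_error")
  # O(n^2) pair comparison, chunked to bound memory at ~n * chunk doubles
  num <- 0; den <- 0
  chunk <- max(1L, min(n, floor(2e7 / n)))
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(n, start + chunk - 1L)
    dy <- outer(y_true[ii], y_true, `-`)
    dp <- outer(y_pred[ii], y_pred, `-`)
    gt <- dy > 0
    den <- den + sum(gt)
    num <- num + sum(gt & dp > 0) + 0.5 * sum(gt & dp == 0)
  }
  num / den
}

#' Modified squared correlation r_m^2
#'
#' `r_m^2 = r^2 * (1 - sqrt(|r^2 - r0^2|))`, where `r^2` is the squared
#' Pearson correlation between observed and predicted values (fit with
#' intercept) and `r0^2` is the coefficient of determination of the
#' least-squares fit of predictions on observations constrained through the
#' origin. The penalty term shrinks the score whenever the through-origin fit
#' disagrees with the free fit, so `r_m^2 <= r^2` always, with equality (and
#' value 1) only for a perfect prediction.
#'
#' @param y_true,y_pred Numeric vectors, length >= 3, neither constant.
#' @export
rm2 <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 3L)
    fdta_stop("rm2 needs >= 3 paired observations", "fusedta_shape_error")
  if (stats::var(y_true) == 0 || stats::var(y_pred) == 0)
    fdta_stop("rm2 undefined for constant sequences",
              "fusedta_undefined_metric_error")
  r2 <- stats::cor(y_true, y_pred)^2
  k <- sum(y_true * y_pred) / sum(y_true^2)
  ss_res <- sum((y_pred - k * y_true)^2)
  ss_tot <- sum((y_pred - mean(y_pred))^2)
  r02 <- 1 - ss_res / ss_tot
  gap <- abs(r2 - r02)
  if (gap < 1e-12) gap <- 0   # guard the sqrt against rounding noise
  r2 * (1 - sqrt(gap))
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed by the average-precision step summation: instances are ranked by
#' decreasing score and precision is averaged at the rank of each positive.
#' No linear interpolation between operating points is applied (interpolation
#' biases the area upward). Score ties are broken by input order.
#'
#' @param labels 0/1 vector with at least one positive and one negative.
#' @param scores Numeric scores, higher = more likely positive.
#' @return A number in `[0, 1]`.
#' @export
aupr <- function(labels, scores) {
  if (length(labels) != length(scores))
    fdta_stop("labels and scores must have equal length", "fusedta_shape_error")
  if (!all(labels %in% c(0, 1)))
    fdta_stop("labels must be 0/1", "fusedta_format_error")
  if (sum(labels) == 0 || sum(labels) == length(labels))
    fdta_stop("aupr undefined: need both classes present",
              "fusedta_undefined_metric_error")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  mean(precision[lab == 1])
}

#' McNemar test on two classifiers' paired predictions
#'
#' Compares classifiers A and B on the same instances via their discordant
#' counts `b` (A correct, B wrong) and `c` (B correct, A wrong). For
#' `b + c < 25` an exact two-sided binomial test is used; otherwise the
#' continuity-corrected chi-square test. With no discordant pairs the test is
#' degenerate and p = 1 is returned with a warning.
#'
#' @param labels True 0/1 labels.
#' @param preds_a,preds_b 0/1 predictions from the two classifiers.
#' @param method `"auto"` (default), `"exact"`, or `"chisq"`.
#' @return List with `p_value`, `b`, `c` and `method`.
#' @export
mcnemar_test <- function(labels, preds_a, preds_b,
                         method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  if (length(labels) != length(preds_a) || length(labels) != length(preds_b))
    fdta_stop("labels and predictions must have equal length",
              "fusedta_shape_error")
  if (!all(c(labels, preds_a, preds_b) %in% c(0, 1)))
    fdta_stop("inputs must be binary 0/1", "fusedta_format_error")
  a_ok <- preds_a == labels
  b_ok <- preds_b == labels
  b <- sum(a_ok & !b_ok)
  cc <- sum(!a_ok & b_ok)
  n <- b + cc
  if (n == 0L) {
    fdta_warn("no discordant pairs; McNemar test degenerate, p = 1",
              "fusedta_degenerate_warning")
    return(list(p_value = 1, b = b, c = cc, method = "degenerate"))
  }
  if (method == "auto") method <- if (n < 25L) "exact" else "chisq"
  p <- if (method == "exact") {
    stats::binom.test(b, n, p = 0.5)$p.value
  } else {
    tab <- matrix(c(sum(a_ok & b_ok), cc, b, sum(!a_ok & !b_ok)), 2L, 2L)
    stats::mcnemar.test(tab, correct = TRUE)$p.value
  }
  list(p_value = min(1, p), b = b, c = cc, method = method)
}

#' Evaluate predictions into a full report
#'
#' Computes MSE, CI, r_m^2 and AUPR on the pooled predictions; when a `fold`
#' assignment is supplied, also the standard deviation of CI, r_m^2 and AUPR
#' across folds. Undefined-metric conditions (constant truth, single-class
#' labels) propagate as errors naming the metric.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @param threshold Binarization threshold used for AUPR (e.g. 7 for pKd,
#'   12.1 for KIBA scores).
#' @param fold Optional integer/factor fold assignment per observation.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(y_true, y_pred, threshold, fold = NULL) {
  labels <- binarize_affinity(y_true, threshold)
  report <- list(mse = mse(y_true, y_pred),
                 ci = concordance_index(y_true, y_pred),
                 rm2 = rm2(y_true, y_pred),
                 aupr = aupr(labels, y_pred),
                 std_ci = NA_real_, std_rm2 = NA_real_, std_aupr = NA_real_,
                 threshold = threshold, n = length(y_true))
  if (!is.null(fold)) {
    per <- lapply(split(seq_along(y_true), fold), function(ii) {
      lab <- labels[ii]
      c(ci = concordance_index(y_true[ii], y_pred[ii]),
        rm2 = rm2(y_true[ii], y_pred[ii]),
        aupr = if (sum(lab) > 0 && sum(lab) < length(lab))
          aupr(lab, y_pred[ii]) else NA_real_)
    })
    per <- do.call(rbind, per)
    report$std_ci <- stats::sd(per[, "ci"])
    report$std_rm2 <- stats::sd(per[, "rm2"])
    report$std_aupr <- stats::sd(per[, "aupr"], na.rm = TRUE)
  }
  structure(report, class = "evaluation_report")
}

#' Evaluate a predictions CSV file
#'
#' Tool-agnostic entry point: the file must have columns
#' `drug_id,protein_id,y_true,y_pred`.
#'
#' @param path CSV file of predictions.
#' @inheritParams evaluate_predictions
#' @export
evaluate_file <- function(path, threshold) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("y_true", "y_pred"))
    if (!col %in% names(df))
      fdta_stop(sprintf("missing required column '%s' in %s", col, path),
                "fusedta_format_error")
  evaluate_predictions(df$y_true, df$y_pred, threshold)
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4f", v)
                        else sprintf("%.4f (%.4f)", v, s)
  cat("Evaluation report\n")
  cat(sprintf("  n         %d\n", x$n))
  cat(sprintf("  threshold %.4g\n", x$threshold))
  cat(sprintf("  MSE       %.4f\n", x$mse))
  cat(sprintf("  CI        %s\n", fmt(x$ci, x$std_ci)))
  cat(sprintf("  r_m^2     %s\n", fmt(x$rm2, x$std_rm2)))
  cat(sprintf("  AUPR      %s\n", fmt(x$aupr, x$std_aupr)))
  invisible(x)
}

#' Write an evaluation report as machine-readable key-value text
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  keys <- c("mse", "ci", "rm2", "aupr", "std_ci", "std_rm2", "std_aupr",
            "threshold", "n")
  writeLines(sprintf("%s\t%s", keys,
                     vapply(report[keys], function(v)
                       sprintf("%.10g", as.numeric(v)), "")), path)
  invisible(path)
}
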