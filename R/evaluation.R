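#' F1 score over imputed cells
#'
#' Compares imputed categories against the known true categories of the same
#' cells. Per-category precision and recall come from the confusion counts;
#' F1 is their harmonic mean, `2 * precision * recall / (precision + recall)`.
#' Aggregation is macro (unweighted mean over categories; default), micro
#' (from pooled counts — for single-label assignment this equals accuracy),
#' or weighted (by true-category frequency).
#'
#' A category that never occurs in either vector is excluded from the macro
#' and weighted means (its F1 is undefined). A category that occurs but is
#' never correctly predicted has F1 = 0.
#'
#' @param true_values Integer/factor vector of true categories.
#' @param imputed_values Integer/factor vector of imputed categories, same
#'   length and code set.
#' @param averaging `"macro"` (default), `"micro"`, or `"weighted"`.
#' @return An object of class `irtci_cell_score`: `per_category` (data.frame
#'   of category, n_true, precision, recall, f1), `f1` (the requested
#'   aggregate), `macro_f1`, `micro_f1`, `weighted_f1`, `accuracy`,
#'   `averaging`, `n_cells`.
#' @export
imputed_cell_f1 <- function(true_values, imputed_values,
                            averaging = c("macro", "micro", "weighted")) {
  averaging <- match.arg(averaging)
  if (length(true_values) != length(imputed_values))
    stop("'true_values' and 'imputed_values' must have the same length",
         call. = FALSE)
  if (length(true_values) == 0L)
    stop("cannot score zero cells", call. = FALSE)
  if (anyNA(true_values) || anyNA(imputed_values))
    stop("scored cells must not contain missing values", call. = FALSE)

  lv <- sort(unique(c(as.vector(true_values), as.vector(imputed_values))))
  tr <- factor(true_values, levels = lv)
  im <- factor(imputed_values, levels = lv)
  conf <- table(true = tr, imputed = im)

  tp <- diag(conf)
  n_true <- rowSums(conf)   # support per category
  n_pred <- colSums(conf)
  precision <- ifelse(n_pred > 0, tp / n_pred, NA_real_)
  recall <- ifelse(n_true > 0, tp / n_true, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  # category absent from both vectors: undefined, drop from averages
  present <- n_true + n_pred > 0
  f1[!present] <- NA_real_

  macro <- mean(f1[present])
  acc <- sum(tp) / length(tr)
  micro <- acc  # pooled precision = pooled recall = accuracy for single-label
  weighted <- if (sum(n_true) > 0)
    sum(f1[present] * n_true[present]) / sum(n_true[present]) else NA_real_

  per_cat <- data.frame(category = lv, n_true = as.integer(n_true),
                        precision = as.numeric(precision),
                        recall = as.numeric(recall), f1 = as.numeric(f1))
  structure(list(per_category = per_cat,
                 f1 = switch(averaging, macro = macro, micro = micro,
                             weighted = weighted),
                 macro_f1 = macro, micro_f1 = micro, weighted_f1 = weighted,
                 accuracy = acc, averaging = averaging,
                 n_cells = length(tr)),
            class = "irtci_cell_score")
}

#' @export
print.irtci_cell_score <- function(x, ...) {
  cat(sprintf("imputed-cell F1 (%s): %.4f over %d cells (accuracy %.4f)\n",
              x$averaging, x$f1, x$n_cells, x$accuracy))
  print(x$per_category, row.names = FALSE)
  invisible(x)
}

#' Modal-category baseline imputation
#'
#' The reference imputer every model-based method must beat: every missing
#' cell of an item receives the item's most frequent observed category
#' (ties to the lowest code). Used by the package's own benchmarks.
#'
#' @param observed Integer vector of the item's observed (non-missing) codes.
#' @return The modal category code.
#' @export
modal_category <- function(observed) {
  observed <- observed[!is.na(observed)]
  if (!length(observed)) stop("no observed values", call. = FALSE)
  counts <- table(observed)
  as.integer(names(counts)[which.max(counts)])
}
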