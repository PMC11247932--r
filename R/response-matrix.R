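#' Response matrix
#'
#' The package's central container: an `N x n` integer matrix of category
#' codes (`0..m_i - 1` per item), with `NA` marking missing cells, plus the
#' per-item specifications. Sentinel recoding (e.g. the `-1` convention) is an
#' I/O concern handled by [read_table()]; internally missing is always `NA`.
#'
#' @param values Integer matrix (or coercible), `NA` for missing cells.
#' @param item_specs List of [item_spec()] objects, one per column.
#' @param case_ids Optional character vector of row labels.
#' @param validate If `TRUE` (default), enforce code ranges and the
#'   at-least-one-observation-per-case rule.
#' @return An object of class `irtci_response_matrix`.
#' @export
response_matrix <- function(values, item_specs, case_ids = NULL, validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (length(item_specs) != ncol(values))
    stop("need one item spec per column", call. = FALSE)
  for (j in seq_along(item_specs)) {
    if (!inherits(item_specs[[j]], "irtci_item_spec"))
      stop("item_specs must be a list of item_spec objects", call. = FALSE)
    item_specs[[j]]$item_index <- j - 1L
  }
  if (!is.null(case_ids) && length(case_ids) != nrow(values))
    stop("case_ids length must equal the number of rows", call. = FALSE)
  rm <- structure(
    list(values = values, item_specs = item_specs,
         case_ids = if (is.null(case_ids)) NULL else as.character(case_ids)),
    class = "irtci_response_matrix"
  )
  if (validate) validate_response_matrix(rm)
  rm
}

#' Validate a response matrix
#'
#' Checks that every observed code is within its item's declared range and
#' that every case has at least one observed entry.
#'
#' @param rm An `irtci_response_matrix`.
#' @return `rm`, invisibly; errors describe the first violation found.
#' @export
validate_response_matrix <- function(rm) {
  stopifnot(inherits(rm, "irtci_response_matrix"))
  v <- rm$values
  for (j in seq_len(ncol(v))) {
    obs <- v[!is.na(v[, j]), j]
    m <- rm$item_specs[[j]]$n_categories
    if (length(obs) && (min(obs) < 0L || max(obs) >= m))
      stop(sprintf("item '%s': observed codes outside 0..%d",
                   rm$item_specs[[j]]$name, m - 1L), call. = FALSE)
  }
  if (nrow(v) && any(rowSums(!is.na(v)) == 0L))
    stop("every case must have at least one observed entry", call. = FALSE)
  invisible(rm)
}

#' @export
print.irtci_response_matrix <- function(x, ...) {
  fam <- vapply(x$item_specs, `[[`, "", "family")
  cat(sprintf("irtci response matrix: %d cases x %d items (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("  families:", paste(sprintf("%s(%d)", fam,
      vapply(x$item_specs, `[[`, 0L, "n_categories")), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.irtci_response_matrix <- function(x) dim(x$values)
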