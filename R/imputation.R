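#' Quantile discretization of a continuous feature
#'
#' Bins a continuous vector into `n_bins` empirical-quantile bins (quartiles
#' by default), yielding ordinal codes `0..n_bins - 1`. Intervals are
#' left-closed / right-open except the last, which is closed, so every value
#' maps to exactly one bin and the coding is order-preserving. IRT models
#' categorical responses only, so continuous features pass through here
#' before fitting.
#'
#' @param values Numeric vector; `NA`s are carried through as `NA` codes.
#' @param n_bins Number of bins (>= 2). Default 4 (quartiles).
#' @return List with `codes` (integer vector) and `map` (class
#'   `irtci_discretization`: `edges`, inner cut points flanked by -Inf/Inf,
#'   and `n_bins`).
#' @export
discretize_continuous <- function(values, n_bins = 4L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < n_bins)
    stop(sprintf("need at least %d distinct values to form %d bins",
                 n_bins, n_bins), call. = FALSE)
  cuts <- stats::quantile(obs, probs = seq_len(n_bins - 1L) / n_bins,
                          names = FALSE, type = 7)
  if (any(diff(cuts) <= 0))
    stop("degenerate feature: quantile cut points are not distinct", call. = FALSE)
  edges <- c(-Inf, cuts, Inf)
  codes <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  # left-closed/right-open: x in [edge_k, edge_{k+1}) -> code k-1
  codes[ok] <- as.integer(findInterval(values[ok], edges,
                                       rightmost.closed = TRUE) - 1L)
  map <- structure(list(edges = edges, n_bins = n_bins),
                   class = "irtci_discretization")
  list(codes = codes, map = map)
}

#' Apply a stored discretization map to new values
#'
#' @param values Numeric vector.
#' @param map An `irtci_discretization` from [discretize_continuous()].
#' @return Integer codes `0..n_bins - 1` (`NA` preserved).
#' @export
apply_discretization <- function(values, map) {
  stopifnot(inherits(map, "irtci_discretization"))
  codes <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  codes[ok] <- as.integer(findInterval(values[ok], map$edges,
                                       rightmost.closed = TRUE) - 1L)
  pmin(pmax(codes, 0L), map$n_bins - 1L)
}

#' Impute a single cell from a fitted model
#'
#' Evaluates the item's category probabilities at the case's EAP theta (or,
#' optionally, integrates them over the case's full posterior) and picks the
#' most probable category. For a binary item the argmax reproduces the
#' 50-percent threshold rule exactly; ties go to the lowest category index.
#'
#' @param fitted An [fit_irt()] object.
#' @param item_index 1-based column index of the item to impute.
#' @param theta An [eap_theta()] result for the case.
#' @param posterior If `TRUE`, average the category probabilities over the
#'   case's posterior on the grid instead of plugging in the EAP point.
#'   Default `FALSE` (point-EAP).
#' @return List with `category` (integer code) and `probs` (the vector used).
#' @export
impute_cell <- function(fitted, item_index, theta, posterior = FALSE) {
  stopifnot(inherits(fitted, "irtci_fit"))
  item_index <- as.integer(item_index)
  if (item_index < 1L || item_index > length(fitted$item_params))
    stop("'item_index' out of range", call. = FALSE)
  p <- if (posterior) {
    P <- .prob_matrix(fitted$grid$nodes, fitted$item_params[[item_index]])
    as.vector(crossprod(P, theta$posterior))
  } else {
    category_probs(theta$eap_mean, fitted$item_params[[item_index]])
  }
  p <- p / sum(p)
  list(category = as.integer(which.max(p) - 1L), probs = p)
}

#' IRT-based categorical imputation (IRTCI)
#'
#' The full pipeline: fit one unidimensional IRT model on all feature columns
#' of the response matrix (declared outcome columns are excluded, so the
#' imputation can never leak the outcome), score each case's theta by EAP
#' from its observed entries, and replace every missing cell with the most
#' probable category of its item at that theta. Deterministic end to end.
#'
#' @param responses An [response_matrix()] object (missing cells are `NA`).
#' @param outcome Optional integer/character vector naming outcome columns to
#'   exclude from fitting and imputation.
#' @param posterior Passed to [impute_cell()]; default `FALSE` (point-EAP).
#' @param n_nodes,bound,tol,max_cycles Passed to [fit_irt()].
#' @return An object of class `irtci_imputation`: `completed` (integer matrix
#'   with no missing cells in the modelled columns), `cells` (data.frame of
#'   per-imputed-cell records: case, item, chosen category, EAP used),
#'   `probs` (list of probability vectors aligned to `cells`), `fit`,
#'   and `theta` (per-case EAP summaries).
#' @export
irtci_impute <- function(responses, outcome = NULL, posterior = FALSE,
                         n_nodes = 41L, bound = 6, tol = 1e-4,
                         max_cycles = 500L) {
  stopifnot(inherits(responses, "irtci_response_matrix"))
  v <- responses$values
  item_names <- vapply(responses$item_specs, `[[`, "", "name")
  cols <- seq_len(ncol(v))
  if (!is.null(outcome)) {
    out_idx <- if (is.character(outcome)) match(outcome, item_names) else as.integer(outcome)
    if (anyNA(out_idx) || any(out_idx < 1L | out_idx > ncol(v)))
      stop("unknown outcome column", call. = FALSE)
    cols <- setdiff(cols, out_idx)
  }
  feat <- response_matrix(v[, cols, drop = FALSE],
                          responses$item_specs[cols],
                          responses$case_ids, validate = TRUE)
  fit <- fit_irt(feat, n_nodes = n_nodes, bound = bound, tol = tol,
                 max_cycles = max_cycles)
  fv <- fit$values  # post-collapse codes

  N <- nrow(fv)
  eap <- vector("list", N)
  theta_tab <- data.frame(case = seq_len(N), eap_mean = NA_real_, eap_sd = NA_real_)
  for (i in seq_len(N)) {
    eap[[i]] <- eap_theta(fv[i, ], fit)
    theta_tab$eap_mean[i] <- eap[[i]]$eap_mean
    theta_tab$eap_sd[i] <- eap[[i]]$eap_sd
  }

  completed <- v
  miss <- which(is.na(fv), arr.ind = TRUE)
  cells <- data.frame(case = integer(0), item = integer(0),
                      item_name = character(0), category = integer(0),
                      eap_mean = numeric(0))
  probs <- list()
  if (nrow(miss)) {
    ord <- order(miss[, "row"], miss[, "col"])
    miss <- miss[ord, , drop = FALSE]
    for (k in seq_len(nrow(miss))) {
      i <- miss[k, "row"]; j <- miss[k, "col"]
      cell <- impute_cell(fit, j, eap[[i]], posterior = posterior)
      code <- cell$category
      # decode collapsed categories back to the declared coding
      if (!is.null(fit$remaps[[j]])) code <- fit$remaps[[j]][code + 1L]
      completed[i, cols[j]] <- code
      cells <- rbind(cells, data.frame(
        case = i, item = cols[j], item_name = item_names[cols[j]],
        category = code, eap_mean = eap[[i]]$eap_mean))
      probs[[k]] <- cell$probs
    }
  }
  rownames(cells) <- NULL
  structure(list(completed = completed, cells = cells, probs = probs,
                 fit = fit, theta = theta_tab, feature_cols = cols),
            class = "irtci_imputation")
}

#' @export
print.irtci_imputation <- function(x, ...) {
  cat(sprintf("irtci imputation: %d cells imputed across %d items\n",
              nrow(x$cells), length(unique(x$cells$item))))
  invisible(x)
}
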