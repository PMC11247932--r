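#' MCAR amputation of a complete column
#'
#' Sets exactly `round(fraction * N)` cells of one column to `NA`, chosen
#' uniformly without replacement. Reproducible per seed; no other cell is
#' touched.
#'
#' @param table A data.frame.
#' @param target_col Column name or index to ampute; must be complete.
#' @param fraction Fraction of rows to make missing, in (0, 1).
#' @param seed Integer seed.
#' @return The table with missing cells, plus attribute `"miss_rows"` (the
#'   row indices amputed).
#' @export
ampute_mcar <- function(table, target_col, fraction, seed = 1L) {
  stopifnot(is.data.frame(table))
  j <- .resolve_col(table, target_col)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  if (anyNA(table[[j]]))
    stop("target column already contains missing values", call. = FALSE)
  n_miss <- round(fraction * nrow(table))
  rows <- local_rng(seed, sample.int(nrow(table), n_miss))
  table[rows, j] <- NA
  attr(table, "miss_rows") <- sort(rows)
  table
}

#' MAR amputation by sorting on a conditional variable
#'
#' Stably sorts the table on a complete conditional column (descending by
#' default, so cases with large conditional values lose their data), sets the
#' target column to `NA` in the first `round(fraction * N)` rows, and restores
#' the original row order. Deterministic: no randomness is involved.
#'
#' @param table A data.frame.
#' @param target_col Column to ampute.
#' @param conditional_col Complete, ordered-comparable column driving the
#'   missingness.
#' @param fraction Fraction of rows to make missing, in (0, 1).
#' @param direction `"desc"` (default) removes from the top of the descending
#'   sort; `"asc"` from the ascending sort.
#' @return The table with missing cells, plus attribute `"miss_rows"`.
#' @export
ampute_mar <- function(table, target_col, conditional_col, fraction,
                       direction = c("desc", "asc")) {
  stopifnot(is.data.frame(table))
  direction <- match.arg(direction)
  j <- .resolve_col(table, target_col)
  cj <- .resolve_col(table, conditional_col)
  cond <- table[[cj]]
  if (anyNA(cond)) stop("conditional column must be complete", call. = FALSE)
  if (!(is.numeric(cond) || is.ordered(cond) || is.character(cond) ||
        is.logical(cond)))
    stop("conditional column is not ordered-comparable", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("'fraction' must be in [0, 1)", call. = FALSE)
  n_miss <- round(fraction * nrow(table))
  ord <- order(cond, decreasing = (direction == "desc"), method = "radix")
  rows <- ord[seq_len(n_miss)]
  if (n_miss > 0L) table[rows, j] <- NA
  attr(table, "miss_rows") <- sort(rows)
  table
}

.resolve_col <- function(table, col) {
  j <- if (is.character(col)) match(col, names(table)) else as.integer(col)
  if (is.na(j) || j < 1L || j > ncol(table))
    stop(sprintf("unknown column '%s'", as.character(col)), call. = FALSE)
  j
}

# ---- EM for multivariate-normal mean/covariance with missing data ----------
# Grouped by missingness pattern; returns ML estimates (divide by N).

.em_norm <- function(Y, tol = 1e-6, max_iter = 200L) {
  N <- nrow(Y); p <- ncol(Y)
  R <- !is.na(Y)
  # start from available-case moments, ridge if needed
  mu <- colMeans(Y, na.rm = TRUE)
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S)[!is.finite(diag(S)) | diag(S) <= 0] <- 1
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    S <- S + diag(1e-8 * max(diag(S)), p)

  pat_key <- apply(R, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(N), pat_key)

  for (iter in seq_len(max_iter)) {
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    for (rows in pats) {
      obs <- R[rows[1L], ]
      Yo <- Y[rows, obs, drop = FALSE]
      n_j <- length(rows)
      if (all(obs)) {
        sum_y <- sum_y + colSums(Yo)
        sum_yy <- sum_yy + crossprod(Yo)
        next
      }
      mis <- !obs
      Soo <- S[obs, obs, drop = FALSE]
      Smo <- S[mis, obs, drop = FALSE]
      B <- Smo %*% solve(Soo)
      resid <- sweep(Yo, 2L, mu[obs])
      Em <- matrix(mu[mis], n_j, sum(mis), byrow = TRUE) + resid %*% t(B)
      Cm <- S[mis, mis, drop = FALSE] - B %*% t(Smo)  # conditional covariance
      full <- matrix(0, n_j, p)
      full[, obs] <- Yo
      full[, mis] <- Em
      sum_y <- sum_y + colSums(full)
      cp <- crossprod(full)
      cp[mis, mis] <- cp[mis, mis, drop = FALSE] + n_j * Cm
      sum_yy <- sum_yy + cp
    }
    mu_new <- sum_y / N
    S_new <- sum_yy / N - tcrossprod(mu_new)
    S_new <- (S_new + t(S_new)) / 2
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new; S <- S_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = S)
}

#' Little's MCAR test
#'
#' Chi-square test of the missing-completely-at-random assumption. Rows are
#' grouped by missingness pattern; EM estimates of the grand mean and
#' covariance (assuming multivariate normality) are computed; the statistic
#' sums, over patterns, `n_j (ybar_obs_j - mu_j)' Sigma_j^{-1}
#' (ybar_obs_j - mu_j)` restricted to each pattern's observed variables, and
#' is referred to a chi-square with `sum_j p_j - p` degrees of freedom.
#' A significant result indicates systematic (non-MCAR) missingness.
#'
#' Categorical columns must be numerically coded before testing; the
#' multivariate-normal working model is then an approximation.
#'
#' @param table A data.frame of numeric (or numerically coded) columns.
#' @param tol,max_iter EM settings for the grand mean/covariance.
#' @return An object of class `irtci_mcar_test`: `statistic`, `df`,
#'   `p_value`, `n_patterns`, and `applicable` (`FALSE` when the data are
#'   complete, in which case `df = 0` and `p_value = 1`).
#' @export
littles_test <- function(table, tol = 1e-6, max_iter = 200L) {
  stopifnot(is.data.frame(table))
  Y <- as.matrix(table)
  if (!is.numeric(Y))
    stop("all columns must be numeric or numerically coded", call. = FALSE)
  # drop rows with nothing observed: they carry no information about means
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  N <- nrow(Y); p <- ncol(Y)
  R <- !is.na(Y)
  pat_key <- apply(R, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(N), pat_key)
  n_patterns <- length(pats)

  if (n_patterns == 1L && all(R[1L, ])) {
    return(structure(list(statistic = 0, df = 0L, p_value = 1,
                          n_patterns = 1L, applicable = FALSE),
                     class = "irtci_mcar_test"))
  }

  est <- .em_norm(Y, tol = tol, max_iter = max_iter)
  d2 <- 0
  sum_pj <- 0L
  for (key in names(pats)) {
    rows <- pats[[key]]
    obs <- R[rows[1L], ]
    p_j <- sum(obs)
    sum_pj <- sum_pj + p_j
    ybar <- colMeans(Y[rows, obs, drop = FALSE])
    diff <- ybar - est$mu[obs]
    Sj <- est$sigma[obs, obs, drop = FALSE]
    qf <- tryCatch(sum(diff * solve(Sj, diff)), error = function(e)
      stop(sprintf("singular covariance for missingness pattern '%s'", key),
           call. = FALSE))
    d2 <- d2 + length(rows) * qf
  }
  df <- sum_pj - p
  p_value <- if (df > 0L) stats::pchisq(d2, df, lower.tail = FALSE) else 1
  structure(list(statistic = d2, df = as.integer(df), p_value = p_value,
                 n_patterns = n_patterns, applicable = df > 0L),
            class = "irtci_mcar_test")
}

#' @export
print.irtci_mcar_test <- function(x, ...) {
  cat(sprintf("Little's MCAR test: chi2 = %.3f, df = %d, p = %.4g (%d patterns)\n",
              x$statistic, x$df, x$p_value, x$n_patterns))
  if (!x$applicable) cat("  (not applicable: no testable missingness)\n")
  invisible(x)
}
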