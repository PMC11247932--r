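#' Item specification
#'
#' Describes one categorical feature (an "item" in IRT terminology): which
#' model family links it to the latent trait, and how many response
#' categories it has. Category codes are always the consecutive integers
#' `0..n_categories-1`.
#'
#' @param name Character label for the item.
#' @param family One of `"binary_2pl"`, `"ordinal_grm"`, `"nominal_nrm"`.
#' @param n_categories Integer number of response categories (>= 2; exactly 2
#'   for `binary_2pl`).
#' @param item_index Optional zero-based position of the item in its matrix.
#' @return An object of class `irtci_item_spec`.
#' @export
item_spec <- function(name, family, n_categories, item_index = 0L) {
  family <- match.arg(family, c("binary_2pl", "ordinal_grm", "nominal_nrm"))
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L)
    stop("'n_categories' must be an integer >= 2", call. = FALSE)
  if (family == "binary_2pl" && n_categories != 2L)
    stop("a 'binary_2pl' item must have exactly 2 categories", call. = FALSE)
  structure(
    list(name = as.character(name), family = family,
         n_categories = n_categories, item_index = as.integer(item_index)),
    class = "irtci_item_spec"
  )
}

#' Two-parameter logistic item parameters
#'
#' @param a Discrimination (slope), must be > 0. Logistic metric: no 1.7
#'   scaling constant is applied anywhere in this package.
#' @param b Difficulty (threshold), in theta units.
#' @return An object of class `irtci_params_2pl`.
#' @export
params_2pl <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("2-PL discrimination 'a' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("2-PL difficulty 'b' must be a single finite value", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = c("irtci_params_2pl", "irtci_params"))
}

#' Graded response model item parameters
#'
#' One shared slope and `m - 1` strictly increasing boundary thresholds for an
#' item with `m` ordered categories. Unordered thresholds are an error, never
#' silently reordered: the estimator is responsible for maintaining ordering.
#'
#' @param a Shared discrimination, > 0.
#' @param b Numeric vector of thresholds, strictly increasing.
#' @return An object of class `irtci_params_grm`.
#' @export
params_grm <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("GRM discrimination 'a' must be a single finite value > 0", call. = FALSE)
  b <- as.numeric(b)
  if (length(b) < 1L || anyNA(b) || any(!is.finite(b)))
    stop("GRM thresholds 'b' must be finite", call. = FALSE)
  if (length(b) > 1L && any(diff(b) <= 0))
    stop("GRM thresholds must be strictly increasing", call. = FALSE)
  structure(list(a = as.numeric(a), b = b),
            class = c("irtci_params_grm", "irtci_params"))
}

#' Nominal response model item parameters
#'
#' Per-category slopes and intercepts for a divide-by-total (softmax) item.
#' Identification fixes the lowest category: `a[1] = c[1] = 0`.
#'
#' @param a_vec Numeric vector of category slopes; first element must be 0.
#' @param c_vec Numeric vector of category intercepts; first element must be 0.
#' @return An object of class `irtci_params_nrm`.
#' @export
params_nrm <- function(a_vec, c_vec) {
  a_vec <- as.numeric(a_vec); c_vec <- as.numeric(c_vec)
  if (length(a_vec) != length(c_vec))
    stop("NRM 'a_vec' and 'c_vec' must have the same length", call. = FALSE)
  if (length(a_vec) < 2L)
    stop("NRM items need at least 2 categories", call. = FALSE)
  if (anyNA(a_vec) || anyNA(c_vec) || any(!is.finite(c(a_vec, c_vec))))
    stop("NRM parameters must be finite", call. = FALSE)
  if (a_vec[1L] != 0 || c_vec[1L] != 0)
    stop("NRM identification requires a_vec[1] = c_vec[1] = 0", call. = FALSE)
  structure(list(a = a_vec, c = c_vec),
            class = c("irtci_params_nrm", "irtci_params"))
}

# logistic with overflow guard; exact 0/1 at the extremes is acceptable
# downstream because likelihood factors are clamped there.
.sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

.check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) < 1L || anyNA(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric", call. = FALSE)
  as.numeric(theta)
}

#' 2-PL success probability
#'
#' Probability of the "1" response under the two-parameter logistic model,
#' `P(U = 1 | theta) = exp(a (theta - b)) / (1 + exp(a (theta - b)))`.
#'
#' @param theta Latent trait value(s); finite numeric vector.
#' @param params An [params_2pl()] object.
#' @return Numeric vector of probabilities in `[0, 1]`, same length as `theta`.
#' @export
prob_2pl <- function(theta, params) {
  stopifnot(inherits(params, "irtci_params_2pl"))
  theta <- .check_theta(theta)
  .sigmoid(params$a * (theta - params$b))
}

#' GRM boundary (cumulative) probabilities
#'
#' Element `k` is `P*(U >= k | theta)`, a 2-PL curve at threshold `b[k]` with
#' the item's shared slope. The implicit bounds `P*(U >= 0) = 1` and
#' `P*(U >= m) = 0` are not returned.
#'
#' @param theta Single latent trait value.
#' @param params An [params_grm()] object.
#' @return Numeric vector of length `m - 1`, strictly decreasing in `k`.
#' @export
grm_boundary_probs <- function(theta, params) {
  stopifnot(inherits(params, "irtci_params_grm"))
  theta <- .check_theta(theta)
  if (length(theta) != 1L) stop("'theta' must be a single value", call. = FALSE)
  .sigmoid(params$a * (theta - params$b))
}

#' GRM category probabilities
#'
#' Adjacent differences of the boundary curves: `P(U = k) =
#' P*(U >= k) - P*(U >= k + 1)` with `P*(U >= 0) = 1` and `P*(U >= m) = 0`.
#'
#' @inheritParams grm_boundary_probs
#' @return Numeric vector of length `m`; nonnegative, sums to 1.
#' @export
grm_category_probs <- function(theta, params) {
  bp <- grm_boundary_probs(theta, params)
  p <- -diff(c(1, bp, 0))
  # adjacent sigmoids of an ordered item can differ by < eps; clamp rounding
  pmax(p, 0)
}

#' NRM category probabilities
#'
#' Divide-by-total (softmax) probabilities `P(U = k) = exp(a_k theta + c_k) /
#' sum_x exp(a_x theta + c_x)`, evaluated with a max-subtraction guard so that
#' logits up to +/-700 do not overflow.
#'
#' @param theta Single latent trait value.
#' @param params An [params_nrm()] object.
#' @return Numeric vector of length `m`; positive, sums to 1.
#' @export
nrm_category_probs <- function(theta, params) {
  stopifnot(inherits(params, "irtci_params_nrm"))
  theta <- .check_theta(theta)
  if (length(theta) != 1L) stop("'theta' must be a single value", call. = FALSE)
  z <- params$a * theta + params$c
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

#' Category probabilities for any item family
#'
#' Dispatches on the parameter class: binary items return `(P(0), P(1))`,
#' ordinal items the GRM category vector, nominal items the NRM softmax.
#'
#' @param theta Single latent trait value.
#' @param params A `irtci_params_*` object.
#' @return Numeric probability vector over the item's categories.
#' @export
category_probs <- function(theta, params) {
  if (inherits(params, "irtci_params_2pl")) {
    p1 <- prob_2pl(theta, params)
    c(1 - p1, p1)
  } else if (inherits(params, "irtci_params_grm")) {
    grm_category_probs(theta, params)
  } else if (inherits(params, "irtci_params_nrm")) {
    nrm_category_probs(theta, params)
  } else {
    stop("unknown item parameter class", call. = FALSE)
  }
}

# probability matrix over a node vector: n_nodes x m. Vectorized over nodes;
# used by the EM inner loop, so kept allocation-light.
.prob_matrix <- function(nodes, params) {
  if (inherits(params, "irtci_params_2pl")) {
    p1 <- .sigmoid(params$a * (nodes - params$b))
    cbind(1 - p1, p1, deparse.level = 0)
  } else if (inherits(params, "irtci_params_grm")) {
    bp <- vapply(params$b, function(bk) .sigmoid(params$a * (nodes - bk)),
                 numeric(length(nodes)))
    bp <- matrix(bp, nrow = length(nodes))
    cum <- cbind(1, bp, 0, deparse.level = 0)
    p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE]
    pmax(p, 1e-300)
  } else if (inherits(params, "irtci_params_nrm")) {
    z <- outer(nodes, params$a) + rep(params$c, each = length(nodes))
    z <- z - apply(z, 1L, max)
    ez <- exp(z)
    ez / rowSums(ez)
  } else stop("unknown item parameter class", call. = FALSE)
}
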