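#' Simulate a response matrix from known item parameters
#'
#' Draws each case's latent trait from a standard normal (or takes a supplied
#' vector) and samples every cell from its item's category distribution at
#' that trait value. This is the ground-truth generator used throughout the
#' package's parameter-recovery and imputation-accuracy tests.
#'
#' Randomness is scoped: the global `.Random.seed` is saved and restored, so
#' simulation never perturbs, and is never perturbed by, surrounding code.
#'
#' @param item_params List of `irtci_params_*` objects (any mix of families).
#' @param n_cases Number of cases to draw (ignored if `theta` is supplied).
#' @param theta Optional numeric vector of latent trait values.
#' @param seed Integer seed fixing all randomness of the run.
#' @param names Optional character vector of item names.
#' @return List with `responses` (an [response_matrix()]) and `theta` (the
#'   trait values actually used).
#' @export
simulate_responses <- function(item_params, n_cases = NULL, theta = NULL,
                               seed = 1L, names = NULL) {
  if (is.null(theta) && is.null(n_cases))
    stop("supply 'n_cases' or 'theta'", call. = FALSE)
  n_items <- length(item_params)
  if (is.null(names))
    names <- paste0("item", seq_len(n_items))
  specs <- lapply(seq_len(n_items), function(j) {
    p <- item_params[[j]]
    if (inherits(p, "irtci_params_2pl"))
      item_spec(names[j], "binary_2pl", 2L, j - 1L)
    else if (inherits(p, "irtci_params_grm"))
      item_spec(names[j], "ordinal_grm", length(p$b) + 1L, j - 1L)
    else if (inherits(p, "irtci_params_nrm"))
      item_spec(names[j], "nominal_nrm", length(p$a), j - 1L)
    else stop("unknown item parameter class", call. = FALSE)
  })

  out <- local_rng(seed, {
    th <- if (is.null(theta)) stats::rnorm(n_cases) else as.numeric(theta)
    N <- length(th)
    v <- matrix(NA_integer_, N, n_items)
    for (j in seq_len(n_items)) {
      m <- specs[[j]]$n_categories
      P <- .prob_matrix(th, item_params[[j]])        # N x m
      cum <- t(apply(P, 1L, cumsum))
      u <- stats::runif(N)
      v[, j] <- as.integer(pmin(rowSums(u > cum), m - 1L))  # boundaries passed
    }
    list(v = v, th = th)
  })

  list(responses = response_matrix(out$v, specs, validate = FALSE),
       theta = out$th)
}

#' Evaluate code with a private RNG stream
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
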