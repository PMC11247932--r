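#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes on `[-bound, bound]` with weights proportional to the
#' standard-normal density, renormalized to sum to one. This discretizes the
#' standard-normal prior that identifies the latent scale.
#'
#' @param n_nodes Number of nodes (>= 11). Default 41.
#' @param bound Half-width of the grid in theta units. Default 6.
#' @return An object of class `irtci_grid` with `nodes` and `weights`.
#' @export
make_grid <- function(n_nodes = 41L, bound = 6) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 11L)
    stop("'n_nodes' must be >= 11", call. = FALSE)
  if (!is.numeric(bound) || length(bound) != 1L || !is.finite(bound) || bound <= 0)
    stop("'bound' must be a single positive value", call. = FALSE)
  nodes <- seq(-bound, bound, length.out = n_nodes)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "irtci_grid")
}

#' Likelihood of one case at every grid node
#'
#' For each node `theta_q`, the product over the case's OBSERVED items of the
#' probability of the observed category. Missing items contribute a factor of
#' one (they are marginalized out), so an all-missing row returns a vector of
#' ones and its posterior is the prior.
#'
#' @param row Integer vector of category codes for one case (`NA` = missing).
#' @param item_params List of `irtci_params_*` objects, one per item.
#' @param grid An [make_grid()] object.
#' @return Numeric vector over nodes, all entries > 0.
#' @export
case_likelihood_at_nodes <- function(row, item_params, grid) {
  stopifnot(inherits(grid, "irtci_grid"))
  if (length(row) != length(item_params))
    stop("row length must match the number of items", call. = FALSE)
  L <- rep(1, length(grid$nodes))
  for (i in seq_along(row)) {
    if (is.na(row[i])) next
    P <- .prob_matrix(grid$nodes, item_params[[i]])
    L <- L * pmax(P[, row[i] + 1L], 1e-300)
  }
  L
}

# ---- starting values -------------------------------------------------------

.start_params <- function(u, spec) {
  obs <- u[!is.na(u)]
  m <- spec$n_categories
  prop <- tabulate(obs + 1L, nbins = m) / length(obs)
  prop <- pmin(pmax(prop, 1e-3), 1 - 1e-3)
  switch(spec$family,
    binary_2pl = params_2pl(a = 1, b = stats::qnorm(prop[1L] / sum(prop[1:2]))),
    ordinal_grm = {
      cum <- cumsum(prop)[-m] / sum(prop)
      b <- stats::qnorm(pmin(pmax(cum, 1e-3), 1 - 1e-3))
      # enforce strict ordering on ties from near-empty categories
      for (k in seq_along(b)[-1]) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 0.05
      params_grm(a = 1, b = b)
    },
    nominal_nrm = {
      cvec <- log(prop / prop[1L])
      # slopes start at small increasing values, not all zero: the all-zero
      # slope configuration is an exact EM fixed point (flat likelihood in
      # theta makes every posterior equal the prior), a saddle the algorithm
      # would never leave in a pure-NRM fit
      params_nrm(a_vec = 0.25 * (seq_len(m) - 1L), c_vec = cvec - cvec[1L])
    })
}

# ---- M-step objective: expected complete-data log-likelihood ---------------
# r: n_nodes x m expected counts; nodes: grid nodes. Each family is optimized
# in an unconstrained parameterization so optim() never leaves the valid set.

.pack <- function(params) {
  if (inherits(params, "irtci_params_2pl")) c(log(params$a), params$b)
  else if (inherits(params, "irtci_params_grm")) {
    b <- params$b
    if (length(b) == 1L) c(log(params$a), b)
    else c(log(params$a), b[1L], log(diff(b)))
  } else {
    m <- length(params$a)
    c(params$a[-1L], params$c[-1L])
  }
}

.unpack <- function(x, family, m) {
  switch(family,
    binary_2pl = params_2pl(a = exp(x[1L]), b = x[2L]),
    ordinal_grm = {
      if (m == 2L) params_grm(a = exp(x[1L]), b = x[2L])
      else params_grm(a = exp(x[1L]), b = x[2L] + c(0, cumsum(exp(x[-(1:2)]))))
    },
    nominal_nrm = params_nrm(a_vec = c(0, x[seq_len(m - 1L)]),
                             c_vec = c(0, x[m - 1L + seq_len(m - 1L)])))
}

.q_value <- function(x, family, m, r, nodes) {
  p <- tryCatch(.unpack(x, family, m), error = function(e) NULL)
  if (is.null(p)) return(1e10)
  P <- .prob_matrix(nodes, p)
  -sum(r * log(pmax(P, 1e-300)))
}

# analytic gradients for 2-PL and NRM keep the M-step cheap; GRM uses optim's
# numeric gradient (few parameters, cheap objective).
.q_grad <- function(x, family, m, r, nodes) {
  if (family == "binary_2pl") {
    a <- exp(x[1L]); b <- x[2L]
    p1 <- .sigmoid(a * (nodes - b))
    n_q <- rowSums(r)
    resid <- r[, 2L] - n_q * p1
    -c(sum(resid * (nodes - b)) * a, -a * sum(resid))
  } else if (family == "nominal_nrm") {
    p <- .unpack(x, family, m)
    P <- .prob_matrix(nodes, p)
    n_q <- rowSums(r)
    resid <- r - n_q * P            # n_nodes x m
    ga <- colSums(resid * nodes)[-1L]
    gc <- colSums(resid)[-1L]
    -c(ga, gc)
  } else NULL
}

.mstep_item <- function(params, spec, r, nodes) {
  # normalize the expected counts: the argmax is unchanged and the objective
  # becomes invariant to duplicating cases, so BFGS follows an identical path
  r <- r / sum(r)
  x0 <- .pack(params)
  fam <- spec$family
  m <- spec$n_categories
  gr <- if (fam %in% c("binary_2pl", "nominal_nrm")) .q_grad else NULL
  old <- .q_value(x0, fam, m, r, nodes)
  fit <- tryCatch(
    stats::optim(x0, .q_value, gr = gr, family = fam, m = m, r = r,
                 nodes = nodes, method = "BFGS",
                 control = list(maxit = 100, reltol = 1e-10)),
    error = function(e) NULL)
  # generalized EM: accept only improvements so the marginal likelihood is
  # monotone even when BFGS stalls
  if (is.null(fit) || fit$value > old) return(params)
  .unpack(fit$par, fam, m)
}

# ---- EM driver -------------------------------------------------------------

#' Fit IRT item parameters by marginal maximum likelihood
#'
#' Bock-Aitkin EM over a fixed quadrature grid with a standard-normal prior:
#' the E-step computes each case's posterior weights over the nodes, the
#' M-step maximizes each item's expected complete-data log-likelihood by
#' quasi-Newton ascent (a generalized EM step: an update is kept only if it
#' improves, so the marginal log-likelihood never decreases). Missing cells
#' simply drop out of each case's likelihood product. Fully deterministic.
#'
#' Items observed in fewer categories than declared are collapsed to the
#' observed codes (with a warning); the remap is recorded in `$remaps` so
#' imputations can be decoded back to the declared codes.
#'
#' @param responses An [response_matrix()] object.
#' @param n_nodes,bound Quadrature grid settings (see [make_grid()]).
#' @param tol Convergence tolerance on the maximum absolute parameter change
#'   between EM cycles. Default `1e-4`.
#' @param max_cycles Maximum EM cycles. Default 500; on hitting it the
#'   best-so-far parameters are returned with `converged = FALSE` and a
#'   warning.
#' @return An object of class `irtci_fit`: `item_params`, `item_specs`,
#'   `grid`, `log_likelihood` (marginal, final), `loglik_trace`,
#'   `n_em_cycles`, `converged`, `remaps`.
#' @export
fit_irt <- function(responses, n_nodes = 41L, bound = 6, tol = 1e-4,
                    max_cycles = 500L) {
  stopifnot(inherits(responses, "irtci_response_matrix"))
  validate_response_matrix(responses)
  v <- responses$values
  specs <- responses$item_specs
  n_items <- ncol(v)

  # collapse under-observed items to their observed category set
  remaps <- vector("list", n_items)
  for (j in seq_len(n_items)) {
    obs_codes <- sort(unique(v[!is.na(v[, j]), j]))
    if (length(obs_codes) < 2L)
      stop(sprintf("item '%s' has fewer than 2 observed categories",
                   specs[[j]]$name), call. = FALSE)
    if (length(obs_codes) < specs[[j]]$n_categories ||
        max(obs_codes) >= specs[[j]]$n_categories) {
      warning(sprintf("item '%s': collapsing %d declared to %d observed categories",
                      specs[[j]]$name, specs[[j]]$n_categories,
                      length(obs_codes)), call. = FALSE)
      remap <- match(v[, j], obs_codes) - 1L
      v[, j] <- as.integer(remap)
      remaps[[j]] <- obs_codes  # position k (0-based k-1) maps back to obs_codes[k]
      specs[[j]]$n_categories <- length(obs_codes)
      if (specs[[j]]$family == "binary_2pl" && length(obs_codes) != 2L)
        specs[[j]]$family <- "ordinal_grm"
    }
  }

  grid <- make_grid(n_nodes, bound)
  nodes <- grid$nodes
  Q <- length(nodes)
  N <- nrow(v)

  params <- lapply(seq_len(n_items), function(j) .start_params(v[, j], specs[[j]]))

  # per-item response indicators, precomputed once
  obs_idx <- lapply(seq_len(n_items), function(j) which(!is.na(v[, j])))
  resp <- lapply(seq_len(n_items), function(j) v[obs_idx[[j]], j] + 1L)

  loglik_trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    # E-step: case likelihood matrix L (N x Q)
    L <- matrix(1, N, Q)
    Pmats <- lapply(params, .prob_matrix, nodes = nodes)
    for (j in seq_len(n_items)) {
      Pj <- pmax(Pmats[[j]], 1e-300)
      L[obs_idx[[j]], ] <- L[obs_idx[[j]], , drop = FALSE] *
        t(Pj)[resp[[j]], , drop = FALSE]
    }
    marg <- as.vector(L %*% grid$weights)
    loglik_trace <- c(loglik_trace, sum(log(marg)))
    W <- L * rep(grid$weights, each = N)
    W <- W / rowSums(W)

    # M-step per item
    new_params <- params
    for (j in seq_len(n_items)) {
      m <- specs[[j]]$n_categories
      Wj <- W[obs_idx[[j]], , drop = FALSE]
      r <- matrix(0, Q, m)
      for (k in seq_len(m)) {
        sel <- resp[[j]] == k
        if (any(sel)) r[, k] <- colSums(Wj[sel, , drop = FALSE])
      }
      new_params[[j]] <- .mstep_item(params[[j]], specs[[j]], r, nodes)
    }

    delta <- max(mapply(function(p, q) max(abs(unlist(p) - unlist(q))),
                        new_params, params))
    params <- new_params
    if (delta < tol) { converged <- TRUE; break }
    if (cycles >= max_cycles) {
      warning(sprintf("EM did not converge in %d cycles (last change %.2e)",
                      max_cycles, delta), call. = FALSE)
      break
    }
  }

  # final marginal log-likelihood at the returned parameters
  L <- matrix(1, N, Q)
  for (j in seq_len(n_items)) {
    Pj <- pmax(.prob_matrix(nodes, params[[j]]), 1e-300)
    L[obs_idx[[j]], ] <- L[obs_idx[[j]], , drop = FALSE] *
      t(Pj)[resp[[j]], , drop = FALSE]
  }
  final_ll <- sum(log(as.vector(L %*% grid$weights)))
  loglik_trace <- c(loglik_trace, final_ll)

  structure(
    list(item_params = params, item_specs = specs, grid = grid,
         log_likelihood = final_ll, loglik_trace = loglik_trace,
         n_em_cycles = cycles, converged = converged, remaps = remaps,
         values = v),
    class = "irtci_fit")
}

#' @export
print.irtci_fit <- function(x, ...) {
  cat(sprintf("irtci fit: %d items, logLik = %.3f, %d EM cycles (%s)\n",
              length(x$item_params), x$log_likelihood, x$n_em_cycles,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' EAP latent-trait score for one case
#'
#' Posterior mean and standard deviation of theta on the fitted model's grid,
#' with the standard-normal prior weights. An all-missing row returns the
#' prior mean (0) and prior SD.
#'
#' @param row Integer response vector (`NA` = missing), coded like the data
#'   the model was fitted to (post-collapse codes if items were collapsed).
#' @param fitted An [fit_irt()] object.
#' @return List with `eap_mean`, `eap_sd`, and the normalized `posterior`
#'   weights over the grid nodes.
#' @export
eap_theta <- function(row, fitted) {
  stopifnot(inherits(fitted, "irtci_fit"))
  L <- case_likelihood_at_nodes(row, fitted$item_params, fitted$grid)
  w <- fitted$grid$weights * L
  w <- w / sum(w)
  mu <- sum(fitted$grid$nodes * w)
  sd <- sqrt(max(sum((fitted$grid$nodes - mu)^2 * w), 0))
  list(eap_mean = mu, eap_sd = sd, posterior = w)
}
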