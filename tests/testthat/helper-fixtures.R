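# Shared fixture builders. All randomness is seeded by the caller.

rand_params_2pl <- function() params_2pl(a = runif(1, 0.5, 2.5), b = rnorm(1))

rand_params_grm <- function(m = sample(3:6, 1)) {
  params_grm(a = runif(1, 0.5, 2.5), b = sort(rnorm(m - 1, 0, 1.5)))
}

rand_params_nrm <- function(m = sample(3:5, 1)) {
  params_nrm(a_vec = c(0, runif(m - 1, -2, 2)),
             c_vec = c(0, rnorm(m - 1, 0, 1)))
}

# battery of mixed item parameters for simulation-based tests
mixed_item_battery <- function() {
  list(params_2pl(1.4, -0.5),
       params_2pl(0.9, 0.8),
       params_grm(1.2, c(-1, 0, 1)),
       params_grm(1.8, c(-0.5, 0.7)),
       params_nrm(c(0, 0.8, -0.6), c(0, 0.3, -0.2)))
}

# Independent EAP oracle: dense trapezoid integration of the posterior using
# probabilities computed from the model formulas directly (plogis / softmax),
# NOT via the package's probability functions.
oracle_eap <- function(row, item_params, n_grid = 10001L, bound = 6) {
  th <- seq(-bound, bound, length.out = n_grid)
  logL <- rep(0, n_grid)
  for (i in seq_along(row)) {
    u <- row[i]
    if (is.na(u)) next
    p <- item_params[[i]]
    pk <- if (inherits(p, "irtci_params_2pl")) {
      p1 <- stats::plogis(p$a * (th - p$b))
      if (u == 1L) p1 else 1 - p1
    } else if (inherits(p, "irtci_params_grm")) {
      m <- length(p$b) + 1L
      upper <- if (u == m - 1L) 0 else stats::plogis(p$a * (th - p$b[u + 1L]))
      lower <- if (u == 0L) 1 else stats::plogis(p$a * (th - p$b[u]))
      lower - upper
    } else {
      ez <- exp(outer(th, p$a) + rep(p$c, each = n_grid))
      ez[, u + 1L] / rowSums(ez)
    }
    logL <- logL + log(pmax(pk, 1e-300))
  }
  dens <- exp(logL + stats::dnorm(th, log = TRUE))
  trap <- function(y) sum((y[-1] + y[-n_grid]) / 2) * (th[2] - th[1])
  z0 <- trap(dens)
  mu <- trap(th * dens) / z0
  sd <- sqrt(trap((th - mu)^2 * dens) / z0)
  list(eap_mean = mu, eap_sd = sd)
}

# wrap raw item parameters as a fit object so eap_theta / impute_cell can be
# exercised without running EM
as_fit <- function(item_params, grid = make_grid()) {
  specs <- lapply(seq_along(item_params), function(j) {
    p <- item_params[[j]]
    if (inherits(p, "irtci_params_2pl"))
      item_spec(paste0("i", j), "binary_2pl", 2L, j - 1L)
    else if (inherits(p, "irtci_params_grm"))
      item_spec(paste0("i", j), "ordinal_grm", length(p$b) + 1L, j - 1L)
    else item_spec(paste0("i", j), "nominal_nrm", length(p$a), j - 1L)
  })
  structure(list(item_params = item_params, item_specs = specs, grid = grid,
                 log_likelihood = NA_real_, loglik_trace = numeric(0),
                 n_em_cycles = 0L, converged = TRUE,
                 remaps = vector("list", length(item_params))),
            class = "irtci_fit")
}

# multivariate-normal sampler with a single correlated pair (target, cond)
mvn_table <- function(n, p = 5, rho = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (rho != 0)
    X[, 1] <- rho * X[, 2] + sqrt(1 - rho^2) * X[, 1]
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_len(p))
  df
}
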