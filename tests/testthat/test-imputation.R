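test_that("quantile discretization reproduces the hand-computed quartiles", {
  d <- discretize_continuous(1:8, n_bins = 4)
  expect_identical(d$codes, c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  # rank-based: a monotone transform gives identical codes
  d2 <- discretize_continuous(exp(1:8), n_bins = 4)
  expect_identical(d2$codes, d$codes)
  # n_bins = 2 splits at the median
  x <- c(10, 3, 7, 1, 9, 5)
  d3 <- discretize_continuous(x, n_bins = 2)
  expect_identical(d3$codes, as.integer(x > median(x)))
  # order preservation on random data
  set.seed(14)
  y <- rnorm(200)
  d4 <- discretize_continuous(y, n_bins = 4)
  expect_true(all(diff(d4$codes[order(y)]) >= 0))
  expect_equal(sort(unique(d4$codes)), 0:3)
})

test_that("discretization errors on degenerate features and keeps NAs", {
  expect_error(discretize_continuous(rep(1, 10), 4), "distinct")
  expect_error(discretize_continuous(c(1, 2, 3), 4), "distinct")
  d <- discretize_continuous(c(1:8, NA), n_bins = 4)
  expect_true(is.na(d$codes[9]))
  # stored map reapplies consistently, clamping out-of-range values
  expect_identical(apply_discretization(c(0, 4.4, 100), d$map),
                   c(0L, 1L, 3L))
})

test_that("impute_cell applies the 50% rule for binary and argmax otherwise", {
  fit <- as_fit(list(params_2pl(2, 0), params_grm(1.4, c(-1, 1)),
                     params_nrm(c(0, 1.2, -0.8), c(0, 0.5, 0.3))))
  th_hi <- list(eap_mean = 1.5, eap_sd = 0.4,
                posterior = fit$grid$weights)
  cell <- impute_cell(fit, 1, th_hi)
  expect_identical(cell$category, 1L)          # P(1) = sigmoid(3) > 0.5
  expect_equal(sum(cell$probs), 1, tolerance = 1e-12)
  th_lo <- list(eap_mean = -1.5, eap_sd = 0.4, posterior = fit$grid$weights)
  expect_identical(impute_cell(fit, 1, th_lo)$category, 0L)
  # exact tie goes to the lowest category
  th0 <- list(eap_mean = 0, eap_sd = 0.4, posterior = fit$grid$weights)
  expect_identical(impute_cell(fit, 1, th0)$category, 0L)
  # GRM argmax
  g <- impute_cell(fit, 2, th0)
  expect_identical(g$category, 1L)
  expect_equal(g$probs, grm_category_probs(0, fit$item_params[[2]]),
               tolerance = 1e-12)
  expect_error(impute_cell(fit, 9, th0), "out of range")
})

test_that("posterior-integrated probabilities average over the grid", {
  fit <- as_fit(list(params_2pl(1.5, 0)))
  w <- fit$grid$weights * dnorm(fit$grid$nodes, 1, 0.5)
  th <- list(eap_mean = sum(fit$grid$nodes * w) / sum(w), eap_sd = 0.5,
             posterior = w / sum(w))
  cell <- impute_cell(fit, 1, th, posterior = TRUE)
  manual <- sum((w / sum(w)) * prob_2pl(fit$grid$nodes, fit$item_params[[1]]))
  expect_equal(cell$probs[2], manual, tolerance = 1e-12)
})

test_that("irtci_impute completes a matrix and leaves observed cells alone", {
  ip <- list(params_grm(1.6, c(-1.2, -0.2, 0.8)), params_grm(1.2, c(-0.6, 0.9)),
             params_2pl(1.4, 0.1), params_grm(1.8, c(-0.9, 0.3, 1.1)))
  sim <- simulate_responses(ip, n_cases = 500, seed = 55)
  full <- sim$responses$values
  amp <- full
  set.seed(66)
  miss <- sample(length(amp), 120)
  amp[miss] <- NA_integer_
  # guard against a fully-missing row in the fixture
  stopifnot(all(rowSums(!is.na(amp)) > 0))
  rm <- response_matrix(amp, sim$responses$item_specs)
  res <- irtci_impute(rm)
  expect_false(anyNA(res$completed))
  expect_identical(res$completed[-miss], full[-miss])
  expect_equal(nrow(res$cells), 120L)
  for (p in res$probs) expect_equal(sum(p), 1, tolerance = 1e-10)
  # chosen category attains the maximum of its recorded vector
  for (k in seq_len(nrow(res$cells))) {
    expect_identical(res$cells$category[k],
                     as.integer(which.max(res$probs[[k]]) - 1L))
  }
})

test_that("imputing a complete matrix is the identity", {
  ip <- list(params_2pl(1.3, 0), params_grm(1.1, c(-0.5, 0.5)),
             params_2pl(1.6, -0.7))
  sim <- simulate_responses(ip, n_cases = 300, seed = 12)
  res <- irtci_impute(sim$responses)
  expect_identical(res$completed, sim$responses$values)
  expect_equal(nrow(res$cells), 0L)
})

test_that("identical observed patterns receive identical imputations", {
  ip <- list(params_2pl(1.5, -0.4), params_grm(1.3, c(-1, 0.8)),
             params_2pl(0.9, 0.6))
  sim <- simulate_responses(ip, n_cases = 400, seed = 23)
  v <- sim$responses$values
  v[1, 2] <- NA; v[2, 2] <- NA
  v[2, c(1, 3)] <- v[1, c(1, 3)]   # same observed pattern as case 1
  rm <- response_matrix(v, sim$responses$item_specs)
  res <- irtci_impute(rm)
  expect_identical(res$completed[1, 2], res$completed[2, 2])
})

test_that("a declared outcome column never influences imputations", {
  ip <- list(params_2pl(1.4, 0), params_grm(1.6, c(-0.8, 0.7)),
             params_2pl(1.1, -0.5), params_2pl(1.2, 0.9))
  sim <- simulate_responses(ip, n_cases = 400, seed = 31)
  v <- sim$responses$values
  set.seed(32)
  v[sample(400, 40), 2] <- NA
  stopifnot(all(rowSums(!is.na(v)) > 0))
  rm1 <- response_matrix(v, sim$responses$item_specs)
  res1 <- irtci_impute(rm1, outcome = 4)
  # permute the outcome column: imputations must not move
  v2 <- v
  set.seed(33)
  v2[, 4] <- v[sample(400), 4]
  rm2 <- response_matrix(v2, sim$responses$item_specs)
  res2 <- irtci_impute(rm2, outcome = 4)
  expect_identical(res1$cells$category, res2$cells$category)
  expect_identical(res1$completed[, 1:3], res2$completed[, 1:3])
  # outcome column passes through untouched
  expect_identical(res2$completed[, 4], v2[, 4])
})
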