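test_that("quadrature grid is a renormalized normal prior", {
  g <- make_grid(41, 6)
  expect_length(g$nodes, 41)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_equal(sum(g$nodes * g$weights), 0, tolerance = 1e-12)
  expect_equal(g$weights[1], g$weights[41])
  expect_true(all(diff(g$nodes) > 0))
  expect_error(make_grid(5), ">= 11")
  expect_error(make_grid(41, -1), "positive")
})

test_that("case likelihood factorizes over observed items", {
  g <- make_grid()
  ip <- mixed_item_battery()
  # all-missing row: empty product
  expect_equal(case_likelihood_at_nodes(rep(NA_integer_, 5), ip, g),
               rep(1, 41))
  # single binary item answered 1 equals the 2-PL curve at the nodes
  one <- case_likelihood_at_nodes(c(1L, NA, NA, NA, NA), ip, g)
  expect_equal(one, prob_2pl(g$nodes, ip[[1]]), tolerance = 1e-12)
  # two-item likelihood is the product of the one-item likelihoods
  r1 <- c(1L, NA, 2L, NA, NA)
  la <- case_likelihood_at_nodes(c(1L, NA, NA, NA, NA), ip, g)
  lb <- case_likelihood_at_nodes(c(NA, NA, 2L, NA, NA), ip, g)
  expect_equal(case_likelihood_at_nodes(r1, ip, g), la * lb, tolerance = 1e-12)
  expect_true(all(case_likelihood_at_nodes(r1, ip, g) > 0))
})

test_that("EAP matches a dense trapezoid oracle and handles empty rows", {
  ip <- mixed_item_battery()
  fit <- as_fit(ip)
  empty <- eap_theta(rep(NA_integer_, 5), fit)
  expect_equal(empty$eap_mean, 0, tolerance = 1e-10)
  prior_sd <- sqrt(sum(fit$grid$nodes^2 * fit$grid$weights))
  expect_equal(empty$eap_sd, prior_sd, tolerance = 1e-10)
  expect_equal(prior_sd, 1, tolerance = 0.01)

  set.seed(3)
  for (rep in 1:10) {
    row <- vapply(fit$item_specs, function(s)
      sample.int(s$n_categories, 1L) - 1L, 0L)
    est <- eap_theta(row, fit)
    orc <- oracle_eap(row, ip)
    expect_equal(est$eap_mean, orc$eap_mean, tolerance = 1e-3)
    expect_equal(est$eap_sd, orc$eap_sd, tolerance = 1e-3)
  }
})

test_that("EAP is nondecreasing in total score for an equal-slope 2-PL test", {
  ip <- lapply(c(-1.5, -0.5, 0, 0.5, 1.5), function(b) params_2pl(1.2, b))
  fit <- as_fit(ip)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  eap <- apply(patterns, 1, function(r) eap_theta(as.integer(r), fit)$eap_mean)
  score <- rowSums(patterns)
  # every pattern with a higher total score beats every lower-score pattern
  for (s in 1:5)
    expect_gt(min(eap[score == s]), max(eap[score == s - 1]))
})

test_that("MML-EM recovers 2-PL parameters from simulated data", {
  set.seed(21)
  a_true <- runif(10, 0.8, 2.2); b_true <- rnorm(10)
  ip <- mapply(params_2pl, a_true, b_true, SIMPLIFY = FALSE)
  sim <- simulate_responses(ip, n_cases = 2000, seed = 101)
  fit <- fit_irt(sim$responses)
  expect_true(fit$converged)
  a_est <- vapply(fit$item_params, `[[`, 0, "a")
  b_est <- vapply(fit$item_params, `[[`, 0, "b")
  expect_gte(cor(a_true, a_est), 0.85)
  expect_gte(cor(b_true, b_est), 0.95)
  expect_lte(sqrt(mean((b_true - b_est)^2)), 0.15)
  # EM monotonicity
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("fit is deterministic and invariant to duplicating every case", {
  set.seed(5)
  ip <- list(params_2pl(1.2, -0.3), params_grm(1.5, c(-0.8, 0.6)),
             params_nrm(c(0, 0.9, -0.7), c(0, 0.2, -0.1)))
  sim <- simulate_responses(ip, n_cases = 400, seed = 9)
  f1 <- fit_irt(sim$responses)
  f2 <- fit_irt(sim$responses)
  expect_identical(unlist(f1$item_params), unlist(f2$item_params))

  dup <- response_matrix(rbind(sim$responses$values, sim$responses$values),
                         sim$responses$item_specs)
  f3 <- fit_irt(dup)
  expect_equal(unlist(f1$item_params), unlist(f3$item_params),
               tolerance = 1e-6)
  expect_equal(f3$log_likelihood, 2 * f1$log_likelihood, tolerance = 1e-6)
})

test_that("degenerate and under-observed items are handled as specified", {
  specs <- list(item_spec("x", "binary_2pl", 2), item_spec("y", "ordinal_grm", 4))
  v <- cbind(rep(0L, 50), rep(0:1, 25))
  expect_error(fit_irt(response_matrix(v, specs)),
               "fewer than 2 observed categories")
  # declared 4 categories, only 2 observed: collapse with a warning
  set.seed(8)
  v2 <- cbind(sample(0:1, 200, TRUE), sample(c(0L, 2L), 200, TRUE))
  expect_warning(fit <- fit_irt(response_matrix(v2, specs, validate = FALSE)),
                 "collapsing")
  expect_equal(fit$remaps[[2]], c(0L, 2L))
  expect_equal(fit$item_specs[[2]]$n_categories, 2L)
})

test_that("response matrix validation enforces its invariants", {
  specs <- list(item_spec("x", "binary_2pl", 2))
  expect_error(response_matrix(matrix(3L, 2, 1), specs), "outside")
  expect_error(response_matrix(matrix(NA_integer_, 2, 1), specs),
               "at least one observed")
  rm <- response_matrix(matrix(c(0L, 1L), 2, 1), specs)
  expect_s3_class(rm, "irtci_response_matrix")
  expect_equal(dim(rm), c(2L, 1L))
})
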