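# MLE fitting, KS distance, likelihood-ratio selection.

test_that("exponential MLE is the shifted-mean closed form (SE at beta = 1)", {
  k <- 1000 + stats::qexp(seq(0.005, 0.995, length.out = 200), rate = 2e-4)
  fit <- fit_degree_model(k, 1000, "exponential")
  expect_equal(unname(fit$params["lambda"]), 1 / (mean(k) - 1000))
  # the SE profile rate at beta = 1 is the same closed form
  expect_equal(length(k) / sum(k^1 - 1000^1), 1 / (mean(k) - 1000))
})

test_that("SE parameters are recovered; coarse grid MLE agrees", {
  k <- sample_degree_values("stretched_exponential",
                            list(beta = 0.7, lambda = 5e-5),
                            k_min = 1000, n = 1e5, seed = 17)
  fit <- fit_degree_model(k, 1000, "stretched_exponential")
  expect_equal(unname(fit$params["beta"]), 0.7, tolerance = 0.02 / 0.7)
  # independent coarse grid-search MLE over (beta, profiled lambda)
  grid <- seq(0.5, 0.9, by = 0.005)
  ll <- vapply(grid, function(b) {
    l <- length(k) / sum(k^b - 1000^b)
    sum(log(b) + log(l) + (b - 1) * log(k) - l * (k^b - 1000^b))
  }, 0)
  expect_equal(unname(fit$params["beta"]), grid[which.max(ll)],
               tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("cutoff power-law parameters are recovered near gamma = 1", {
  k <- sample_degree_values("powerlaw_cutoff",
                            list(gamma = 1, lambda = 6.086e-6),
                            k_min = 1000, n = 2e4, seed = 18)
  fit <- fit_degree_model(k, 1000, "powerlaw_cutoff")
  expect_equal(unname(fit$params["gamma"]), 1, tolerance = 0.1)
  expect_equal(unname(fit$params["lambda"]), 6.086e-6, tolerance = 0.15)
  expect_true(is.finite(fit$diagnostics$gamma_flatness))
})

test_that("all five fitted densities integrate to 1 on [k_min, Inf)", {
  set.seed(19)
  k <- sample_degree_values("stretched_exponential",
                            list(beta = 0.8, lambda = 1e-4),
                            k_min = 1000, n = 2000, seed = 19)
  for (model in DEGREE_MODELS) {
    fit <- fit_degree_model(k, 1000, model)
    dens <- function(x) exp(odflow:::degree_loglik_points(model, fit$params,
                                                          1000, x))
    # integrate in log-k for numerical stability of slowly decaying tails
    total <- stats::integrate(function(u) dens(exp(u)) * exp(u),
                              log(1000), 120, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6, label = model)
  }
})

test_that("MLE recovery error shrinks with sample size", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    k <- sample_degree_values("stretched_exponential",
                              list(beta = 0.7, lambda = 5e-5),
                              k_min = 1000, n = n, seed = 23)
    abs(fit_degree_model(k, 1000, "stretched_exponential")$params["beta"] - 0.7)
  }, 0)
  expect_lt(errs[3], errs[1])
})

test_that("EC log-likelihood approaches the pure power law as lambda -> 0", {
  set.seed(29)
  k <- 1000 * (1 - stats::runif(500))^(-1 / 1.5)  # power law, gamma = 2.5
  pl <- sum(odflow:::degree_loglik_points("powerlaw", c(gamma = 2.5), 1000, k))
  ec <- vapply(c(1e-7, 1e-9, 1e-11), function(l)
    sum(odflow:::degree_loglik_points("powerlaw_cutoff",
                                      c(gamma = 2.5, lambda = l), 1000, k)), 0)
  expect_lt(abs(ec[3] - pl), abs(ec[1] - pl))
  expect_equal(ec[3], pl, tolerance = 1e-4)
})

test_that("KS distance matches a 6-candidate hand enumeration", {
  # 3 points vs Exp(1) CDF from k_min = 0
  fit <- structure(list(model = "exponential", params = c(lambda = 1),
                        k_min = 0), class = "degree_fit")
  ks <- ks_distance(c(1, 2, 3), fit)
  Fv <- 1 - exp(-c(1, 2, 3))
  hand <- max(abs(c(1, 2, 3) / 3 - Fv), abs(c(0, 1, 2) / 3 - Fv))
  expect_equal(ks, hand)
  # self-comparison: a fit whose CDF is the empirical step function gives ~0
  k <- sample_degree_values("stretched_exponential",
                            list(beta = 1, lambda = 1e-3), 100, 5000, seed = 5)
  f <- fit_degree_model(k, 100, "stretched_exponential")
  expect_lt(f$ks, 0.05)
  # KS shrinks stochastically with n under the true model
  ks_n <- vapply(c(500, 5e4), function(n) {
    kk <- sample_degree_values("stretched_exponential",
                               list(beta = 1, lambda = 1e-3), 100, n, seed = 6)
    fit_degree_model(kk, 100, "stretched_exponential")$ks
  }, 0)
  expect_lt(ks_n[2], ks_n[1])
})

test_that("likelihood ratio favours the generating model and handles ties", {
  k <- 1000 + stats::rexp(1e4, 1e-4)
  set.seed(7)
  fe <- fit_degree_model(k, 1000, "exponential")
  fp <- fit_degree_model(k, 1000, "powerlaw")
  lr <- loglik_ratio(fe, fp, k)
  expect_gt(lr$ratio, 0)
  expect_equal(lr$ratio, fe$loglik - fp$loglik)  # direct-sum oracle
  expect_lt(lr$p_value, 0.05)
  tie <- loglik_ratio(fe, fe, k)
  expect_identical(tie$preferred, "inconclusive")
  expect_equal(tie$ratio, 0)
})

test_that("model selection ranks the generating stretched exponential first", {
  k <- sample_degree_values("stretched_exponential",
                            list(beta = 0.708, lambda = 4.138e-5),
                            k_min = 1000, n = 1e5, seed = 37)
  sel <- select_best(k, 1000)
  expect_identical(sel$table$model[1], "stretched_exponential")
  one <- select_best(k, 1000, models = "exponential")
  expect_identical(one$table$model, "exponential")
})

test_that("fit contracts are enforced", {
  expect_error(fit_degree_model(c(5, rep(2000, 11)), 1000, "powerlaw"), "k_min")
  expect_error(fit_degree_model(rep(2000, 5), 1000, "powerlaw"), "10 samples")
})
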