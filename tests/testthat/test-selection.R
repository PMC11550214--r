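# Goodness-of-fit statistics and information-theoretic model comparison.

test_that("R-squared matches its defining arithmetic", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1, 2, 4)), 1 - 1 / 2)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)),
               class = "biokin_degenerate_data_error")
  expect_error(r_squared(1, 1), class = "biokin_input_error")
})

test_that("adjusted R-squared uses the n - p denominator exactly", {
  expect_equal(adjusted_r_squared(1, 10, 3), 1)
  expect_equal(adjusted_r_squared(0.9, 10, 2), 1 - (9 / 8) * 0.1)
  expect_equal(adjusted_r_squared(0.9, 10, 2), 0.8875)
  # p = 1 leaves R-squared untouched
  expect_equal(adjusted_r_squared(0.37, 12, 1), 0.37)
  expect_error(adjusted_r_squared(0.9, 2, 2), class = "biokin_dof_error")
  # monotone increasing in r2 at fixed n, p
  r2s <- seq(-0.5, 1, by = 0.1)
  expect_true(all(diff(vapply(r2s, adjusted_r_squared, numeric(1),
                              n = 15, p = 3)) > 0))
})

test_that("the profile Gaussian log-likelihood matches closed forms", {
  # n = 10, sum x^2 = 10: the ln n and ln sum terms cancel
  x10 <- rep(1, 10)
  expect_equal(gaussian_loglik(x10), -5 * (log(2 * pi) + 1),
               tolerance = 1e-12)
  expect_equal(gaussian_loglik(x10), -14.18939, tolerance = 1e-6)
  expect_equal(gaussian_loglik(1, n = 1), -0.5 * (log(2 * pi) + 1),
               tolerance = 1e-12)
  # scaling residuals by c shifts the log-likelihood by -n log c
  r <- c(0.3, -1.2, 0.8, 0.1)
  expect_equal(gaussian_loglik(3 * r), gaussian_loglik(r) - 4 * log(3),
               tolerance = 1e-12)
  # invariant to sign flips and permutations
  expect_equal(gaussian_loglik(-r), gaussian_loglik(r))
  expect_equal(gaussian_loglik(sample(r)), gaussian_loglik(r))
  # perfect fit: unbounded likelihood is signalled as Inf
  expect_identical(gaussian_loglik(rep(0, 5)), Inf)
})

test_that("AIC and AICc follow their definitions", {
  expect_equal(aic(2, 0), 4)
  expect_equal(aic(2, -14.18939), 32.37878, tolerance = 1e-6)
  expect_equal(aic(3, -7) - aic(2, -7), 2)
  expect_equal(aicc(32.37878, 10, 2), 32.37878 + 12 / 7, tolerance = 1e-6)
  expect_equal(aicc(10, 4, 2), 10 + 12)
  # correction vanishes with n and is decreasing in n
  ns <- c(5, 10, 50, 1000, 1e6)
  corr <- vapply(ns, function(n) aicc(0, n, 2), numeric(1))
  expect_true(all(diff(corr) < 0))
  expect_lt(corr[length(corr)], 1e-4)
  expect_error(aicc(10, 3, 2), class = "biokin_dof_error")
})

test_that("Akaike weights normalise the evidence", {
  expect_equal(akaike_weights(5), 1)
  expect_equal(akaike_weights(c(7, 7)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(w, c(0.73106, 0.26894), tolerance = 1e-5)
  # invariance to a common offset, sums to one
  set.seed(2)
  for (i in 1:20) {
    a <- stats::rnorm(4, 20, 5)
    expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(a + 100), akaike_weights(a),
                 tolerance = 1e-12)
  }
  expect_error(akaike_weights(numeric()), class = "biokin_input_error")
  expect_error(akaike_weights(c(1, Inf)), class = "biokin_input_error")
})

test_that("model comparison prefers fewer parameters at equal residuals", {
  sc <- silver_scenario()
  dat <- generate_dataset("OC", silver_oc_params(), sc,
                          noise = noise_spec("proportional", 0.05,
                                             seed = 31L))
  cfg <- study_config(seed = 4L)
  oc <- fit_model(dat, "OC", sc, cfg)
  # an OC-SF "fit" with the same fitted values, differing only in p
  ocsf <- oc
  ocsf$model <- "OC-SF"
  ocsf$npar <- 3L
  ocsf$params <- kinetic_params(oc$params$k1, oc$params$k2, 0)
  cmp <- compare_models(dat, list(oc, ocsf))
  expect_equal(cmp$best_index, 1L)
  expect_equal(cmp$labels[cmp$best_index], "OC")
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-12)
  expect_equal(cmp$deltas[cmp$best_index], 0)
  expect_gte(cmp$weights[cmp$best_index], 1 / 2)
  expect_gt(cmp$weights[1], cmp$weights[2])
})

test_that("a perfect fit is reported as best with the whole weight and flagged", {
  sc <- silver_scenario()
  dat <- generate_dataset("OC", silver_oc_params(), sc, twelve_times(),
                          noise_spec("none"))
  perfect <- fit_model(dat, "OC", sc, study_config(seed = 1L))
  perfect$fitted_values <- dat$concentration   # exact by construction
  perfect$residuals <- rep(0, nrow(dat))
  rough <- fit_model(dat, "OC-SF", sc, tiny_config(seed = 9L,
                                                   max_generations = 60L))
  cmp <- compare_models(dat, list(perfect, rough))
  expect_true(cmp$degenerate)
  expect_equal(cmp$weights, c(1, 0))
  expect_equal(cmp$best_index, 1L)
  expect_true(all(is.finite(cmp$weights)))
})

test_that("comparison inputs must share the data", {
  sc <- silver_scenario()
  dat <- generate_dataset("OC", silver_oc_params(), sc,
                          noise = noise_spec("proportional", 0.05,
                                             seed = 1L))
  other <- generate_dataset("OC", silver_oc_params(), sc, twelve_times(),
                            noise_spec("none"))
  f <- fit_model(dat, "OC", sc, tiny_config())
  expect_error(compare_models(other, list(f)),
               class = "biokin_input_error")
})
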