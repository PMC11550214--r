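# Closed-form model evaluation: phase expressions, boundary behaviour,
# limits and the analytical-solution grid.

test_that("predictions reproduce hand-evaluated uptake and elimination values", {
  sc <- exposure_scenario(c_exposure = 1, t_e = 1, t_total = 2, dt = 0.5)
  p <- kinetic_params(1, 1)
  # t = 0 cancels the exponential term for any parameters
  expect_equal(predict_concentration("OC", p, sc, 0), 0)
  sc0 <- exposure_scenario(c_exposure = 3, t_e = 1, t_total = 2, c_org0 = 0.7)
  expect_equal(predict_concentration("OC", kinetic_params(2.2, 0.4), sc0, 0),
               0.7)
  # uptake at t = 1 and elimination at t = 2, unit rates
  expect_equal(predict_concentration("OC", p, sc, 1), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(predict_concentration("OC", p, sc, 2), exp(-1) - exp(-2),
               tolerance = 1e-12)
  # sf = 1: pure linear accrual during uptake
  psf1 <- kinetic_params(0.3, 0.5, 1)
  sc1 <- exposure_scenario(c_exposure = 2, t_e = 10, t_total = 20,
                           c_org0 = 0.2)
  tt <- c(0, 2.5, 7, 10)
  expect_equal(predict_concentration("OC-SF", psf1, sc1, tt),
               0.2 + 2 * 0.3 * tt, tolerance = 1e-12)
})

test_that("the stored-fraction model nests the plain model at SF = 0", {
  sc <- silver_scenario()
  p0 <- silver_oc_params()
  psf <- kinetic_params(p0$k1, p0$k2, 0)
  tt <- seq(0, 96, by = 0.5)
  expect_identical(predict_concentration("OC-SF", psf, sc, tt),
                   predict_concentration("OC", p0, sc, tt))
})

test_that("predictions are continuous at the phase boundary", {
  # the uptake and elimination expressions, written out branch by branch,
  # must agree at t = t_e -- and the evaluator must sit on that value
  set.seed(42)
  for (i in 1:200) {
    p <- random_valid_params()
    cx <- 10^stats::runif(1, -1, 1)
    te <- stats::runif(1, 1, 50)
    c0 <- stats::runif(1)
    sc <- exposure_scenario(c_exposure = cx, t_e = te, t_total = 100,
                            c_org0 = c0)
    up <- c0 + p$sf * cx * p$k1 * te +
      (1 - p$sf) * cx * (p$k1 / p$k2) * (1 - exp(-p$k2 * te))
    down <- c0 + p$sf * cx * p$k1 * te +
      (1 - p$sf) * cx * (p$k1 / p$k2) * (exp(0) - exp(-p$k2 * te))
    expect_lt(abs(up - down), 1e-9)
    expect_equal(predict_concentration("OC-SF", p, sc, te), up,
                 tolerance = 1e-12)
  }
})

test_that("uptake is non-decreasing and OC elimination non-increasing in time", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_valid_params()
    sc <- exposure_scenario(c_exposure = 1, t_e = 20, t_total = 60)
    up <- predict_concentration("OC-SF", p, sc, seq(0, 20, by = 0.5))
    expect_true(all(diff(up) >= -1e-12))
    oc <- kinetic_params(p$k1, p$k2)
    down <- predict_concentration("OC", oc, sc, seq(20, 60, by = 0.5))
    expect_true(all(diff(down) <= 1e-12))
  }
})

test_that("long-time elimination limits are the inert burdens", {
  p <- kinetic_params(0.426, 0.155, 0.086)
  sc <- exposure_scenario(c_exposure = 2, t_e = 48, t_total = 96,
                          c_org0 = 0.3)
  far <- 1e5
  expect_equal(predict_concentration("OC", kinetic_params(0.2, 0.05), sc, far),
               0.3, tolerance = 1e-9)
  expect_equal(predict_concentration("OC-SF", p, sc, far),
               0.3 + 0.086 * 2 * 0.426 * 48, tolerance = 1e-9)
})

test_that("invalid inputs are rejected with classed errors", {
  sc <- silver_scenario()
  p <- silver_oc_params()
  expect_error(predict_concentration("OC", p, sc, -1),
               class = "biokin_domain_error")
  expect_error(kinetic_params(1, 0), class = "biokin_parameter_error")
  expect_error(kinetic_params(-1, 1), class = "biokin_parameter_error")
  expect_error(kinetic_params(1, 1, 1.5), class = "biokin_parameter_error")
  expect_error(predict_concentration("OC", kinetic_params(1, 1, 0.5), sc, 1),
               class = "biokin_parameter_error")
  expect_error(model_kind("bogus"), class = "biokin_parameter_error")
})

test_that("the simulation grid covers 0 to t_total and always contains t_e", {
  p <- silver_oc_params()
  # dt = t_total: two grid points plus the phase boundary
  sc2 <- exposure_scenario(c_exposure = 1, t_e = 30, t_total = 96, dt = 96)
  s2 <- simulate_series("OC", p, sc2)
  expect_equal(s2$time, c(0, 30, 96))
  # t_e on the grid is not duplicated
  sc3 <- silver_scenario(dt = 8)
  s3 <- simulate_series("OC", p, sc3)
  expect_equal(s3$time, seq(0, 96, by = 8))
  # grid values match pointwise re-evaluation to machine precision
  sc4 <- silver_scenario(dt = 7)   # t_e = 48 off-grid
  s4 <- simulate_series("OC-SF", silver_ocsf_params(), sc4)
  expect_true(48 %in% s4$time)
  expect_identical(s4$concentration,
                   predict_concentration("OC-SF", silver_ocsf_params(), sc4,
                                         s4$time))
  expect_error(simulate_series("OC", p,
                 exposure_scenario(c_exposure = 1, t_e = 5, t_total = 10,
                                   dt = 20)),
               class = "biokin_config_error")
})

test_that("steady-state burden is the uptake-phase plateau", {
  expect_equal(steady_state_burden(kinetic_params(1, 1),
                 exposure_scenario(c_exposure = 1, t_e = 10)), 1)
  expect_equal(steady_state_burden(kinetic_params(5, 2),
                 exposure_scenario(c_exposure = 0, t_e = 10, c_org0 = 0.4)),
               0.4)
  # graphene-like kinetics: c_exposure * k1 / k2
  expect_equal(steady_state_burden(kinetic_params(2766.4, 0.064),
                 exposure_scenario(c_exposure = 0.25, t_e = 24)),
               0.25 * 2766.4 / 0.064, tolerance = 1e-12)
})
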