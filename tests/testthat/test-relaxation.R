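test_that("b=0 signal and biased axonal coefficient match hand evaluation", {
  sf <- signal_fractions(nu = 0.475)
  t2 <- t2_profile(T2_a = 50, T2_e = 30)
  s0_expected <- 0.475 * exp(-19 / 50) + 0.525 * exp(-19 / 30)
  expect_equal(s0_hat(sf, t2, TE = 19), s0_expected, tolerance = 1e-12)
  expect_equal(fAW_at_TE(sf, t2, TE = 19),
               0.475 * exp(-19 / 50) / s0_expected, tolerance = 1e-12)

  expect_equal(s0_hat(sf, t2, TE = 0), 1)
  expect_equal(fAW_at_TE(sf, t2, TE = 0), 0.475)
  # all T2 equal -> common exponential factor
  t2eq <- t2_profile(T2_a = 40, T2_e = 40, T2_iso = 40, T2_dot = 40)
  sf4 <- signal_fractions(0.4, nu_iso = 0.1, nu_dot = 0.05)
  expect_equal(s0_hat(sf4, t2eq, TE = 25), exp(-25 / 40), tolerance = 1e-12)
  expect_error(s0_hat(signal_fractions(0.4, nu_iso = 0.1),
                      t2_profile(50, 30), TE = 10), "T2_iso")
})

test_that("predicted scaling matches the closed form and its limits", {
  sf <- signal_fractions(nu = 0.475)
  t2 <- t2_profile(T2_a = 50, T2_e = 30)
  # Delta_e = 1/(1/30 - 1/50) = 75 ms
  expect_equal(predicted_scaling(sf, t2, TE = 19),
               0.475 + 0.525 * exp(-19 / 75), tolerance = 1e-12)
  # cross-check against the defining ratio S0hat / exp(-TE/T2a)
  expect_equal(predicted_scaling(sf, t2, TE = 19),
               s0_hat(sf, t2, 19) / exp(-19 / 50), tolerance = 1e-12)
  expect_equal(predicted_scaling(sf, t2, TE = 0), 1)
  expect_equal(predicted_scaling(sf, t2_profile(40, 40), TE = 30), 1)
  # s < 1 when non-axonal T2 shorter than axonal, > 1 when longer
  expect_lt(predicted_scaling(sf, t2, 19), 1)
  expect_gt(predicted_scaling(sf, t2_profile(T2_a = 30, T2_e = 50), 19), 1)
})

test_that("scaling times biased coefficient recovers the unbiased fraction", {
  set.seed(123)
  for (i in 1:1000) {
    sf <- signal_fractions(nu = runif(1, 0.05, 0.95),
                           nu_iso = runif(1, 0, 0.3),
                           nu_dot = runif(1, 0, 0.2))
    t2 <- t2_profile(T2_a = runif(1, 20, 120), T2_e = runif(1, 10, 120),
                     T2_iso = runif(1, 50, 2000), T2_dot = runif(1, 5, 80))
    TE <- runif(1, 0, 60)
    lhs <- predicted_scaling(sf, t2, TE) * fAW_at_TE(sf, t2, TE)
    rhs <- (1 - sf$nu_dot) * (1 - sf$nu_iso) * sf$nu
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("scaling is monotone in TE and S0 decreasing, in (0,1]", {
  sf <- signal_fractions(nu = 0.4)
  te_grid <- seq(0, 60, by = 5)
  short <- vapply(te_grid, function(te)
    predicted_scaling(sf, t2_profile(50, 30), te), 0)
  long <- vapply(te_grid, function(te)
    predicted_scaling(sf, t2_profile(30, 50), te), 0)
  expect_true(all(diff(short) < 0))
  expect_true(all(diff(long) > 0))
  s0 <- vapply(te_grid, function(te) s0_hat(sf, t2_profile(50, 30), te), 0)
  expect_true(all(diff(s0) < 0))
  expect_true(all(s0 > 0 & s0 <= 1))
})

test_that("solve_delta_e inverts the two-compartment scaling", {
  sf <- signal_fractions(nu = 0.475)
  target <- 0.475 + 0.525 * exp(-19 / 75) # the Delta_e = 75 ms case
  expect_equal(solve_delta_e(sf, TE = 19, s_target = target), 75,
               tolerance = 1e-10)
  # forward consistency across random targets
  set.seed(9)
  for (i in 1:100) {
    nu <- runif(1, 0.1, 0.9)
    sfi <- signal_fractions(nu)
    s_t <- runif(1, nu + 0.02, 0.999)
    de <- solve_delta_e(sfi, TE = 19, s_target = s_t)
    t2 <- t2_profile(T2_a = 50, T2_e = 1 / (1 / de + 1 / 50))
    expect_equal(predicted_scaling(sfi, t2, 19), s_t, tolerance = 1e-10)
  }
  expect_error(solve_delta_e(sf, 19, s_target = 0.475), "strictly in")
  expect_error(solve_delta_e(sf, 19, s_target = 1), "strictly in")
  expect_error(solve_delta_e(sf, 19, s_target = 1 - 1e-12), "infeasible")
})

test_that("synthetic T2 profile reproduces the requested scaling", {
  sf <- signal_fractions(nu = 0.475)
  t2 <- synthetic_t2_profile(sf, TE = 19, s_target = 0.89)
  expect_equal(predicted_scaling(sf, t2, 19), 0.89, tolerance = 1e-10)
})
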