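test_that("modulus calibration round-trips the forward model", {
  m <- default_model()
  for (E_true in c(250, 700, 1500, 2800)) {
    g <- bend_scale(m, scale_state(-0.22, 37, E_true))$gamma_deg
    fit <- fit_passive_modulus(m, target_gamma = g, bracket = c(200, 3000))
    expect_lt(abs(fit$fitted_value - E_true) / E_true, 1e-6)
    expect_true(fit$converged)
    expect_lt(abs(fit$residual_deg), 1e-4)
    expect_true(fit$fitted_value >= fit$bracket[1] &&
                  fit$fitted_value <= fit$bracket[2])
    expect_lte(fit$iterations, 200)
  }
})

test_that("modulus calibration agrees with a dense grid-scan oracle", {
  m <- default_model()
  target <- 24.4
  fit <- fit_passive_modulus(m, target_gamma = target)
  E <- seq(100, 5000, length.out = 2000)
  g <- .gamma_states(m, -0.22, 37, E) - target
  cell <- which(g[-1] * g[-2000] <= 0)
  expect_length(cell, 1L)  # unique sign change over the bracket
  expect_gte(fit$fitted_value, E[cell])
  expect_lte(fit$fitted_value, E[cell + 1])
})

test_that("non-monotone or non-straddling brackets are refused", {
  m <- default_model()
  # the curvature peaks near E_passive ~ E_active, so a bracket spanning
  # the peak is non-monotone and must be refused, not silently solved
  expect_error(fit_passive_modulus(m, target_gamma = 30, bracket = c(10, 5000)),
               "monotone")
  expect_error(fit_passive_modulus(m, target_gamma = 200,
                                   bracket = c(500, 1500)),
               "no sign change.*residual")
})

test_that("contraction calibration round-trips and hits zero at zero target", {
  m <- default_model()
  p <- drying_path(E_passive_dry = 2000)
  st <- interval_states(p, c(80, 30))
  z <- fit_contraction(m, target_gamma = 0, state_wet = st[[1]],
                       state_dry = st[[2]],
                       bracket = c(-0.01, 0.22))
  # with no extra contraction the stiffened dry layer bends slightly less,
  # so the exact-zero target needs only a tiny increment
  expect_lt(abs(z$fitted_value), 0.01)
  expect_true(z$converged)
  for (de_true in c(0.04, 0.1, 0.18)) {
    dry <- scale_state(st[[1]]$eps_active - de_true, st[[2]]$E_active,
                       st[[2]]$E_passive)
    target <- angular_change(m, st[[1]], dry)
    fit <- fit_contraction(m, target_gamma = target,
                           state_wet = st[[1]], state_dry = st[[2]])
    expect_lt(abs(fit$fitted_value - de_true) / de_true, 1e-6)
  }
})

test_that("drying sweep starts at zero, grows monotonically, ends at the dry angle", {
  m <- default_model()
  fit <- fit_passive_modulus(m, target_gamma = 24.4)
  p <- drying_path(E_passive_dry = fit$fitted_value)
  sw <- drying_sweep(m, p, n_points = 21)
  expect_s3_class(sw, "sweep_table")
  expect_equal(nrow(sw), 21)
  expect_equal(sw$gamma_deg[1], 0)
  expect_true(all(diff(sw$gamma_deg) >= 0))
  expect_equal(sw$gamma_deg[21], 24.4, tolerance = 1e-6)
  expect_equal(sw$E_passive_MPa[c(1, 21)], c(70, fit$fitted_value))
  # humidity equivalents clamp to the curve range and decrease on drying
  expect_true(all(sw$rh_percent >= 30 & sw$rh_percent <= 80))
  expect_true(all(diff(sw$rh_percent) <= 0))
  expect_error(drying_sweep(m, p, n_points = 1), "at least 2")
})

test_that("interval angles add up along the drying path (state-function curvature)", {
  m <- default_model()
  p <- drying_path(E_passive_dry = 1800)
  rh <- c(80, 70, 60, 50, 40, 30)
  st <- interval_states(p, rh)
  steps <- vapply(seq_len(length(rh) - 1), function(i)
    angular_change(m, st[[i]], st[[i + 1]]), numeric(1))
  total <- angular_change(m, st[[1]], st[[length(rh)]])
  expect_equal(sum(steps), total, tolerance = 1e-12)
})

test_that("interval prediction reports angle and the 620 MPa modulus change", {
  m <- default_model()
  p <- drying_path(E_passive_dry = 1800)
  same <- predict_interval_angle(m, p, 55, 55)
  expect_equal(same$angle_deg, 0)
  expect_equal(same$modulus_difference_MPa, 0)
  iv <- predict_interval_angle(m, p, 80, 30)
  expect_equal(iv$modulus_difference_MPa, 620)
  expect_gt(iv$angle_deg, 0)
  # swapping the endpoints flips both signs
  rev <- predict_interval_angle(m, p, 30, 80)
  expect_equal(rev$angle_deg, -iv$angle_deg)
  expect_equal(rev$modulus_difference_MPa, -620)
})
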