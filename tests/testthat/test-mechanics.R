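bilayer_df <- function(t, w, E, eps)
  data.frame(thickness = t, width = w, modulus = E, eigenstrain = eps)

test_that("uniform eigenstrain produces pure membrane strain, no curvature", {
  layers <- bilayer_df(c(0.8, 0.6), 1.8, c(37, 1170), c(-0.05, -0.05))
  r <- section_response(layers)
  expect_equal(r$eps0, -0.05)
  expect_equal(r$kappa, 0)
  r0 <- section_response(bilayer_df(c(0.8, 0.6), 1.8, c(37, 1170), c(0, 0)))
  expect_equal(r0$eps0, 0)
  expect_equal(r0$kappa, 0)
})

test_that("the symmetric bimetal recovers the 1.5*deps/h closed form", {
  r <- section_response(bilayer_df(c(1, 1), 2, c(500, 500), c(-0.1, 0)))
  expect_equal(r$kappa, 1.5 * 0.1 / 2)
  expect_equal(timoshenko_curvature(1, 1, 500, 500, 0.1), 0.075)
  expect_equal(timoshenko_curvature(1, 1, 500, 500, 0), 0)
})

test_that("section solver matches the bimetallic closed form on random bilayers", {
  set.seed(42)
  for (i in 1:200) {
    b <- random_bilayer()
    r <- section_response(bilayer_df(c(b$t_active, b$t_passive), b$width,
                                     c(b$E_active, b$E_passive), c(b$eps, 0)))
    # layer 1 of the closed form is the top (passive) layer; mismatch is
    # top free strain minus bottom free strain
    k <- timoshenko_curvature(b$t_passive, b$t_active,
                              b$E_passive, b$E_active, -b$eps)
    expect_lt(abs(r$kappa - k), 1e-10 * max(abs(k), 1e-12))
  }
})

test_that("curvature is linear in the eigenstrain mismatch", {
  base <- bilayer_df(c(0.8, 0.6), 1.8, c(37, 1170), c(-0.22, 0))
  k1 <- section_response(base)$kappa
  for (f in c(0.5, 2)) {
    scaled <- base
    scaled$eigenstrain <- base$eigenstrain * f
    expect_equal(section_response(scaled)$kappa, k1 * f)
  }
})

test_that("curvature does not depend on the reference-axis position", {
  layers <- bilayer_df(c(0.3, 0.9, 0.4), c(2, 2, 2), c(40, 900, 60),
                       c(-0.15, 0, 0.02))
  k0 <- section_response(layers)$kappa
  for (shift in c(-1.3, 0.4, 2)) {
    r <- section_response(layers, z_ref = shift)
    expect_equal(r$kappa, k0)
  }
})

test_that("degenerate sections are rejected with informative errors", {
  expect_error(section_response(data.frame(x = 1)), "columns")
  expect_error(section_response(bilayer_df(c(0, 1), 1, c(1, 1), c(0, 0))),
               "positive")
  expect_error(section_response(bilayer_df(1, 1, -5, 0)), "positive")
  expect_error(timoshenko_curvature(0, 1, 1, 1, 0.1), "positive")
  expect_error(timoshenko_curvature(1, 1, -1, 1, 0.1), "positive")
})

test_that("a prismatic zone integrates to gamma = kappa * L exactly", {
  z <- bending_zone(length_mm = 5, width_start_mm = 2, width_end_mm = 2,
                    active = layer_profile("active", 0.8, 0.8),
                    passive = layer_profile("passive", 0.6, 0.6))
  m <- scale_model(zone = z)
  st <- scale_state(-0.1, 37, 1170)
  kap <- section_response(bilayer_df(c(0.8, 0.6), 2, c(37, 1170),
                                     c(-0.1, 0)))$kappa
  b <- bend_scale(m, st)
  expect_equal(b$gamma_deg, kap * 5 * 180 / pi, tolerance = 1e-12)
  expect_equal(b$theta[length(b$theta)] * 180 / pi, b$gamma_deg)
  expect_equal(b$theta[1], 0)
})

test_that("drying bends the scale open: positive curvature and angle", {
  m <- default_model()
  b <- bend_scale(m, scale_state(-0.22, 37, 1170))
  expect_true(all(b$kappa > 0))
  expect_gt(b$gamma_deg, 0)
  # flipping the active side flips the sign
  m2 <- scale_model(active_side = "adaxial")
  expect_equal(bend_scale(m2, scale_state(-0.22, 37, 1170))$gamma_deg,
               -b$gamma_deg)
  # centerline starts at the clamped origin and the lever tip extends it
  expect_equal(unlist(b$centerline[1, ]), c(x_mm = 0, y_mm = 0))
  n <- nrow(b$centerline)
  tip <- b$centerline[n, ] - b$centerline[n - 1, ]
  expect_equal(atan2(tip$y_mm, tip$x_mm) * 180 / pi, b$gamma_deg)
  expect_equal(sqrt(tip$x_mm^2 + tip$y_mm^2), m$lever_mm)
})

test_that("station refinement leaves the angle essentially unchanged", {
  st <- scale_state(-0.22, 37, 1170)
  g51 <- bend_scale(default_model(n_stations = 51), st)$gamma_deg
  g101 <- bend_scale(default_model(n_stations = 101), st)$gamma_deg
  expect_lt(abs(g101 - g51) / abs(g51), 1e-6)
  # and agrees with a brute-force dense quadrature of per-station
  # section_response calls
  g_ref <- gamma_brute(default_model(), st)
  expect_lt(abs(g51 - g_ref) / abs(g_ref), 1e-5)
})

test_that("tip position equals the elastica of the same curvature field", {
  m <- default_model(n_stations = 201)
  b <- bend_scale(m, scale_state(-0.22, 37, 1500))
  kf <- stats::splinefun(b$stations, b$kappa)
  out <- deSolve::ode(
    y = c(theta = 0, x = 0, y = 0),
    times = b$stations,
    func = function(s, y, p) list(c(kf(s), cos(y[1]), sin(y[1]))),
    parms = NULL,
    method = "ode45", rtol = 1e-10, atol = 1e-12)
  n <- length(b$stations)
  expect_equal(b$theta[n], unname(out[n, "theta"]), tolerance = 1e-7)
  expect_equal(b$centerline$x_mm[n], unname(out[n, "x"]), tolerance = 1e-6)
  expect_equal(b$centerline$y_mm[n], unname(out[n, "y"]), tolerance = 1e-6)
})

test_that("gamma decreases with passive modulus on the stiff branch", {
  m <- default_model()
  Ep <- seq(150, 5000, length.out = 40)  # >= 4x the 37 MPa active modulus
  g <- vapply(Ep, function(E)
    bend_scale(m, scale_state(-0.22, 37, E))$gamma_deg, numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("angular change is antisymmetric and vanishes for equal states", {
  m <- default_model()
  a <- scale_state(-0.02, 35, 180)
  b <- scale_state(-0.15, 37, 800)
  expect_equal(angular_change(m, a, a), 0)
  expect_equal(angular_change(m, a, b), -angular_change(m, b, a))
})
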