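test_that("modulus curves interpolate linearly and clamp at the endpoints", {
  sf <- sf_sim()
  expect_equal(young_modulus(sf, 30), 800)
  expect_equal(young_modulus(sf, 80), 180)
  expect_equal(young_modulus(sf, 55), 490)        # linear midpoint
  # clamped outside the measured range, never extrapolated
  expect_equal(young_modulus(sf, 0), young_modulus(sf, 30))
  expect_equal(young_modulus(sf, 100), young_modulus(sf, 80))
  # continuity / knot exactness on a multi-knot curve
  bt <- material_preset("brown_tissue")
  expect_equal(young_modulus(bt, 50), 52)
  expect_equal(young_modulus(bt, bt$rh), bt$E)
  rh <- seq(0, 100, by = 0.5)
  E <- young_modulus(bt, rh)
  expect_true(all(E > 0))
  expect_true(all(abs(diff(E)) < 10))  # no jumps on a fine grid
})

test_that("material_curve rejects malformed knot sets", {
  expect_error(material_curve("x", numeric(0), numeric(0)), "knot")
  expect_error(material_curve("x", c(50, 30), c(1, 2)), "increasing")
  expect_error(material_curve("x", c(30, 30), c(1, 2)), "increasing")
  expect_error(material_curve("x", c(30, 60), c(10, -1)), "positive")
  expect_error(material_curve("x", c(30, 150), c(1, 2)), "\\[0, 100\\]")
  expect_error(young_modulus(sf_sim(), NA_real_), "finite")
})

test_that("plane strain stiffens the effective modulus by 1/(1 - nu^2)", {
  cu <- sf_sim()
  uni <- tissue_material(cu)                       # default: uniaxial
  ps <- tissue_material(cu, poisson_ratio = 0.3, plane_strain = TRUE)
  expect_equal(young_modulus(uni, 55), 490)
  expect_equal(young_modulus(ps, 55), 490 / (1 - 0.3^2))
  expect_error(tissue_material(cu, poisson_ratio = 0.5), "0.5")
  expect_error(tissue_material(cu, poisson_ratio = -0.1), "0.5")
})

test_that("sclereid regression runs 37 MPa (dry) to 21 MPa (wet), clamped", {
  expect_equal(sclereid_modulus(30), 37)
  expect_equal(sclereid_modulus(80), 21)
  expect_equal(sclereid_modulus(55), 29)
  expect_equal(sclereid_modulus(10), 37)
  expect_equal(sclereid_modulus(95), 21)
})

test_that("packaged presets reproduce the measured anchor values", {
  expect_equal(young_modulus(material_preset("sclerenchyma_sim"), c(30, 80)),
               c(800, 180))
  expect_equal(young_modulus(material_preset("sclerenchyma_afm"), c(30, 75)),
               c(800, 200))
  sc <- material_preset("sclereid_afm")
  expect_equal(young_modulus(sc, c(50, 60)), c(35, 25))
  expect_error(material_preset("no_such_tissue"), "no curve")
})

test_that("drying path couples contraction and stiffening monotonically", {
  p <- drying_path()  # 0.22, 70 -> 1170 MPa
  expect_equal(active_strain(p, 1), -0.22)
  expect_equal(active_strain(p, 0), 0)
  expect_equal(active_strain(p, 0.5), -0.11)
  expect_error(active_strain(p, 1.2), "\\[0, 1\\]")
  expect_error(active_strain(p, -0.01), "\\[0, 1\\]")
  xi <- seq(0, 1, length.out = 101)
  expect_true(all(diff(active_strain(p, xi)) <= 0))
  expect_true(all(diff(passive_modulus(p, xi)) >= 0))
  expect_equal(passive_modulus(p, c(0, 1)), c(70, 1170))
  # a path that does not stiffen on drying is not a drying path
  expect_error(drying_path(E_passive_wet = 500, E_passive_dry = 100),
               "exceed")
})

test_that("humidity maps onto the drying coordinate through the passive curve", {
  p <- drying_path(E_passive_wet = 70, E_passive_dry = 1170)
  cu <- sf_sim()
  expect_equal(xi_from_rh(p, cu, 80), (180 - 70) / 1100)   # 0.1
  expect_equal(xi_from_rh(p, cu, 30), 730 / 1100)          # ~0.6636
  # curve value below the wet endpoint clips to xi = 0
  lo <- material_curve("soft", c(30, 80), c(70, 30))
  expect_equal(xi_from_rh(p, lo, 30), 0)
  expect_equal(xi_from_rh(p, lo, 80), 0)
  # rh_equivalent inverts the curve and clamps outside the attained moduli
  expect_equal(rh_equivalent(cu, c(800, 180, 490)), c(30, 80, 55))
  expect_equal(rh_equivalent(cu, 2000), 30)
  expect_error(rh_equivalent(material_curve("flat", c(30, 50, 80),
                                            c(50, 60, 50)), 55),
               "monotone")
})
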