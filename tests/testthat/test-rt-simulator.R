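test_that("leaf parameter validation rejects out-of-range inputs", {
  expect_error(leaf_params(cab = 40, n_structure = 0.9), "n_structure")
  expect_error(leaf_params(cab = -1), "contents")
  expect_error(leaf_params(cab = 40, cw = -0.1), "contents")
  expect_s3_class(leaf_params(cab = 0), "leaf_params")
})

test_that("leaf optics conserve energy and respond to pigments and structure", {
  lo25 <- prospect(leaf_params(cab = 25))
  lo50 <- prospect(leaf_params(cab = 50))
  # chlorophyll absorbs in the red: higher cab -> lower reflectance at 670 nm
  expect_lt(
    lo50$reflectance[lo50$wavelength == 670],
    lo25$reflectance[lo25$wavelength == 670]
  )
  # energy conservation at every wavelength, for several leaves
  for (leaf in list(
    leaf_params(cab = 25, n_structure = 1),
    leaf_params(cab = 50, n_structure = 1.5),
    leaf_params(cab = 40, cw = 0.05, cm = 0.02)
  )) {
    lo <- prospect(leaf)
    expect_true(all(lo$reflectance >= 0 & lo$transmittance >= 0))
    expect_true(all(lo$reflectance + lo$transmittance <= 1))
  }
  # more mesophyll layers scatter more in the NIR
  r800_n1 <- prospect(leaf_params(cab = 40, n_structure = 1))
  r800_n15 <- prospect(leaf_params(cab = 40, n_structure = 1.5))
  expect_gt(
    r800_n15$reflectance[r800_n15$wavelength == 800],
    r800_n1$reflectance[r800_n1$wavelength == 800]
  )
  # determinism
  expect_identical(prospect(leaf_params(cab = 33)), prospect(leaf_params(cab = 33)))
})

test_that("vectorized leaf optics match an independent plain-loop oracle", {
  wl_pick <- c(420, 550, 672, 760, 900, 1040)
  constants <- synthetic_optical_constants(400:1050)
  for (leaf in list(
    leaf_params(cab = 25, n_structure = 1),
    leaf_params(cab = 50, n_structure = 1.5),
    leaf_params(cab = 37, n_structure = 1.2, cw = 0.02, cm = 0.01)
  )) {
    lo <- prospect(leaf, 400:1050, constants = constants)
    for (w in wl_pick) {
      i <- which(constants$wavelength == w)
      k <- (leaf$cab * constants$k_cab[i] + leaf$car * constants$k_car[i] +
        leaf$cw * constants$k_cw[i] + leaf$cm * constants$k_cm[i]) /
        leaf$n_structure
      o <- oracle_prospect_one(k, constants$refractive_index[i], leaf$n_structure)
      expect_equal(lo$reflectance[i], unname(o["reflectance"]), tolerance = 1e-9)
      expect_equal(lo$transmittance[i], unname(o["transmittance"]), tolerance = 1e-9)
    }
  }
})

test_that("canopy radiative transfer honours the empty-canopy and saturation limits", {
  lo <- prospect(leaf_params(cab = 25, n_structure = 1.5))
  soil <- synthetic_soil_spectrum(400:1050)$reflectance
  g <- rt_geometry()

  # empty canopy: reflectance equals the soil exactly
  s0 <- sailh(lo, 0, 30, 0.01, soil, g)
  expect_equal(s0$reflectance, soil, tolerance = 1e-12)
  expect_true(all(s0$tau_ss == 1) && all(s0$tau_oo == 1))

  # soil independence at saturating LAI
  dark <- sailh(lo, 15, 30, 0.01, soil * 0, g)
  bright <- sailh(lo, 15, 30, 0.01, soil, g)
  expect_lt(max(abs(dark$reflectance - bright$reflectance)), 1e-4)

  # turbid-medium solution saturates in LAI once the hot-spot term is absent
  a <- sailh(lo, 15, 30, 0, soil, g)
  b <- sailh(lo, 20, 30, 0, soil, g)
  expect_lt(max(abs(a$reflectance - b$reflectance)), 1e-3)

  # physical bounds across a spread of grid corners
  for (lai in c(1, 4, 7)) {
    for (ala in c(0, 30, 60)) {
      s <- sailh(lo, lai, ala, 0.01, soil * 0.6, g)
      expect_true(all(s$reflectance >= 0 & s$reflectance <= 1))
      expect_true(all(s$rho_so >= 0 & s$rho_so <= 1))
      expect_true(all(s$tau_ss >= 0 & s$tau_ss <= 1))
    }
  }

  expect_error(sailh(lo, -1, 30, 0.01, soil, g), "lai")
  expect_error(sailh(lo, 3, 30, 0.01, soil[1:10], g), "wavelength grid")
})

test_that("crown composition respects its closed-form limits", {
  sc <- canopy_scene(cab = 40)
  g <- rt_geometry()

  # default stand: C_view = 500 * pi * 1^2 / 10000
  cc <- crown_cover(sc, g)
  expect_equal(unname(cc["c_view"]), 500 * pi / 10000, tolerance = 1e-12)
  expect_equal(unname(cc["c_sun"]), unname(cc["c_view"]) / cos(30 * pi / 180),
    tolerance = 1e-12
  )

  # no trees: the background comes through exactly
  rho_inf <- rep(0.5, 5)
  rho_bg <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  sc0 <- canopy_scene(cab = 40, stem_density = 0)
  expect_equal(
    flim_compose(rho_inf, rho_bg, 0.7, 0.7, sc0, g),
    rho_bg
  )

  # closed opaque canopy: full cover, no gaps -> pure crown reflectance
  sc1 <- canopy_scene(cab = 40, stem_density = 4000, crown_diameter = 2)
  expect_equal(unname(crown_cover(sc1, g)["c_view"]), 1)
  expect_equal(
    flim_compose(rho_inf, rho_bg, 0, 0, sc1, g),
    rho_inf
  )

  # composition is bounded between crown and background at every wavelength
  r <- flim_compose(rho_inf, rho_bg, 0.4, 0.6, sc, g)
  expect_true(all(r >= pmin(rho_inf, rho_bg) & r <= pmax(rho_inf, rho_bg)))
})

test_that("the full simulator produces physical, deterministic, pigment-sensitive spectra", {
  g <- rt_geometry()
  sc_min <- canopy_scene(
    cab = 25, n_structure = 1, lai_single_tree = 1,
    soil_scale = 0.6, ala_deg = 0
  )
  sp <- inform_simulate(sc_min, g)
  expect_equal(nrow(sp), 651)
  expect_true(all(sp$reflectance >= 0 & sp$reflectance <= 1))
  # red-edge inflection between 680 and 760 nm
  infl <- red_edge_inflection(sp$wavelength, sp$reflectance)
  expect_true(!is.na(infl) && infl >= 680 && infl <= 760)

  # determinism
  expect_identical(inform_simulate(sc_min, g), inform_simulate(sc_min, g))

  # reflectance at 670 nm non-increasing in cab over the grid levels
  r670 <- vapply(seq(25, 50, by = 5), function(cab) {
    s <- inform_simulate(canopy_scene(
      cab = cab, n_structure = 1.5,
      lai_single_tree = 4, soil_scale = 0.8, ala_deg = 30
    ), g)
    s$reflectance[s$wavelength == 670]
  }, numeric(1))
  expect_true(all(diff(r670) <= 0))

  # soil-limit oracle: bare scene returns the scaled reference soil
  sc_bare <- canopy_scene(
    cab = 40, lai_single_tree = 0, soil_scale = 0.7,
    stem_density = 0, lai_understory = 0
  )
  soil <- synthetic_soil_spectrum(400:1050)$reflectance
  expect_lt(
    max(abs(inform_simulate(sc_bare, g)$reflectance - 0.7 * soil)),
    1e-9
  )
})
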