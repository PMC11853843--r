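grid161 <- default_wavelengths()

test_that("built endmembers realize their declared absorption peaks", {
  cases <- list(
    water    = c(970, 1180, 1430),
    lipid    = c(920, 1210),        # 1730/1760 nm lie above the grid
    collagen = c(1200, 1500))       # 1725 nm lies above the grid
  for (mat in names(cases)) {
    em <- material_spectrum(mat, grid161)
    expect_true(all(em$reflectance > 0 & em$reflectance <= 1))
    for (center in cases[[mat]]) {
      b <- which.min(abs(grid161 - center))
      lo <- max(1, b - 1); hi <- min(length(grid161), b + 1)
      # a local reflectance minimum within +/- 1 band of the center
      neighborhood <- em$reflectance[max(1, b - 5):min(length(grid161), b + 5)]
      argmin_local <- which.min(neighborhood) + max(1, b - 5) - 1
      expect_true(argmin_local >= lo && argmin_local <= hi,
                  label = sprintf("%s peak at %d nm realized", mat, center))
    }
  }
})

test_that("out-of-grid peaks are dropped with a notice; empty sum is flat", {
  expect_message(
    em <- build_endmember("collagen", c(1200, 1500, 1725), 0.5,
                          wavelengths = grid161),
    "1725")
  expect_equal(em$peak_centers, c(1200, 1500))
  flat <- build_endmember("blank", numeric(0), numeric(0), baseline = 0.7,
                          wavelengths = grid161)
  expect_equal(flat$reflectance, rep(exp(-0.7), 161))
  expect_error(build_endmember("x", 1000, -0.1, wavelengths = grid161),
               "negative")
  expect_error(build_endmember("x", 1000, 0.1, wavelengths = numeric(0)),
               "empty wavelength grid")
})

test_that("collagen concentration scaling follows both stated laws", {
  base <- material_spectrum("collagen", grid161)
  # beer_lambert: doubling the concentration squares the reflectance
  sq <- collagen_at_concentration(base, 8, reference_concentration = 4,
                                  mode = "beer_lambert")
  expect_equal(sq$reflectance, base$reflectance^2, tolerance = 1e-12)
  # linear mode endpoints reproduce the endpoint spectra exactly
  r2 <- collagen_at_concentration(base, 2, mode = "beer_lambert")
  lin2 <- collagen_at_concentration(base, 2, mode = "linear_reflectance")
  expect_equal(lin2$reflectance, r2$reflectance, tolerance = 1e-12)
  # c = 3% puts weight 2/3 on the 2% spectrum
  r5 <- collagen_at_concentration(base, 5, mode = "beer_lambert")
  lin3 <- collagen_at_concentration(base, 3, mode = "linear_reflectance")
  expect_equal(lin3$reflectance,
               2 / 3 * r2$reflectance + 1 / 3 * r5$reflectance,
               tolerance = 1e-12)
  expect_error(collagen_at_concentration(base, 6, mode = "linear_reflectance"),
               "extrapolate")
  expect_error(collagen_at_concentration(base, -1), "> 0")
})

test_that("slab series attenuates monotonically and obeys the exponent law", {
  sc0 <- phantom_scene("slab_series", mu_eff = 0, sigma = 0, nrow = 20,
                       ncol = 20)
  cubes0 <- simulate_slab_series(sc0)
  for (cb in cubes0[-1]) expect_equal(cb$data, cubes0[[1]]$data)

  sc <- phantom_scene("slab_series", mu_eff = 0.04, sigma = 0, nrow = 20,
                      ncol = 20)
  cubes <- simulate_slab_series(sc)
  b1073 <- nearest_band(cubes[[1]], 1073)
  means <- vapply(cubes, function(cb) mean(cb$data[, , b1073]), numeric(1))
  expect_true(all(diff(means) < 0))
  # doubling thickness squares the attenuation factor:
  # A(20) / A(10) = A(10), i.e. cube20 = cube10 * exp(-2 mu 10)
  expect_equal(cubes[["20"]]$data,
               cubes[["10"]]$data * exp(-2 * 0.04 * 10), tolerance = 1e-12)
  expect_equal(cubes[["40"]]$data,
               cubes[["20"]]$data * exp(-2 * 0.04 * 20), tolerance = 1e-12)
  expect_error(phantom_scene("slab_series", thicknesses_mm = c(10, 10)),
               "increasing")
})

test_that("embedded target mixes lipid by the two-way attenuation fraction", {
  sc <- phantom_scene("embedded_target", mu_eff = 0.05, depth_mm = 20,
                      sigma = 0, nrow = 30, ncol = 30, target_size = 10)
  sim <- simulate_embedded_target(sc)
  expect_equal(sim$truth$fraction, exp(-2), tolerance = 1e-12)
  expect_equal(sum(sim$truth$mask), 100L)  # configured block area

  # depth 0: target pixels equal the pure lipid spectrum
  sc0 <- phantom_scene("embedded_target", depth_mm = 0, sigma = 0,
                       nrow = 30, ncol = 30, target_size = 10)
  sim0 <- simulate_embedded_target(sc0)
  tgt_px <- which(sim0$truth$mask, arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(sim0$cube$data[tgt_px[1], tgt_px[2], ]),
               sim0$endmembers$lipid$reflectance, tolerance = 1e-12)
  # fraction requested directly converts to the equivalent depth
  scf <- phantom_scene("embedded_target", target_fraction = 0.05)
  expect_equal(exp(-2 * scf$mu_eff * scf$depth_mm), 0.05, tolerance = 1e-12)
  expect_error(phantom_scene("embedded_target", nrow = 20, ncol = 20,
                             target_size = 30), "bounds")
})

test_that("noiseless scenes lie exactly in the endmember convex hull", {
  sc <- phantom_scene("embedded_target", sigma = 0, nrow = 20, ncol = 20,
                      target_size = 6, depth_mm = 15)
  sim <- simulate_embedded_target(sc)
  f <- sim$truth$fraction
  lip <- sim$endmembers$lipid$reflectance
  col <- sim$endmembers$collagen$reflectance
  for (px in list(c(1, 1), c(10, 10))) {
    spec <- as.numeric(sim$cube$data[px[1], px[2], ])
    want <- if (sim$truth$mask[px[1], px[2]]) f * lip + (1 - f) * col else col
    expect_equal(spec, want, tolerance = 1e-12)
  }
  # concentration panels: every pixel is the stated convex combination
  scp <- phantom_scene("concentration_panels", sigma = 0, nrow = 6, ncol = 8)
  simp <- simulate_concentration_panels(scp)
  e2 <- simp$endmembers[[1]]$reflectance
  e5 <- simp$endmembers[[2]]$reflectance
  for (j in seq_len(8)) {
    a1 <- simp$truth$abundance[1, j, 1]
    expect_equal(as.numeric(simp$cube$data[1, j, ]),
                 a1 * e2 + (1 - a1) * e5, tolerance = 1e-12)
  }
})

test_that("panel ground truth abundances are exact and sum to one", {
  sc <- phantom_scene("concentration_panels", sigma = 0, nrow = 4, ncol = 8)
  sim <- simulate_concentration_panels(sc)
  sums <- sim$truth$abundance[, , 1] + sim$truth$abundance[, , 2]
  expect_true(all(abs(sums - 1) < 1e-12))
  # 5% panel is the pure second endmember; 4% panel splits (1/3, 2/3)
  p5 <- sim$truth$panel == 4L
  expect_true(all(sim$truth$abundance[, , 2][p5] == 1))
  p4 <- sim$truth$panel == 3L
  expect_true(all(abs(sim$truth$abundance[, , 1][p4] - 1 / 3) < 1e-12))
  expect_error(phantom_scene("concentration_panels", ncol = 3,
                             concentrations = c(2, 3, 4, 5)), "panel width")
})

test_that("wedge depth profile and lipid fraction behave as declared", {
  sc <- phantom_scene("sloped_wedge", mu_eff = 0.09, sigma = 0, nrow = 4,
                      ncol = 41, max_depth_mm = 40)
  sim <- simulate_sloped_wedge(sc)
  z <- sim$truth$depth_mm
  expect_equal(z[1], 0)
  expect_equal(z[length(z)], 40)
  expect_true(all(diff(z) > 0))
  expect_true(all(diff(sim$truth$fraction) < 0))
  expect_equal(sim$truth$fraction[length(z)], exp(-7.2), tolerance = 1e-12)
  # leftmost column is pure lipid
  expect_equal(as.numeric(sim$cube$data[1, 1, ]),
               sim$endmembers$lipid$reflectance, tolerance = 1e-12)
  expect_error(phantom_scene("sloped_wedge", ncol = 1), "2 columns")
  expect_error(phantom_scene("sloped_wedge", slope_deg = 95), "slope")
})

test_that("simulation is seed-deterministic with seed-independent truth", {
  sc <- phantom_scene("embedded_target", seed = 9, nrow = 16, ncol = 16,
                      target_size = 6)
  a <- simulate_embedded_target(sc)
  b <- simulate_embedded_target(sc)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$truth, b$truth)
  sc2 <- sc; sc2$seed <- 10L
  c2 <- simulate_embedded_target(sc2)
  expect_false(identical(a$cube$data, c2$cube$data))
  expect_identical(a$truth, c2$truth)
})
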