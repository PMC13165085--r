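test_that("trial row counts equal plants x days x pixels for the campaign designs", {
  # cardinality does not depend on band count, so use a coarse grid
  sc <- coarse_scenario(20)
  t24 <- generate_trial(trial_design(n_plants = 18, n_stress = 10, days = 1:5,
                                     pixels_per_plant_day = 10, seed = 1), sc)
  expect_identical(nrow(t24$spectra), 18L * 5L * 10L)
  expect_identical(nrow(t24$spectra), 900L)

  t25 <- generate_trial(trial_design(n_plants = 18, n_stress = 9, days = 1:7,
                                     pixels_per_plant_day = 100, seed = 1), sc)
  expect_identical(nrow(t25$spectra), 12600L)

  # property over assorted sizes
  for (args in list(c(3, 2, 4), c(5, 4, 2), c(1, 6, 3))) {
    tr <- generate_trial(trial_design(n_plants = args[1], n_stress = 0,
                                      days = seq_len(args[2]),
                                      pixels_per_plant_day = args[3], seed = 2), sc)
    expect_identical(nrow(tr$spectra), as.integer(prod(args)))
  }
})

test_that("same seed reproduces the trial exactly; different seed does not", {
  d <- tiny_design(seed = 42)
  sc <- coarse_scenario(30)
  a <- generate_trial(d, sc)
  b <- generate_trial(d, sc)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$psi, b$psi)
  c <- generate_trial(tiny_design(seed = 43), sc)
  expect_false(identical(a$spectra, c$spectra))
})

test_that("stressed plants deepen features monotonically from onset; controls are stationary", {
  d <- trial_design(n_plants = 2, n_stress = 1, days = 1:5,
                    pixels_per_plant_day = 3, seed = 5)
  sc <- coarse_scenario(80, stress_onset_day = 3, severity_ramp = 0.4)
  tr <- generate_trial(d, sc, noise = FALSE)
  wl <- spectrum_wavelengths(tr$spectra)
  water_band <- which.min(abs(wl - 970))
  depth_at <- function(pid, day) {
    rows <- tr$spectra$plant_id == pid & tr$spectra$day == day
    x <- spectrum_matrix(tr$spectra[rows, ])
    # well depth relative to the NIR shoulder just below 900 nm
    shoulder <- which.min(abs(wl - 890))
    mean(x[, shoulder] - x[, water_band])
  }
  stress_id <- tr$truth$plant_id[!is.na(tr$truth$onset_day)]
  control_id <- tr$truth$plant_id[is.na(tr$truth$onset_day)]
  depths <- vapply(1:5, function(day) depth_at(stress_id, day), numeric(1))
  expect_true(all(diff(depths[3:5]) > 0))       # monotone after onset
  expect_equal(depths[1], depths[2])            # flat before onset
  cdepths <- vapply(1:5, function(day) depth_at(control_id, day), numeric(1))
  expect_equal(diff(cdepths), rep(0, 4), tolerance = 1e-12)
})

test_that("zero severity makes stress and control draws share one generating distribution", {
  d <- trial_design(n_plants = 2, n_stress = 1, days = 1:4,
                    pixels_per_plant_day = 50, seed = 9)
  sc <- coarse_scenario(40, severity_ramp = 0)
  tr <- generate_trial(d, sc, noise = FALSE)
  x <- spectrum_matrix(tr$spectra)
  g <- tr$spectra$group
  # noise-free: identical expected spectra band by band
  expect_equal(colMeans(x[g == "stress", ]), colMeans(x[g == "control", ]),
               tolerance = 1e-12)
})

test_that("SNV removes the generator's illumination drift (noise off)", {
  d <- tiny_design(seed = 3, days = 1:4, px = 3)
  sc_drift <- coarse_scenario(50, illumination_drift = 0.3, severity_ramp = 0)
  # drift applies with noise = TRUE; make noise negligible instead of off
  sc_drift$noise_sd_vis <- 0
  tr <- generate_trial(d, sc_drift)
  x <- snv(spectrum_matrix(tr$spectra))
  # all of a control plant's days collapse onto the same SNV spectrum
  ctrl <- tr$spectra$group == "control"
  expect_lt(max(apply(x[ctrl, ], 2, sd)), 1e-10)
})

test_that("irrigation dose arithmetic matches the trial schedule", {
  expect_equal(irrigation_dose(28, 2.3, 1), 1.07)
  expect_equal(irrigation_dose(0, 2.3, 1), 0)
  # independently: 28/60 * 2.3 / 3 = 0.35777... -> 0.36
  expect_equal(irrigation_dose(28, 2.3, 1 / 3), 0.36)
  expect_error(irrigation_dose(-1, 2.3, 1), "non-negative")
  expect_error(irrigation_dose(28, 2.3, 1.5), "<= 1")
})

test_that("degenerate designs are rejected", {
  expect_error(trial_design(days = integer(0)), "non-empty")
  expect_error(trial_design(pixels_per_plant_day = 1), "covariance")
  expect_error(trial_design(days = c(1, 1, 2)), "ordered")
})

test_that("stem potentials are negative and stressed group diverges after psi onset", {
  d <- trial_design(n_plants = 10, n_stress = 5, days = 1:5,
                    pixels_per_plant_day = 2, seed = 11)
  sc <- coarse_scenario(20, stress_onset_day = 3)
  psi <- simulate_stem_potential(d, sc)
  expect_true(all(psi$psi_mpa < 0))
  m <- tapply(psi$psi_mpa, list(psi$day, psi$group), mean)
  expect_lt(m["5", "stress"], m["5", "control"] - 0.1)
  expect_lt(abs(m["1", "stress"] - m["1", "control"]), 0.15)
})

test_that("generated cubes honour the grid, round-trip the mask, and are seed-stable", {
  d <- tiny_design(seed = 2)
  sc <- spectral_scenario() # default grid
  out <- generate_cube(d, sc, "P01", 1, nrow = 16, ncol = 16)
  expect_identical(dim(out$cube)[3], 204L)
  out2 <- generate_cube(d, sc, "P01", 1, nrow = 16, ncol = 16)
  expect_identical(out$cube$data, out2$cube$data)
  # reflectance calibration recovers the scenario's leaf spectrum
  refl <- to_reflectance(out$cube, out$dark, out$white)
  leaf <- which(out$mask, arr.ind = TRUE)
  got <- colMeans(t(apply(leaf, 1, function(rc) refl$data[rc[1], rc[2], ])))
  expect_equal(unname(got), out$reflectance, tolerance = 0.02)
  expect_error(generate_cube(d, sc, "P99", 1), "unknown plant")
  expect_error(generate_cube(d, sc, "P01", 9), "unknown day")
  expect_error(generate_cube(d, sc, "P01", 1, nrow = 8, ncol = 8,
                             mask = matrix(FALSE, 8, 8)), "no vegetation")
})
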