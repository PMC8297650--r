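# Spectra, photon conversion, action-spectrum weighting and dose arithmetic.

test_that("gaussian LED spectrum is normalized, peaked and linear in total", {
  s1 <- gaussian_led_spectrum(310, 10, 1.0)
  expect_equal(band_integrate(s1, bands()$UV), 1.0, tolerance = 1e-6)
  expect_equal(s1$wavelength_nm[which.max(s1$irradiance_W_m2_nm)], 310)
  s2 <- gaussian_led_spectrum(310, 10, 2.0)
  expect_equal(band_integrate(s2, bands()$UV) /
                 band_integrate(s1, bands()$UV), 2.0, tolerance = 1e-9)
  expect_error(gaussian_led_spectrum(310, 0, 1), "fwhm")
})

test_that("band integration handles flat spectra, additivity and no overlap", {
  flat <- spectrum(seq(300, 400, 1), rep(0.01, 101))
  expect_equal(band_integrate(flat, band(300, 400)), 1.0, tolerance = 1e-12)
  lo <- band_integrate(flat, band(300, 350))
  hi <- band_integrate(flat, band(350, 400))
  expect_equal(lo + hi, band_integrate(flat, band(300, 400)),
               tolerance = 1e-12)
  zero <- spectrum(c(300, 400), c(0, 0))
  expect_equal(band_integrate(zero, band(300, 400)), 0)
  expect_warning(v <- band_integrate(flat, band(500, 600)), "overlap")
  expect_equal(v, 0)
})

test_that("photon flux matches direct evaluation of E*lambda/(h c N_A)", {
  # hand evaluation with exact SI constants: 1 W m-2 at 310 nm
  expect_equal(photon_flux(1.0, 310), 2.5914, tolerance = 1e-4)
  expect_equal(photon_flux(0, 310), 0)
  # linear in irradiance and wavelength
  expect_equal(photon_flux(3, 310), 3 * photon_flux(1, 310))
  expect_equal(photon_flux(1, 620), 2 * photon_flux(1, 310))
  expect_error(photon_flux(1, -5), "wavelength")
})

test_that("UV-B to PAR photon ratio at source settings is 1.3%", {
  ratio <- photon_flux(1.0, 310) / 200 * 100
  expect_equal(signif(ratio, 2), 1.3)
})

test_that("plant action spectrum: normalization point, cutoff, 310 nm value", {
  expect_equal(plant_action_spectrum(300), 1.0)
  expect_equal(plant_action_spectrum(313.3), 0)
  expect_equal(plant_action_spectrum(350), 0)
  # closed form at 310 nm, normalized at 300 nm
  expect_equal(plant_action_spectrum(310), 0.18279, tolerance = 1e-4)
  expect_true(all(plant_action_spectrum(seq(250, 400, 0.5)) >= 0))
})

test_that("be_factor: monochromatic 300 nm ~ 1, above-cutoff spectrum -> 0", {
  mono <- gaussian_led_spectrum(300, 0.05, 1.0, range = c(299, 301),
                                step = 0.005)
  expect_equal(be_factor(mono), 1.0, tolerance = 1e-3)
  above <- gaussian_led_spectrum(350, 5, 1.0, range = c(320, 400))
  expect_equal(be_factor(above), 0)
  expect_equal(calibrate_be_factor(21.6, 2.1), 2.1 / 21.6)
  expect_error(calibrate_be_factor(0, 1), "positive")
})

test_that("cumulative dose arithmetic is linear and reproduces both ends", {
  expect_equal(cumulative_dose(1.0, exposure_schedule(6, 1)), 21.6)
  expect_equal(cumulative_dose(1.0, exposure_schedule(12, 3)), 129.6)
  expect_equal(cumulative_dose(1.0, exposure_schedule(6, 0)), 0)
  # linearity in irradiance, hours, days
  expect_equal(cumulative_dose(2.0, exposure_schedule(6, 1)),
               2 * cumulative_dose(1.0, exposure_schedule(6, 1)))
  expect_equal(cumulative_dose(1.0, exposure_schedule(12, 1)),
               2 * cumulative_dose(1.0, exposure_schedule(6, 1)))
  expect_equal(cumulative_dose(1.0, exposure_schedule(6, 3)),
               3 * cumulative_dose(1.0, exposure_schedule(6, 1)))
  # inverse relation
  expect_equal(effective_irradiance(21.6, exposure_schedule(6, 1)), 1.0)
})

test_that("dose summary ties weighted and unweighted doses by the factor", {
  bef <- calibrate_be_factor(21.6, 2.1)
  for (s in treatment_grid()) {
    d <- dose_summary(1.0, s, bef)
    expect_equal(d$be_kJ_m2, bef * d$unweighted_kJ_m2, tolerance = 1e-9)
  }
})

test_that("treatment grid enumerates the six schedules with correct ordering", {
  grid <- treatment_grid()
  expect_length(grid, 6)
  expect_true("2 d 12 h" %in% names(grid))
  doses <- vapply(grid, function(s) cumulative_dose(1.0, s), numeric(1))
  expect_equal(unname(doses[c("1 d 6 h", "1 d 12 h", "2 d 6 h", "2 d 12 h",
                              "3 d 6 h", "3 d 12 h")]),
               c(21.6, 43.2, 43.2, 86.4, 64.8, 129.6))
  ord <- sort(doses)
  expect_equal(unname(ord[1]), 21.6)
  expect_equal(unname(ord[6]), 129.6)
})

test_that("spectrum CSV round trips", {
  s <- gaussian_led_spectrum(310, 10, 1.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$irradiance_W_m2_nm, s$irradiance_W_m2_nm, tolerance = 1e-12)
})

test_that("daily light integral reproduces the growth-light value", {
  expect_equal(daily_light_integral(200, 16), 11.52)
})
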