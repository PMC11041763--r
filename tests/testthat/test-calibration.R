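# Two-endmember Stern-Volmer calibration and inversion

test_that("uniform endmembers give the closed-form Ksv", {
  # F_anoxic = 2, F_air = 1, saturation 200 => Ksv = (2/1 - 1)/200 = 1/200
  g <- disk_geometry(64, 25, 10)
  an <- matrix(2, 64, 64); air <- matrix(1, 64, 64)
  cal <- fit_calibration(an, air, g, n_zones = 1, o2_saturation = 200)
  expect_equal(cal$Ksv, 1 / 200)
  expect_true(all(cal$ok))
})

test_that("render round trip recovers Ksv exactly without noise, within 2% with", {
  s <- small_scene(n_frames = 2, n_colonies = 0, n_diatoms = 0, seed = 3)
  cal <- fit_calibration(s$calib_anoxic, s$calib_air, s$geometry,
                         n_zones = 20, o2_saturation = 250)
  expect_equal(cal$Ksv, rep(0.012, 20), tolerance = 1e-12)
  sN <- small_scene(n_frames = 2, n_colonies = 0, n_diatoms = 0, seed = 3,
                    noise_sd = 0.01)
  calN <- fit_calibration(sN$calib_anoxic, sN$calib_air, sN$geometry,
                          n_zones = 20, o2_saturation = 250)
  expect_lt(max(abs(calN$Ksv - 0.012) / 0.012), 0.02)
})

test_that("degenerate endmembers fail loudly", {
  g <- disk_geometry(64, 25, 10)
  an <- matrix(1, 64, 64)
  expect_error(fit_calibration(an, an, g, n_zones = 3, o2_saturation = 200),
               "every zone")
  # an empty annulus is an error, not a silent skip
  expect_error(fit_calibration(matrix(2, 64, 64), matrix(1, 64, 64), g,
                               n_zones = 5000, o2_saturation = 200),
               "no pixels")
})

test_that("endmember frames invert to the endmember concentrations", {
  g <- disk_geometry(64, 25, 10)
  an <- matrix(2, 64, 64); air <- matrix(1, 64, 64)
  cal <- fit_calibration(an, air, g, n_zones = 4, o2_saturation = 200)
  C0 <- fluorescence_to_oxygen(an, cal, g)
  expect_true(all(C0[g$mask == 1] == 0))
  Cs <- fluorescence_to_oxygen(air, cal, g)
  expect_true(all(Cs[g$mask == 1] == 200))
  expect_true(all(is.na(Cs[g$mask == 0])))
  # hand inversion: F = 4/3 with F_anoxic = 2, Ksv = 1/200 => C = 100
  Ch <- fluorescence_to_oxygen(matrix(4 / 3, 64, 64), cal, g)
  expect_equal(unique(Ch[g$mask == 1]), 100, tolerance = 1e-10)
})

test_that("the inversion is monotone decreasing in fluorescence", {
  g <- disk_geometry(64, 25, 10)
  cal <- fit_calibration(matrix(2, 64, 64), matrix(1, 64, 64), g,
                         n_zones = 1, o2_saturation = 200)
  Fs <- seq(1, 2, by = 0.05)
  Cs <- sapply(Fs, function(f)
    fluorescence_to_oxygen(matrix(f, 64, 64), cal, g)[round(g$center[1]),
                                                      round(g$center[2])])
  expect_true(all(diff(Cs) < 0))
})

test_that("non-positive fluorescence pixels are masked and counted", {
  g <- disk_geometry(64, 25, 10)
  cal <- fit_calibration(matrix(2, 64, 64), matrix(1, 64, 64), g,
                         n_zones = 1, o2_saturation = 200)
  f <- matrix(1.5, 64, 64)
  ctr <- round(g$center)
  f[ctr[1], ctr[2]] <- -1
  expect_message(C <- fluorescence_to_oxygen(f, cal, g), "masked 1")
  expect_true(is.na(C[ctr[1], ctr[2]]))
  expect_equal(attr(C, "masked_pixels"), 1)
})

test_that("oxygen categories use strict thresholds with exclusive boundaries", {
  expect_equal(as.character(classify_oxygen(0.5)), "nanoxic")
  expect_equal(as.character(classify_oxygen(7)), "microoxic")
  expect_equal(as.character(classify_oxygen(40)), "oxic") # boundary exclusive
  expect_equal(as.character(classify_oxygen(c(0, 1, 4.9, 5, 9.9, 10, 39.9))),
               c("nanoxic", "suboxic", "suboxic", "microoxic", "microoxic",
                 "hypoxic", "hypoxic"))
  expect_error(classify_oxygen(-1), ">= 0")
  # category counts nest: everything below 1 is also below 5, 10, 40
  set.seed(1)
  x <- runif(500, 0, 300)
  n <- sapply(c(1, 5, 10, 40), function(th) sum(x < th))
  expect_true(all(diff(n) >= 0))
})

test_that("round trip recovers the true oxygen field (RMSE < 2 umol/L)", {
  s <- small_scene(n_frames = 4, n_colonies = 5, n_diatoms = 0, seed = 9)
  cal <- fit_calibration(s$calib_anoxic, s$calib_air, s$geometry,
                         n_zones = 20, o2_saturation = 250)
  o2 <- fluorescence_to_oxygen(s$sensor[, , 4], cal, s$geometry)
  err <- (o2 - s$truth$o2[, , 4])[s$geometry$mask == 1]
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 2)
})
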