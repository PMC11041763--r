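# Depth translation, growth phases, oxygen exposure

test_that("time translates to depth linearly at the imposed sinking speed", {
  expect_equal(depth_from_time(100, 4.8), 20)
  expect_equal(depth_from_time(200, 4.8), 40)
  expect_equal(depth_from_time(0, 7), 0)
  expect_error(depth_from_time(-1), ">= 0")
  # linearity: depth(a + b) = depth(a) + depth(b)
  set.seed(2)
  a <- runif(20, 0, 300); b <- runif(20, 0, 300)
  expect_equal(depth_from_time(a + b), depth_from_time(a) + depth_from_time(b))
})

test_that("device physics helpers give the expected magnitudes", {
  expect_equal(daily_throughflow_mL(0.01), 14.4)
  expect_lte(daily_throughflow_mL(0.01), 15)
  expect_equal(round(diffusive_flush_min(1.5e-3, 1.9e-9)), 20)
})

test_that("a diauxic track decomposes into exp1 / lag / exp2", {
  set.seed(5)
  t <- 0:120
  g <- diauxic_growth(mu1 = 0.05, lag_start_h = 50, lag_duration_h = 30,
                      mu2 = 0.04, area0_um2 = 100, area_max_um2 = Inf)
  obs <- data.frame(time_h = t,
                    area_um2 = colony_area_at(g, t) * exp(rnorm(121, 0, 0.03)))
  f <- fit_growth_phases(obs)
  expect_setequal(intersect(f$segments$phase, c("exp1", "lag", "exp2")),
                  c("exp1", "lag", "exp2"))
  expect_equal(f$lag_start_h, 50, tolerance = 2)
  expect_equal(f$lag_duration_h, 30, tolerance = 4)
  expect_equal(f$lag_duration_m, 6, tolerance = 0.8)
  expect_equal(f$mu1, 0.05, tolerance = 0.01)
  expect_equal(f$mu2, 0.04, tolerance = 0.01)
})

test_that("a single-exponential track has no lag segment", {
  t <- 0:40
  obs <- data.frame(time_h = t, area_um2 = 100 * exp(0.05 * t))
  f <- fit_growth_phases(obs)
  expect_true(is.na(f$lag_duration_h))
  expect_false(any(f$segments$phase == "lag"))
})

test_that("short tracks are flagged and excluded from lag statistics", {
  obs <- data.frame(time_h = 0:5, area_um2 = 100 * exp(0.05 * (0:5)))
  f <- fit_growth_phases(obs)
  expect_equal(f$flagged, "too_short")
  tr <- as_tracks(make_track(1, 0:5, 100 * exp(0.05 * (0:5))),
                  make_track(2, 0:80, colony_area_at(
                    diauxic_growth(0.05, 40, 20, 0.04, 100, Inf), 0:80)))
  ls <- lag_statistics(tr)
  expect_equal(ls$n_fitted, 1)
  expect_gte(ls$n_excluded, 1)
})

test_that("zero and below-detection areas are treated as missing", {
  t <- 0:60
  a <- 100 * exp(0.05 * t)
  a[c(10, 30)] <- 0
  f <- fit_growth_phases(data.frame(time_h = t, area_um2 = a))
  expect_false(any(f$segments$phase == "lag"))
  expect_equal(f$mu1, 0.05, tolerance = 0.01)
})

test_that("population lag recovery is close to the generating distribution", {
  tr <- simulate_colony_tracks(n_tracks = 60, n_frames = 200, seed = 23)
  truth <- attr(tr, "truth")
  ls <- lag_statistics(tr)
  true_mean_m <- mean(truth$lag_duration_h) * 4.8 / 24
  expect_lt(abs(ls$mean_m - true_mean_m) / true_mean_m, 0.10)
  expect_equal(ls$n_fitted, 60)
})

test_that("oxygen exposure fractions are nested and handle the edge cases", {
  # uniform 20 umol/L: below 40, not below 10
  f <- oxygen_exposure_fractions(rep(20, 10))
  expect_equal(unname(f), c(1, 0, 0, 0))
  # half at 0.5, half at 200: every fraction is one half
  f2 <- oxygen_exposure_fractions(c(0.5, 200), weights = c(5, 5))
  expect_equal(unname(f2), c(0.5, 0.5, 0.5, 0.5))
  # empty frame: missing, not zero
  expect_true(all(is.na(oxygen_exposure_fractions(numeric(0)))))
  # nesting holds for arbitrary fields
  set.seed(8)
  for (i in 1:20) {
    x <- runif(50, 0, 300)
    fr <- oxygen_exposure_fractions(x, thresholds = c(1, 5, 10, 40))
    expect_true(all(diff(unname(fr)) >= 0))
  }
})

test_that("exposure fractions match a brute-force pixel count on a real field", {
  g <- disk_geometry(96, 40, 10)
  sinks <- matrix(0, 96, 96)
  ctr <- round(g$center)
  sinks[(ctr[1] - 6):(ctr[1] + 6), (ctr[2] - 6):(ctr[2] + 6)] <- 30
  C <- simulate_oxygen_field(g, sinks, boundary = 45)
  labels <- matrix(0L, 96, 96)
  labels[(ctr[1] - 6):(ctr[1] + 6), (ctr[2] - 6):(ctr[2] + 6)] <- 1L
  vals <- C[labels > 0]
  fr <- oxygen_exposure_fractions(vals)
  for (i in seq_along(c(40, 10, 5, 1))) {
    th <- c(40, 10, 5, 1)[i]
    expect_equal(unname(fr[i]), sum(vals < th) / length(vals))
  }
})

test_that("particle mean oxygen series averages colony medians", {
  tr <- as_tracks(make_track(1, 0:4, rep(1000, 5), o2 = rep(145, 5)))
  s <- particle_mean_o2_series(tr)
  expect_equal(s$mean_o2, rep(145, 5))
  tr2 <- as_tracks(make_track(1, 0:4, rep(1000, 5), o2 = rep(100, 5)),
                   make_track(2, 0:4, rep(1000, 5), o2 = rep(200, 5)))
  s2 <- particle_mean_o2_series(tr2)
  expect_equal(s2$mean_o2, rep(150, 5))
  # replicates: mean of per-particle series with spread
  s3 <- particle_mean_o2_series(list(tr, tr2))
  expect_equal(s3$mean_o2, rep(147.5, 5))
  expect_equal(s3$n, rep(2L, 5))
})
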