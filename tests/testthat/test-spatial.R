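# Radial profiles, expression peaks, chemistry depth profiles

test_that("radial biomass profile conserves area and matches a recount", {
  g <- disk_geometry(101, 45, 10)
  set.seed(4)
  d <- runif(30, 0, 440); a <- runif(30, 100, 5000)
  tr <- do.call(as_tracks, lapply(1:30, function(i)
    make_track(i, 0:3, rep(a[i], 4), dist = rep(d[i], 4))))
  prof <- radial_biomass_profile(tr, g, n_bins = 9)
  expect_equal(sum(prof$total_area_um2), sum(a))
  expect_equal(sum(prof$n_colonies), 30)
  # recount oracle
  edges <- seq(0, g$equivalent_radius_um, length.out = 10)
  for (z in 1:9) {
    sel <- d >= edges[z] & d < edges[z + 1]
    if (z == 9) sel <- d >= edges[z] & d <= edges[z + 1]
    expect_equal(prof$n_colonies[z], sum(sel))
  }
  # mean size x count sums back to total area
  ok <- prof$n_colonies > 0
  expect_equal(sum(prof$mean_area_um2[ok] * prof$n_colonies[ok]), sum(a))
})

test_that("all colonies at one distance fill a single bin", {
  g <- disk_geometry(101, 45, 10)
  tr <- do.call(as_tracks, lapply(1:5, function(i)
    make_track(i, 0:2, rep(500, 3), dist = rep(120, 3))))
  prof <- radial_biomass_profile(tr, g, n_bins = 9)
  expect_equal(sum(prof$n_colonies > 0), 1)
  expect_equal(prof$total_area_um2[prof$n_colonies > 0], 2500)
})

test_that("the colony radial pdf integrates to one and finds point masses", {
  g <- disk_geometry(301, 145, 10)
  set.seed(6)
  k <- colony_radial_pdf(runif(500, 0, 1400), g)
  dx <- k$distance_um[2] - k$distance_um[1]
  integral <- sum((k$density[-1] + k$density[-nrow(k)]) / 2) * dx
  expect_equal(integral, 1, tolerance = 1e-6)
  # two colonies at 100 um: mode at 100 um
  k2 <- colony_radial_pdf(c(100, 100), g, bandwidth = 20)
  expect_equal(k2$distance_um[which.max(k2$density)], 100, tolerance = 5)
  expect_error(colony_radial_pdf(100, g), "degenerate|two")
})

test_that("a uniform placement gives a flat density away from the far boundary", {
  g <- disk_geometry(301, 145, 10)
  set.seed(9)
  k <- colony_radial_pdf(runif(4000, 0, 1400), g, bandwidth = 40)
  mid <- k$density[k$distance_um > 150 & k$distance_um < 1200]
  expect_lt(max(abs(mid - 1 / 1400)) / (1 / 1400), 0.15)
})

test_that("synthetic expression rings are recovered at their true radius", {
  g <- disk_geometry(201, 90, 10) # R = 900 um
  img <- render_expression_ring(g, 300, 50)
  p <- expression_radial_profile(img, g, channel = "NarK")
  expect_equal(p$peak_mean_um, 300, tolerance = 5)
  # density integrates to one
  dx <- diff(p$profile$distance_um[1:2])
  expect_equal(sum(p$profile$density) * dx, 1, tolerance = 1e-6)
})

test_that("expression peak recovery is unbiased within half a bin width", {
  g <- disk_geometry(201, 90, 10)
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    img <- render_expression_ring(g, 250, 40, noise_sd = 0.01)
    expression_radial_profile(img, g)$peak_mean_um - 250
  }, numeric(1))
  expect_lt(abs(mean(errs)), 5)
})

test_that("uniform expression puts the weighted median at the half-signal bin", {
  g <- disk_geometry(201, 90, 10)
  img <- matrix(0.02, 201, 201)
  img[g$mask == 1] <- 1
  p <- expression_radial_profile(img, g, bin_width_um = 10)
  # cumulative-sum oracle over the per-bin weights
  w <- p$profile$density / sum(p$profile$density)
  oracle <- p$profile$distance_um[which(cumsum(w) >= 0.5)[1]]
  expect_equal(p$peak_median_um, oracle)
})

test_that("diatom pixels are excluded from expression profiles", {
  g <- disk_geometry(201, 90, 10)
  img <- render_expression_ring(g, 300, 50)
  dia <- matrix(0, 201, 201)
  sel <- g$mask == 1 & g$distance_to_edge_um < 100
  dia[sel] <- 1
  img2 <- img; img2[sel] <- 5 # bright chlorophyll contamination
  p <- expression_radial_profile(img2, g, diatom_mask = dia)
  expect_equal(p$peak_mean_um, 300, tolerance = 6)
  expect_error(expression_radial_profile(matrix(0, 201, 201), g), "no signal")
})

test_that("chemistry series map onto depth and average replicates", {
  ch <- simulate_bulk_chemistry("broken")
  pr <- chemistry_depth_profile(ch, 4.8)
  expect_equal(pr$depth_m[pr$time_h == 96], 19.2)
  expect_equal(pr$doc_mg_L[1], 28.0)
  # constant series stay flat
  const <- data.frame(time_h = c(0, 24, 48), doc_mg_L = 5,
                      no3_umol_L = 10, no2_umol_L = 0)
  expect_equal(unique(chemistry_depth_profile(const)$doc_mg_L), 5)
  # replicates
  reps <- do.call(rbind, lapply(1:3, function(r)
    transform(simulate_bulk_chemistry("intact",
                                      noise_sd_doc = 0.5, seed = r),
              replicate = r)))
  prr <- chemistry_depth_profile(reps)
  expect_true(all(c("doc_mg_L", "doc_mg_L_sd") %in% names(prr)))
  expect_equal(nrow(prr), 14)
  # hours -> days commutes with the depth mapping
  expect_equal(depth_from_time(48, 4.8), 4.8 * 2)
  bad <- data.frame(time_h = c(0, 48, 24), doc_mg_L = 1,
                    no3_umol_L = 1, no2_umol_L = 0)
  expect_error(chemistry_depth_profile(bad), "monotone")
})

test_that("condition comparison is a Welch test with the expected symmetries", {
  expect_equal(compare_conditions(c(1, 1, 1), c(1, 1, 1)),
               list(t = 0, df = 4, p = 1))
  set.seed(7)
  a <- c(1, 1, 1) + rnorm(3, 0, 1e-6)
  b <- c(2, 2, 2) + rnorm(3, 0, 1e-6)
  r <- compare_conditions(a, b)
  expect_lt(r$p, 0.01)
  r2 <- compare_conditions(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(compare_conditions(1, c(1, 2)), "two values")
})
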