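# Synthetic-scene generator

test_that("a fixed seed renders a bit-identical scene; seeds differ", {
  cfg <- scene_config(pixel_size_um = 20, n_frames = 3, n_colonies = 3,
                      n_diatoms = 3, noise_sd = 0.01, rng_seed = 42)
  s1 <- render_scene(cfg, store_o2 = FALSE)
  s2 <- render_scene(cfg, store_o2 = FALSE)
  expect_identical(s1$brightfield, s2$brightfield)
  expect_identical(s1$sensor, s2$sensor)
  expect_identical(s1$calib_anoxic, s2$calib_anoxic)
  cfg2 <- scene_config(pixel_size_um = 20, n_frames = 3, n_colonies = 3,
                       n_diatoms = 3, noise_sd = 0.01, rng_seed = 43)
  s3 <- render_scene(cfg2, store_o2 = FALSE)
  expect_false(identical(s1$sensor, s3$sensor))
})

test_that("without colonies or noise every sensor frame is the air endmember", {
  cfg <- scene_config(pixel_size_um = 20, n_frames = 3, n_colonies = 0,
                      n_diatoms = 3, noise_sd = 0, rng_seed = 1)
  s <- render_scene(cfg, store_o2 = FALSE)
  for (t in 1:3)
    expect_equal(s$sensor[, , t], s$calib_air, tolerance = 1e-12)
})

test_that("ground-truth areas follow the diauxic law (doubling time ln2/mu)", {
  g <- diauxic_growth(mu1 = 0.05, lag_start_h = 1e6, lag_duration_h = 0,
                      mu2 = 0, area0_um2 = 100, area_max_um2 = Inf)
  td <- log(2) / 0.05 # ~13.9 h
  expect_equal(colony_area_at(g, td), 200, tolerance = 1e-10)
  expect_equal(colony_area_at(g, 2 * td) / colony_area_at(g, td), 2,
               tolerance = 1e-10)
  # lag freezes growth, second phase resumes at mu2
  g2 <- diauxic_growth(mu1 = 0.05, lag_start_h = 10, lag_duration_h = 5,
                       mu2 = 0.02, area0_um2 = 100, area_max_um2 = Inf)
  expect_equal(colony_area_at(g2, 15), colony_area_at(g2, 10))
  expect_equal(colony_area_at(g2, 20) / colony_area_at(g2, 15),
               exp(0.02 * 5), tolerance = 1e-10)
})

test_that("rendered label maps agree with the stored ground-truth areas", {
  s <- small_scene(n_frames = 4, n_colonies = 4, seed = 5)
  for (t in 1:4) {
    counts <- tabulate(s$truth$labels[, , t], nbins = 4)
    expect_equal(counts, unname(s$truth$areas_px2[, t]))
  }
  # colony masks stay inside the particle
  expect_true(all(s$geometry$mask[s$truth$labels[, , 4] > 0] == 1))
})

test_that("explicit colony positions outside the particle are rejected", {
  pos <- cbind(c(1490), c(0)) # 10 um from the edge: cannot fit
  expect_error(render_scene(scene_config(
    pixel_size_um = 20, n_frames = 2, n_colonies = 1, n_diatoms = 0,
    colony_seed_positions = pos, rng_seed = 1)), "outside|rim")
})

test_that("the sensor transform is strictly decreasing in oxygen", {
  Ksv <- 0.012
  C <- seq(0, 300, by = 10)
  F <- 1 / (1 + Ksv * C)
  expect_true(all(diff(F) < 0))
})

test_that("bulk chemistry anchors and positivity", {
  br <- simulate_bulk_chemistry("broken")
  it <- simulate_bulk_chemistry("intact")
  expect_equal(br$doc_mg_L[1], 28.0)
  expect_equal(it$doc_mg_L[1], 14)
  expect_gt(br$doc_mg_L[1], it$doc_mg_L[1]) # broken leaks more initially
  for (d in list(br, it))
    expect_true(all(unlist(d[, -1]) >= 0))
  # broken decays faster than intact (flatter efflux)
  rel_drop <- function(d) (d$doc_mg_L[1] - d$doc_mg_L[5]) / d$doc_mg_L[1]
  expect_gt(rel_drop(br), rel_drop(it))
  expect_error(simulate_bulk_chemistry("shaken"), "arg")
  # early nitrite pulse in broken vs later peak in intact
  expect_lt(which.max(br$no2_umol_L), which.max(it$no2_umol_L) + 1)
})

test_that("noisy chemistry is reproducible from its seed and stays non-negative", {
  a <- simulate_bulk_chemistry("broken", noise_sd_doc = 1, noise_sd_no2 = 0.001,
                               seed = 9)
  b <- simulate_bulk_chemistry("broken", noise_sd_doc = 1, noise_sd_no2 = 0.001,
                               seed = 9)
  expect_identical(a, b)
  expect_true(all(a$no2_umol_L >= 0))
})

test_that("scene configs round-trip through YAML", {
  cfg <- scene_config(pixel_size_um = 20, n_frames = 5, n_colonies = 2,
                      growth_law = diauxic_growth(mu1 = 0.07))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_size_um = 20, n_frames = 5, n_colonies = 2,
                        growth_law = list(mu1 = 0.07)), path)
  cfg2 <- read_scene_config(path)
  expect_equal(cfg2$n_frames, 5L)
  expect_equal(cfg2$growth_law$mu1, 0.07)
  expect_equal(cfg2$particle_radius_um, cfg$particle_radius_um)
})
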