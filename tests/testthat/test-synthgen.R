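test_that("scene truth conserves planted counts", {
  sc <- tem_scene(n_chains = 2, spores_per_chain = 12, seed = 1)
  expect_equal(nrow(sc$truth$spores), 24)
  expect_equal(nrow(sc$truth$septa), 2 * 11)
})

test_that("identical spec and seed give bit-identical scenes", {
  sp <- scene_spec(n_chains = 1, spores_per_chain = 8,
                   septum_rotation_prob = 0.4, split_prob = 0.2,
                   dead_prob = 0.3, seed = 77)
  a <- make_spore_chain_scene(sp)
  b <- make_spore_chain_scene(sp)
  expect_identical(a$channels$tem$values, b$channels$tem$values)
  expect_identical(a$channels$dna$values, b$channels$dna$values)
  expect_identical(a$truth, b$truth)
})

test_that("planted septum rotation fraction matches the probability at scale", {
  p <- 336 / 1479
  sc <- tem_scene(n_chains = 87, spores_per_chain = 18, pixel_size = 0.25,
                  septum_rotation_prob = p, seed = 5)
  tr <- sc$truth$septa
  expect_equal(nrow(tr), 1479)
  frac <- mean(tr$angle_deg >= 10)
  se_bin <- sqrt(p * (1 - p) / nrow(tr))
  expect_lt(abs(frac - p), 4 * se_bin)
  # class labels are the deterministic function of the planted angle
  expect_identical(tr$class, classify_septum_angle(tr$angle_deg))
})

test_that("truth-table fractions track dead/split probabilities", {
  sc <- tem_scene(n_chains = 40, spores_per_chain = 20, pixel_size = 0.25,
                  dead_prob = 0.35, split_prob = 0.1, seed = 6)
  sp <- sc$truth$spores
  expect_lt(abs(mean(!sp$viable) - 0.35), 4 * sqrt(0.35 * 0.65 / 800))
  expect_lt(abs(mean(sp$split) - 0.1), 4 * sqrt(0.1 * 0.9 / 800))
})

test_that("physical ground truth is independent of the rendering resolution", {
  a <- tem_scene(n_chains = 2, spores_per_chain = 10, pixel_size = 0.05,
                 septum_rotation_prob = 0.3, seed = 9)
  b <- tem_scene(n_chains = 2, spores_per_chain = 10, pixel_size = 0.1,
                 septum_rotation_prob = 0.3, seed = 9)
  expect_equal(a$truth$spores$x_um, b$truth$spores$x_um)
  expect_equal(a$truth$septa$angle_deg, b$truth$septa$angle_deg)
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(pixel_size = -1), "pixel_size")
  expect_error(scene_spec(septum_rotation_prob = 1.5), "probabilities")
  expect_error(scene_spec(rotated_angle_range = c(5, 90)), "rotated_angle_range")
  expect_error(scene_spec(image_shape = c(0, 10)), "image_shape")
  expect_error(scene_spec(dna_content = -2), "dna_content")
})

test_that("noiseless FRAP traces hit the model endpoints and e-fold identity", {
  # recovery_time is tau * ln 20; pick tau = 10 s so t = tau is a sample
  tau <- 10
  tr <- simulate_frap_trace(frap_spec(plateau = 1, bleach_depth = 0,
                                      recovery_time = tau * log(20),
                                      sampling_interval = 2, duration = 100,
                                      noise_sd = 0))[[1]]
  expect_equal(tr$intensity[tr$time_s == 0], 0)
  expect_equal(tr$intensity[tr$time_s == tau], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(tail(tr$intensity, 1), 1, tolerance = exp(-100 / tau) * 1.01)
})

test_that("FRAP noise has the planted standard deviation", {
  spec <- frap_spec(recovery_time = 60, noise_sd = 0.05, n_traces = 200,
                    seed = 3)
  noiseless <- simulate_frap_trace(frap_spec(recovery_time = 60,
                                             noise_sd = 0))[[1]]$intensity
  res <- unlist(lapply(simulate_frap_trace(spec),
                       function(tr) tr$intensity - noiseless))
  expect_equal(sd(res), 0.05, tolerance = 0.05)
})

test_that("FRAP spec validation catches impossible protocols", {
  expect_error(frap_spec(duration = 1, sampling_interval = 2), "duration")
  expect_error(frap_spec(recovery_time = -5), "recovery_time")
  expect_error(frap_spec(bleach_depth = 2, plateau = 1), "bleach_depth")
})

test_that("colony stack defaults cover 7 days at 30 min and follow trajectories", {
  spec <- colony_spec(noise_sd = 0)
  expect_equal(spec$n_frames, 7 * 48 + 1)
  cs <- make_colony_stack(colony_spec(n_frames = 20, noise_sd = 0,
                                      classes = c("white", "grey")))
  expect_equal(max(cs$times_min), 19 * 30)
  tr_w <- roi_mean_series(cs, c(cs$colonies$x_px[1], cs$colonies$y_px[1]),
                          cs$colonies$roi_radius[1])
  expect_equal(tr_w$values, cs$spec$grey_trajectory$white[1:20],
               tolerance = 1e-12)
  # constant trajectory: every frame equals the constant
  flat <- make_colony_stack(colony_spec(n_frames = 5, noise_sd = 0,
    grey_trajectory = list(white = rep(120, 5)), classes = "white"))
  tr <- roi_mean_series(flat, c(flat$colonies$x_px[1], flat$colonies$y_px[1]),
                        flat$colonies$roi_radius[1])
  expect_true(all(tr$values == 120))
  expect_error(colony_spec(grey_trajectory = list()), "trajectory")
})
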