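test_that("upscaling preserves physical extent and constants", {
  g <- pixel_grid(matrix(runif(200 * 300), 200, 300), 0.1)
  expect_identical(upscale_image(g, n_steps = 0), g)
  up <- upscale_image(g)
  # cumulative linear factor ~ 1.05^20 = 2.653, up to per-step rounding
  expect_equal(nrow(up$values) / 200, 1.05^20, tolerance = 0.02)
  expect_equal(ncol(up$values) / 300, 1.05^20, tolerance = 0.02)
  # total imaged area is exactly preserved by the calibration
  expect_equal(prod(dim(up$values)) * up$pixel_size^2,
               200 * 300 * 0.1^2, tolerance = 1e-12)
  # bilinear interpolation of a constant is the constant
  k <- upscale_image(pixel_grid(matrix(3.7, 12, 9), 0.1))
  expect_true(all(abs(k$values - 3.7) < 1e-12))
})

test_that("Sobel magnitude matches the hand-applied kernel on a step", {
  h <- 13
  v <- cbind(matrix(0, 8, 4), matrix(h, 8, 4))
  e <- find_edges(pixel_grid(v, 0.1))
  # ideal vertical step: |Gx| = (1+2+1) h on both adjacent columns
  expect_equal(max(e$values), 4 * h)
  expect_equal(e$values[4, 4], 4 * h)
  expect_equal(e$values[4, 5], 4 * h)
  expect_true(all(e$values[, c(1:2, 7:8)] == 0))
  # constant image: zero everywhere (replicated borders add no edges)
  expect_true(all(find_edges(pixel_grid(matrix(5, 10, 10), 0.1))$values == 0))
  # magnitude is symmetric under transposition
  r <- matrix(runif(120), 10, 12)
  expect_equal(t(find_edges(pixel_grid(r, 0.1))$values),
               find_edges(pixel_grid(t(r), 0.1))$values)
})

test_that("intermeans threshold matches brute-force fixed-point oracle", {
  # two-level image in equal proportion: threshold at the midpoint,
  # exactly the high pixels are selected
  v <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  m <- auto_threshold(pixel_grid(v, 0.1))
  expect_equal(attr(m, "threshold"), 127.5)
  expect_identical(m$values, v > 127.5)

  # 90% zeros, 10% at 200: iterate the recursion independently
  v2 <- matrix(c(rep(0, 90), rep(200, 10)), 10, 10)
  t_oracle <- mean(v2)
  repeat {
    t_new <- (mean(v2[v2 <= t_oracle]) + mean(v2[v2 > t_oracle])) / 2
    if (abs(t_new - t_oracle) < 1e-12) break
    t_oracle <- t_new
  }
  m2 <- auto_threshold(pixel_grid(v2, 0.1))
  expect_equal(attr(m2, "threshold"), t_oracle, tolerance = 1e-6)

  # shift equivariance: adding a constant leaves the mask unchanged
  r <- matrix(runif(400, 0, 100), 20, 20)
  expect_identical(auto_threshold(pixel_grid(r, 0.1))$values,
                   auto_threshold(pixel_grid(r + 42, 0.1))$values)
  expect_error(auto_threshold(pixel_grid(matrix(1, 5, 5), 0.1)), "degenerate")
})

test_that("fill_holes fills enclosed cavities but not border-open ones", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE; ring[4:6, 4:6] <- FALSE
  filled <- fill_holes(binary_mask(ring, 0.1))
  expect_true(all(filled$values[3:7, 3:7]))
  expect_equal(sum(filled$values), 25)
  # cavity open to the border stays open
  u <- matrix(FALSE, 9, 9)
  u[3:7, 3] <- TRUE; u[3:7, 7] <- TRUE; u[7, 3:7] <- TRUE  # open upwards
  expect_identical(fill_holes(binary_mask(u, 0.1))$values, u)
  # mask without holes is unchanged
  solid <- matrix(FALSE, 6, 6); solid[2:4, 2:5] <- TRUE
  expect_identical(fill_holes(binary_mask(solid, 0.1))$values, solid)
})

test_that("fill_holes agrees with EBImage::fillHull on random blobs", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.45, 30, 30)
    ours <- fill_holes(binary_mask(m, 0.1))$values
    ref <- EBImage::fillHull(matrix(as.integer(m), 30, 30)) > 0
    expect_identical(ours, ref)
  }
})

test_that("combine_focus is a pixel-wise AND", {
  a <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2), 0.1)
  e <- binary_mask(matrix(FALSE, 2, 2), 0.1)
  expect_identical(combine_focus(a, a)$values, a$values)
  expect_identical(combine_focus(a, e)$values, e$values)
  bad <- binary_mask(matrix(TRUE, 3, 2), 0.1)
  expect_error(combine_focus(a, bad), "shape")
})

test_that("particle measurements match closed-form shape factors", {
  # disc: roundness 1 within discretisation tolerance
  d <- particles_of(disc_mask(61, 61, 31, 31, 22))
  expect_equal(nrow(d), 1)
  expect_equal(d$roundness, 1, tolerance = 0.02)
  expect_equal(d$area_um2, pi * (22 * 0.05)^2, tolerance = 0.05)
  # 2:1 ellipse: roundness = minor/major = 0.5, rejected by the filter
  e <- particles_of(ellipse_mask(61, 101, 31, 51, 40, 20))
  expect_equal(e$roundness, 0.5, tolerance = 0.02)
  expect_false(e$passes_filter)
  # centroid is reported in physical units
  expect_equal(e$centroid_x_um, 50 * 0.05, tolerance = 0.01)
})

test_that("the particle filter applies the area and roundness bounds", {
  ps <- 0.05  # px area 0.0025 um^2
  m <- matrix(FALSE, 40, 80)
  m[10:23, 5:18] <- TRUE       # 14 x 14 = 196 px = 0.49 um^2 -> rejected
  m[10:29, 40:59] <- TRUE      # 20 x 20 = 400 px = 1.00 um^2 -> kept
  p <- particles_of(m, ps)
  p <- p[order(p$area_um2), ]
  expect_equal(p$area_um2, c(0.49, 1.00))
  expect_true(all(p$roundness > 0.9))  # squares: 3/pi / (4/pi) ... ~0.95
  expect_identical(p$passes_filter, c(FALSE, TRUE))
  # monotonicity: lowering min_area never loses particles
  n_pass <- vapply(c(1.2, 0.65, 0.3, 0.1),
                   function(a) sum(particles_of(m, ps, min_area = a)$passes_filter),
                   numeric(1))
  expect_true(all(diff(n_pass) >= 0))
})

test_that("detection keeps in-focus spores and rejects defocused ones", {
  # fluorescence-like focal depth: defocused objects blurred at 4 x 0.1 um
  sc <- make_spore_chain_scene(scene_spec(
    n_chains = 2, spores_per_chain = 6,
    spore_major = c(1.1, 0.02), spore_minor = c(0.92, 0.02),
    psf_sigma = 0.1, defocus_prob = 0.5, channels = "tem", seed = 14))
  k <- sum(sc$truth$spores$in_focus)
  expect_gt(k, 0); expect_lt(k, 12)
  p <- detect_spores(sc$channels$tem)
  expect_equal(sum(p$passes_filter), k)
  # every passing particle sits on an in-focus planted spore
  pk <- p[p$passes_filter, ]
  mt <- match_particles_to_truth(pk, sc$truth$spores)
  expect_true(all(sc$truth$spores$in_focus[mt$truth_spore]))
})

test_that("detected areas recover planted ellipse areas in physical units", {
  sc <- make_spore_chain_scene(scene_spec(
    n_chains = 2, spores_per_chain = 8,
    spore_major = c(1.1, 0.03), spore_minor = c(0.92, 0.03),
    channels = "tem", seed = 15))
  p <- detect_spores(sc$channels$tem)
  pk <- p[p$passes_filter, ]
  mt <- match_particles_to_truth(pk, sc$truth$spores)
  tr <- sc$truth$spores[mt$truth_spore, ]
  planted <- pi * tr$major_um * tr$minor_um / 4
  expect_true(all(abs(pk$area_um2 / planted - 1) < 0.1))
})

test_that("detected areas are stable under 2x finer rendering", {
  args <- list(n_chains = 1, spores_per_chain = 8,
               spore_major = c(1.1, 0.03), spore_minor = c(0.92, 0.03),
               noise_model = list(type = "gaussian", sd = 0),
               channels = "tem", seed = 16)
  coarse <- make_spore_chain_scene(do.call(scene_spec,
                                           c(args, pixel_size = 0.05)))
  fine <- make_spore_chain_scene(do.call(scene_spec,
                                         c(args, pixel_size = 0.025)))
  a1 <- mean(detect_spores(coarse$channels$tem)$area_um2)
  a2 <- mean(detect_spores(fine$channels$tem)$area_um2)
  expect_lt(abs(a1 / a2 - 1), 0.02)
})

test_that("a background-only image yields no particles", {
  g <- pixel_grid(matrix(rnorm(4000, 30, 2), 50, 80), 0.05)
  p <- detect_spores(g)
  expect_equal(sum(p$passes_filter), 0)
})
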