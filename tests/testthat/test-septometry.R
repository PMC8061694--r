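test_that("septum rotation angle follows planar angle arithmetic", {
  # perpendicular to the axis: canonical, 0 degrees
  expect_equal(measure_septum_angle(c(0, 0, 0, 1), axis = 0), 0)
  # parallel to the hyphal wall: longitudinal, 90 degrees
  expect_equal(measure_septum_angle(c(0, 0, 1, 0), axis = 0), 90)
  # axis at 30 deg, septum at 75 deg -> rotation 45 deg
  seg <- c(0, 0, cos(75 * pi / 180), sin(75 * pi / 180))
  expect_equal(measure_septum_angle(seg, axis = 30), 45, tolerance = 1e-10)
  # the fold is symmetric: tilting the other way gives the same rotation
  seg2 <- c(0, 0, cos(-15 * pi / 180), sin(-15 * pi / 180))
  expect_equal(measure_septum_angle(seg2, axis = 30), 45, tolerance = 1e-10)
  expect_error(measure_septum_angle(c(1, 1, 1, 1), axis = 0), "zero-length")
})

test_that("chain axis orientation is recovered for straight and bent chains", {
  # horizontal bar
  m <- matrix(FALSE, 30, 80); m[12:19, 6:74] <- TRUE
  ax <- estimate_chain_axis(binary_mask(m, 0.05))
  dev0 <- pmin(ax$orientation_deg, 180 - ax$orientation_deg)
  expect_lt(max(dev0), 3)
  # the same bar rotated by 30 degrees (drawn analytically)
  n <- 140
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  x <- (cc - n / 2); y <- (rr - n / 2)
  u <- x * cos(pi / 6) + y * sin(pi / 6)
  v <- -x * sin(pi / 6) + y * cos(pi / 6)
  m30 <- abs(u) <= 55 & abs(v) <= 5
  ax30 <- estimate_chain_axis(binary_mask(m30, 0.05))
  expect_lt(max(abs(ax30$orientation_deg - 30)), 3)
  # L-shape: orientations near 0 on one arm and 90 on the other
  L <- matrix(FALSE, 60, 60)
  L[28:33, 5:55] <- TRUE; L[5:33, 5:10] <- TRUE
  axL <- estimate_chain_axis(binary_mask(L, 0.05), window_um = 0.5)
  horiz <- axL$points_um[, 1] > 1 & axL$points_um[, 2] > 1.2
  vert <- axL$points_um[, 2] < 0.8 & axL$points_um[, 1] < 0.6
  expect_gt(sum(horiz), 3); expect_gt(sum(vert), 3)
  o <- axL$orientation_deg
  expect_lt(max(pmin(o[horiz], 180 - o[horiz])), 10)
  expect_lt(max(abs(o[vert] - 90)), 10)
  # error conditions name the problem
  expect_error(estimate_chain_axis(binary_mask(matrix(FALSE, 5, 5), 0.1)),
               "no component")
  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(estimate_chain_axis(binary_mask(two, 0.1)), "2 components")
})

test_that("septum angles are recovered from rendered scenes within 5 degrees", {
  maes <- c()
  for (seed in c(7, 8)) {
    sc <- tem_scene(n_chains = 6, spores_per_chain = 15,
                    septum_rotation_prob = 0.5,
                    rotated_angle_range = c(10, 80),
                    longitudinal_prob_given_rotated = 0.2, seed = seed)
    se <- detect_septa(sc$channels$tem)
    tr <- sc$truth$septa
    expect_equal(nrow(se), nrow(tr))
    m <- match_septa(se, tr)
    expect_equal(sort(m), seq_len(nrow(tr)))   # one-to-one matching
    maes <- c(maes, mean(abs(se$angle_deg - tr$angle_deg[m])))
    # no confusion between planted canonical and planted longitudinal
    conf <- table(planted = tr$class[m], detected = se$class)
    expect_equal(sum(se$class == "longitudinal" &
                       tr$class[m] == "canonical"), 0)
    expect_equal(sum(se$class == "canonical" &
                       tr$class[m] == "longitudinal"), 0)
    # with classes separated by construction, recovery is exact
    expect_identical(se$class, tr$class[m])
  }
  expect_lt(mean(maes), 5)
})

test_that("angle recovery survives a rotated chain", {
  sc <- tem_scene(n_chains = 2, spores_per_chain = 10,
                  chain_orientation = 30, septum_rotation_prob = 0.4,
                  rotated_angle_range = c(15, 75), seed = 21)
  se <- detect_septa(sc$channels$tem)
  tr <- sc$truth$septa
  m <- match_septa(se, tr)
  expect_lt(mean(abs(se$angle_deg - tr$angle_deg[m])), 5)
})

test_that("tallies reproduce printed percentages from raw counts", {
  # 336 of 1479 septa rotated -> 22.7% at one decimal
  angles <- c(runif(336, 10, 90), runif(1479 - 336, 0, 5))
  st <- classify_and_tally(angles)
  expect_equal(round(st$pct_rotated, 1), 22.7)
  # 2 longitudinal of 10 rotated -> 20%
  st2 <- classify_and_tally(c(rep(90, 2), rep(45, 8), rep(5, 990)))
  expect_equal(st2$pct_longitudinal_of_rotated, 20)
  expect_equal(st2$pct_rotated, 100 * 10 / 1000)
  # all canonical -> zero rotated
  expect_equal(classify_and_tally(runif(50, 0, 9.9))$pct_rotated, 0)
  # empty input is flagged, not divided
  st0 <- classify_and_tally(numeric(0))
  expect_true(is.na(st0$pct_rotated))
  expect_true(is.na(st0$pct_split))
  # split tally
  st3 <- classify_and_tally(numeric(0), split_flags = c(TRUE, FALSE, FALSE))
  expect_equal(st3$pct_split, 100 / 3)
})

test_that("split spores are counted by mask connectivity inside the footprint", {
  sc <- tem_scene(n_chains = 8, spores_per_chain = 12, split_prob = 0.25,
                  seed = 22)
  fl <- count_split_spores(auto_threshold(sc$channels$tem), sc$truth$spores)
  expect_identical(fl, sc$truth$spores$split)
})

test_that("intensity profiles find planted foci across the hypha", {
  ps <- 0.05
  nr <- 80; nc <- 80
  xy <- function(r, c) c((c - 1) * ps, (r - 1) * ps)
  base <- matrix(10, nr, nc)
  # uniform image: flat profile, no peaks
  prof0 <- intensity_profile(pixel_grid(base, ps), centre = xy(40, 40),
                             length_um = 2, width_um = 0.5)
  expect_equal(nrow(prof0$peaks), 0)
  expect_true(all(abs(prof0$intensity - 10) < 1e-9))
  # two Gaussian foci on either side of the wall, 0.9 um apart
  rr <- matrix(seq_len(nr), nr, nc); cc <- t(rr)
  gauss <- function(r0, c0, s) exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * s^2))
  two <- base + 200 * gauss(31, 40, 2) + 200 * gauss(49, 40, 2)
  prof2 <- intensity_profile(pixel_grid(two, ps), centre = xy(40, 40),
                             length_um = 2, width_um = 0.5)
  expect_equal(nrow(prof2$peaks), 2)
  expect_equal(prof2$peak_separation_um, 18 * ps, tolerance = ps * 1.01)
  # a single mid-hyphal focus gives one central peak
  one <- base + 200 * gauss(40, 40, 2)
  prof1 <- intensity_profile(pixel_grid(one, ps), centre = xy(40, 40),
                             length_um = 2, width_um = 0.5)
  expect_equal(nrow(prof1$peaks), 1)
  expect_lt(abs(prof1$peaks$position_um), ps * 1.01)
  expect_error(intensity_profile(pixel_grid(base, ps), centre = c(0.1, 0.1),
                                 length_um = 3, width_um = 1), "outside")
})
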