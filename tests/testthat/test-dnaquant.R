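test_that("background correction zeroes exactly the pixels outside the mask", {
  v <- matrix(runif(100, 1, 5), 10, 10)
  g <- pixel_grid(v, 0.1)
  all_in <- binary_mask(matrix(TRUE, 10, 10), 0.1)
  none_in <- binary_mask(matrix(FALSE, 10, 10), 0.1)
  half <- binary_mask(cbind(matrix(TRUE, 10, 5), matrix(FALSE, 10, 5)), 0.1)
  expect_identical(background_correct(g, all_in)$values, v)
  expect_true(all(background_correct(g, none_in)$values == 0))
  expect_equal(sum(background_correct(g, half)$values), sum(v[, 1:5]))
  expect_error(background_correct(g, binary_mask(matrix(TRUE, 9, 10), 0.1)),
               "shape")
})

test_that("per-spore integration is the sum over particle pixels and linear", {
  m <- disc_mask(40, 40, 20, 20, 9)
  p <- particles_of(m, 0.05)
  u <- 3.25
  g <- pixel_grid(m * u, 0.05)
  raw <- integrate_per_spore(g, p)
  expect_equal(unname(raw), sum(m) * u)
  g2 <- pixel_grid(m * 2 * u, 0.05)
  expect_equal(unname(integrate_per_spore(g2, p)), 2 * unname(raw))
})

test_that("integration maps labels across resolutions by physical position", {
  m <- disc_mask(40, 40, 20, 20, 9)
  p <- particles_of(m, 0.05)
  # fluorescence rendered at half the detection resolution
  coarse <- m[seq(1, 39, 2), seq(1, 39, 2)]
  g <- pixel_grid(coarse * 2.0, 0.1)
  raw <- integrate_per_spore(g, p)
  expect_equal(unname(raw), sum(coarse) * 2.0, tolerance = 0.05)
})

test_that("median normalization sets every included chain median to exactly 1", {
  chain <- rep(1:2, each = 10)
  raw <- c(2, 4, 6, 8, 10, 10, 12, 14, 16, 20,
           runif(10, 0.5, 8))
  tab <- median_normalize(raw, chain)
  expect_true(all(tab$included))
  expect_equal(tab$normalized[1:10], c(2, 4, 6, 8, 10, 10, 12, 14, 16, 20) / 10)
  for (ch in 1:2)
    expect_equal(median(tab$normalized[tab$chain == ch]), 1)
  # gain invariance: any positive per-chain gain cancels
  tab_g <- median_normalize(raw * 137.5, chain)
  expect_equal(tab_g$normalized, tab$normalized)
  # idempotence: normalizing normalized values is the identity
  tab2 <- median_normalize(tab$normalized, chain)
  expect_equal(tab2$normalized, tab$normalized)
})

test_that("chains shorter than 10 spores are excluded and errors are located", {
  chain <- rep(1:2, c(9, 11))
  raw <- runif(20, 1, 3)
  tab <- median_normalize(raw, chain)
  expect_true(all(!tab$included[tab$chain == 1]))
  expect_true(all(is.na(tab$normalized[tab$chain == 1])))
  expect_true(all(tab$included[tab$chain == 2]))
  raw[13] <- 0
  expect_error(median_normalize(raw, chain), "spore 13")
})

test_that("histograms pool included chains and expose variance differences", {
  same <- median_normalize(rep(4, 12), rep(1, 12))
  h <- dna_histogram(same, bin_width = 0.1)
  expect_equal(sum(h$counts), 12)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$mids[h$counts > 0], 0.95)  # the bin containing 1
  wt <- median_normalize(c(0.83, 0.9, 0.95, 0.98, 1, 1, 1.02, 1.05, 1.1, 1.15) * 300,
                         rep(1, 10))
  mut <- median_normalize(c(0.4, 0.7, 0.8, 0.9, 1, 1, 1.2, 1.5, 2.2, 3) * 300,
                          rep(1, 10))
  h_wt <- dna_histogram(wt); h_mut <- dna_histogram(mut)
  expect_gt(h_mut$pooled_variance, h_wt$pooled_variance)
  # per-chain extrema equal the planted relative contents after scaling
  expect_equal(h_mut$per_chain$min, 0.4)
  expect_equal(h_mut$per_chain$max, 3.0)
})

test_that("the full render-segment-integrate-normalize loop recovers contents", {
  contents <- c(0.83, 0.90, 0.95, 0.98, 1.00, 1.00, 1.02, 1.05, 1.10, 1.15)
  sc <- make_spore_chain_scene(scene_spec(
    n_chains = 1, spores_per_chain = 10,
    spore_major = c(1.1, 0), spore_minor = c(0.9, 0),
    dna_content = contents,
    noise_model = list(type = "gaussian", sd = 0),
    channels = c("tem", "dna"), seed = 31))
  p <- detect_spores(sc$channels$tem)
  pk <- p[p$passes_filter, ]
  attr(pk, "labels") <- attr(p, "labels")
  attr(pk, "pixel_size") <- attr(p, "pixel_size")
  mt <- match_particles_to_truth(pk, sc$truth$spores)
  raw <- integrate_per_spore(sc$channels$dna, pk)
  tab <- median_normalize(raw, mt$chain)
  expect_equal(nrow(tab), 10)
  planted_rel <- sc$truth$spores$dna_content[mt$truth_spore] /
    median(sc$truth$spores$dna_content[mt$truth_spore])
  expect_true(all(abs(tab$normalized / planted_rel - 1) < 0.05))
})
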