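#' Specification of a synthetic spore-chain scene
#'
#' Describes a field of sporogenic hyphae that have differentiated into
#' chains of ellipsoidal spores, with division septa planted between
#' consecutive spores. Each septum is independently "rotated" (ectopic)
#' with probability `septum_rotation_prob`; rotated septa are planted at
#' exactly 90 degrees (longitudinal, parallel to the hyphal wall) with
#' probability `longitudinal_prob_given_rotated` and otherwise uniformly in
#' `rotated_angle_range`. Canonical septa are planted uniformly in
#' `[0, 5]` degrees so the planted classes are unambiguously separated from
#' the 10-degree rotation boundary. A spore is physically split along a
#' longitudinal plane with probability `split_prob` (rendered as two
#' lengthwise halves separated by a wall-level gap, i.e. completed
#' fission). All geometry is drawn in micrometres before rasterisation, so
#' the planted ground truth is independent of `pixel_size`.
#'
#' @param image_shape integer (rows, cols) in pixels, or `NULL` to size the
#'   raster automatically around the planted objects.
#' @param pixel_size um/px.
#' @param n_chains,spores_per_chain layout counts.
#' @param spore_major,spore_minor full axis lengths, um, as (mean, sd).
#' @param spore_gap gap between consecutive spores along the chain, um.
#' @param chain_orientation chain axis angle in degrees (scalar or one per
#'   chain), or `"random"` for uniform in `[0, 180)`.
#' @param septum_rotation_prob probability a septum is rotated (>= 10 deg).
#' @param rotated_angle_range degrees, subset of `[10, 90]`.
#' @param longitudinal_prob_given_rotated probability a rotated septum is
#'   planted at exactly 90 degrees.
#' @param split_prob probability a spore is physically split.
#' @param dna_content chromosome-equivalents per spore: a single number, a
#'   numeric vector recycled over spores in planting order, or a
#'   `function(n)` drawing `n` values.
#' @param dead_prob probability a spore is dead (PI-positive).
#' @param defocus_prob probability a spore (with its trailing septum) is
#'   rendered out of focus.
#' @param psf_sigma in-focus Gaussian point-spread sigma, um; out-of-focus
#'   objects are blurred with 4 x `psf_sigma`.
#' @param noise_model list: `type = "gaussian"` with `sd`, or
#'   `type = "poisson"` with `scale` (intensity per photon).
#' @param background_level,spore_level,septum_level TEM-like channel
#'   intensities (8-bit-like scale).
#' @param septum_width septum line width, um.
#' @param split_gap width of the fission gap through split spores, um.
#' @param dna_gain integrated fluorescence per chromosome-equivalent
#'   (a.u. um^2; the rendered density is the spore's DNA amount divided by
#'   its ellipse area, so the integral is content x gain for any size).
#' @param fluor_background constant background of fluorescence channels.
#' @param channels which channels to render, subset of
#'   `c("tem", "dna", "syto9", "pi")`.
#' @param seed integer RNG seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = NULL,
                       pixel_size = 0.05,
                       n_chains = 1L,
                       spores_per_chain = 12L,
                       spore_major = c(1.1, 0.05),
                       spore_minor = c(0.9, 0.04),
                       spore_gap = 0.35,
                       chain_orientation = 0,
                       septum_rotation_prob = 0,
                       rotated_angle_range = c(10, 90),
                       longitudinal_prob_given_rotated = 0,
                       split_prob = 0,
                       dna_content = 1,
                       dead_prob = 0,
                       defocus_prob = 0,
                       psf_sigma = 0.025,
                       noise_model = list(type = "gaussian", sd = 2),
                       background_level = 30,
                       spore_level = 200,
                       septum_level = 0,
                       septum_width = 0.2,
                       split_gap = 0.15,
                       dna_gain = 500,
                       fluor_background = 0,
                       channels = c("tem", "dna", "syto9", "pi"),
                       seed = 1L) {
  spec <- list(image_shape = image_shape, pixel_size = pixel_size,
               n_chains = as.integer(n_chains),
               spores_per_chain = as.integer(spores_per_chain),
               spore_major = spore_major, spore_minor = spore_minor,
               spore_gap = spore_gap, chain_orientation = chain_orientation,
               septum_rotation_prob = septum_rotation_prob,
               rotated_angle_range = rotated_angle_range,
               longitudinal_prob_given_rotated = longitudinal_prob_given_rotated,
               split_prob = split_prob, dna_content = dna_content,
               dead_prob = dead_prob, defocus_prob = defocus_prob,
               psf_sigma = psf_sigma, noise_model = noise_model,
               background_level = background_level, spore_level = spore_level,
               septum_level = septum_level, septum_width = septum_width,
               split_gap = split_gap, dna_gain = dna_gain,
               fluor_background = fluor_background,
               channels = match.arg(channels, several.ok = TRUE),
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  probs <- c(spec$septum_rotation_prob, spec$longitudinal_prob_given_rotated,
             spec$split_prob, spec$dead_prob, spec$defocus_prob)
  if (any(probs < 0 | probs > 1))
    stop("invalid scene_spec: all probabilities must lie in [0, 1]")
  if (spec$pixel_size <= 0)
    stop("invalid scene_spec: pixel_size must be > 0")
  if (!is.null(spec$image_shape) &&
      (length(spec$image_shape) != 2L || any(spec$image_shape <= 0)))
    stop("invalid scene_spec: image_shape must be two positive integers")
  if (spec$psf_sigma < 0)
    stop("invalid scene_spec: psf_sigma must be >= 0")
  r <- spec$rotated_angle_range
  if (length(r) != 2L || r[1] < 10 || r[2] > 90 || r[1] > r[2])
    stop("invalid scene_spec: rotated_angle_range must lie within [10, 90]")
  if (spec$n_chains < 1L || spec$spores_per_chain < 1L)
    stop("invalid scene_spec: need n_chains >= 1 and spores_per_chain >= 1")
  if (is.numeric(spec$dna_content) && any(spec$dna_content <= 0))
    stop("invalid scene_spec: dna_content values must be > 0")
  invisible(spec)
}

# Draw truncated-normal-ish positive sizes (resample below a floor).
draw_size <- function(n, mean_sd, floor_frac = 0.5) {
  v <- rnorm(n, mean_sd[1], mean_sd[2])
  lo <- floor_frac * mean_sd[1]
  while (any(v < lo)) v[v < lo] <- rnorm(sum(v < lo), mean_sd[1], mean_sd[2])
  v
}

draw_dna <- function(dna_content, n) {
  if (is.function(dna_content)) {
    v <- dna_content(n)
  } else {
    v <- rep_len(as.numeric(dna_content), n)
  }
  if (any(v <= 0)) stop("dna_content values must be > 0")
  v
}

# -- geometry sampling (all in um, no rasterisation) -------------------------

sample_scene_geometry <- function(spec) {
  nC <- spec$n_chains; nS <- spec$spores_per_chain
  orient <- spec$chain_orientation
  if (identical(orient, "random")) {
    theta <- runif(nC, 0, 180)
  } else {
    theta <- rep_len(as.numeric(orient), nC)
  }
  spores <- vector("list", nC)
  septa <- vector("list", nC)
  spore_counter <- 0L
  for (ci in seq_len(nC)) {
    maj <- draw_size(nS, spec$spore_major)
    mnr <- pmin(draw_size(nS, spec$spore_minor), maj * 0.95)
    dna <- draw_dna(spec$dna_content, nS)
    dead <- runif(nS) < spec$dead_prob
    split <- runif(nS) < spec$split_prob
    infoc <- runif(nS) >= spec$defocus_prob
    u <- c(cos(deg2rad(theta[ci])), sin(deg2rad(theta[ci])))
    # running centres along the axis
    pos <- numeric(nS)
    for (k in 2:max(nS, 2L)) {
      if (k > nS) break
      pos[k] <- pos[k - 1] + (maj[k - 1] + maj[k]) / 2 + spec$spore_gap
    }
    cx <- pos * u[1]; cy <- pos * u[2]
    spores[[ci]] <- data.frame(
      chain = ci, spore = spore_counter + seq_len(nS),
      x_um = cx, y_um = cy, major_um = maj, minor_um = mnr,
      orientation_deg = theta[ci] %% 180, dna_content = dna,
      viable = !dead, split = split, in_focus = infoc)
    spore_counter <- spore_counter + nS
    if (nS >= 2L) {
      nJ <- nS - 1L
      rotated <- runif(nJ) < spec$septum_rotation_prob
      longit <- rotated & (runif(nJ) < spec$longitudinal_prob_given_rotated)
      ang <- runif(nJ, 0, 5)
      ndiag <- sum(rotated & !longit)
      if (ndiag > 0)
        ang[rotated & !longit] <- runif(ndiag, spec$rotated_angle_range[1],
                                        spec$rotated_angle_range[2])
      ang[longit] <- 90
      tilt_sign <- sample(c(-1, 1), nJ, replace = TRUE)
      anchor_pos <- (pos[-nS] + pos[-1]) / 2
      ax <- anchor_pos * u[1]; ay <- anchor_pos * u[2]
      minor_loc <- (mnr[-nS] + mnr[-1]) / 2
      major_loc <- (maj[-nS] + maj[-1]) / 2
      len <- pmin(minor_loc / pmax(cos(deg2rad(ang)), 1e-9), major_loc)
      phi <- theta[ci] + 90 + tilt_sign * ang
      dx <- cos(deg2rad(phi)) * len / 2
      dy <- sin(deg2rad(phi)) * len / 2
      septa[[ci]] <- data.frame(
        chain = ci, septum = seq_len(nJ),
        x_um = ax, y_um = ay,
        x0_um = ax - dx, y0_um = ay - dy, x1_um = ax + dx, y1_um = ay + dy,
        length_um = len, angle_deg = ang,
        class = classify_septum_angle(ang),
        in_focus = infoc[-nS])
    } else {
      septa[[ci]] <- data.frame(chain = integer(), septum = integer(),
                                x_um = numeric(), y_um = numeric(),
                                x0_um = numeric(), y0_um = numeric(),
                                x1_um = numeric(), y1_um = numeric(),
                                length_um = numeric(), angle_deg = numeric(),
                                class = character(), in_focus = logical())
    }
  }
  list(spores = do.call(rbind, spores), septa = do.call(rbind, septa),
       theta = theta)
}

# Shift geometry so everything fits with a margin, stacking chains in bands.
layout_scene_geometry <- function(geo, spec, margin = 1.2) {
  sp <- geo$spores; se <- geo$septa
  y_off <- 0
  for (ci in seq_len(spec$n_chains)) {
    i <- sp$chain == ci
    j <- se$chain == ci
    ext_x <- range(sp$x_um[i]) + c(-1, 1) * max(sp$major_um[i])
    ext_y <- range(sp$y_um[i]) + c(-1, 1) * max(sp$major_um[i])
    if (any(j)) {
      ext_x <- range(ext_x, se$x0_um[j], se$x1_um[j])
      ext_y <- range(ext_y, se$y0_um[j], se$y1_um[j])
    }
    shift_x <- margin - ext_x[1]
    shift_y <- y_off + margin - ext_y[1]
    sp$x_um[i] <- sp$x_um[i] + shift_x
    sp$y_um[i] <- sp$y_um[i] + shift_y
    if (any(j)) {
      for (col in c("x_um", "x0_um", "x1_um"))
        se[[col]][j] <- se[[col]][j] + shift_x
      for (col in c("y_um", "y0_um", "y1_um"))
        se[[col]][j] <- se[[col]][j] + shift_y
    }
    y_off <- y_off + margin + diff(ext_y)
  }
  extent_x <- max(sp$x_um + sp$major_um) + margin
  extent_y <- y_off + margin
  list(spores = sp, septa = se, extent_um = c(extent_y, extent_x))
}

# -- rasterisation -----------------------------------------------------------

# Fractional pixel coverage of an ellipse (3x3 subsampling) over its
# bounding box; returned as a patch (r0:r1, c0:c1, cov) so the caller can
# add it into the accumulator in place.
ellipse_patch <- function(nr, nc, ps, cx, cy, a, b, phi_deg, gap = NULL) {
  r0 <- max(1L, floor((cy - a) / ps) + 1L - 1L)
  r1 <- min(nr, ceiling((cy + a) / ps) + 1L + 1L)
  c0 <- max(1L, floor((cx - a) / ps) + 1L - 1L)
  c1 <- min(nc, ceiling((cx + a) / ps) + 1L + 1L)
  if (r0 > r1 || c0 > c1) return(NULL)
  ys <- (seq(r0, r1) - 1) * ps
  xs <- (seq(c0, c1) - 1) * ps
  co <- cos(deg2rad(phi_deg)); si <- sin(deg2rad(phi_deg))
  cov <- matrix(0, length(ys), length(xs))
  offs <- ((1:3) - 2) / 3 * ps
  for (oy in offs) for (ox in offs) {
    X <- matrix(xs + ox - cx, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys + oy - cy, length(ys), length(xs))
    U <- (X * co + Y * si) / a
    V <- (-X * si + Y * co) / b
    cov <- cov + (U * U + V * V <= 1)
  }
  cov <- cov / 9
  if (!is.null(gap)) {
    # carve a fission gap: a stripe through the centre along the major axis
    gx0 <- cx - co * a; gy0 <- cy - si * a
    gx1 <- cx + co * a; gy1 <- cy + si * a
    gcov <- segment_coverage(ys, xs, gx0, gy0, gx1, gy1, gap, ps)
    cov <- cov * (1 - gcov)
  }
  list(r = r0:r1, c = c0:c1, cov = cov)
}

# Anti-aliased coverage of a line segment of given width over the pixel
# centres (ys, xs): 1 inside, linear 1-px ramp at the edge.
segment_coverage <- function(ys, xs, x0, y0, x1, y1, width, ps) {
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx * dx + dy * dy
  if (L2 == 0) stop("zero-length segment")
  t <- pmin(pmax(((X - x0) * dx + (Y - y0) * dy) / L2, 0), 1)
  px <- x0 + t * dx; py <- y0 + t * dy
  d <- sqrt((X - px)^2 + (Y - py)^2)
  pmin(pmax((width / 2 + ps / 2 - d) / ps, 0), 1)
}

segment_patch <- function(nr, nc, ps, x0, y0, x1, y1, width) {
  pad <- width / 2 + 2 * ps
  r0 <- max(1L, floor((min(y0, y1) - pad) / ps) + 1L)
  r1 <- min(nr, ceiling((max(y0, y1) + pad) / ps) + 1L)
  c0 <- max(1L, floor((min(x0, x1) - pad) / ps) + 1L)
  c1 <- min(nc, ceiling((max(x0, x1) + pad) / ps) + 1L)
  if (r0 > r1 || c0 > c1) return(NULL)
  ys <- (seq(r0, r1) - 1) * ps
  xs <- (seq(c0, c1) - 1) * ps
  list(r = r0:r1, c = c0:c1,
       cov = segment_coverage(ys, xs, x0, y0, x1, y1, width, ps))
}

add_noise <- function(m, noise_model) {
  type <- noise_model$type %||% "gaussian"
  if (type == "gaussian") {
    sd <- noise_model$sd %||% 0
    if (sd > 0) m <- m + matrix(rnorm(length(m), 0, sd), nrow(m))
  } else if (type == "poisson") {
    scale <- noise_model$scale %||% 1
    m <- matrix(rpois(length(m), pmax(m, 0) / scale) * scale, nrow(m))
  } else stop("unknown noise model type: ", type)
  m
}

#' Render a synthetic spore-chain scene with ground truth
#'
#' Renders a TEM-like channel (bright spores, dark septa on a grey
#' background), a DNA-stain fluorescence channel whose integrated per-spore
#' intensity is proportional to the planted DNA content, and a Syto9/PI
#' live/dead channel pair. Spores are filled ellipses and septa
#' anti-aliased line segments; in-focus objects are convolved with a
#' Gaussian PSF of `psf_sigma`, out-of-focus objects with 4 x `psf_sigma`.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `spore_scene` with elements `channels` (named
#'   list of [pixel_grid()]s), `truth` (list of data.frames `spores` and
#'   `septa`, coordinates in um), and `spec`.
#' @export
make_spore_chain_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    geo <- sample_scene_geometry(spec)
    lay <- layout_scene_geometry(geo, spec)
    ps <- spec$pixel_size
    shape <- spec$image_shape
    if (is.null(shape)) shape <- ceiling(lay$extent_um / ps)
    nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
    sp <- lay$spores; se <- lay$septa

    want_tem <- "tem" %in% spec$channels
    want_dna <- "dna" %in% spec$channels
    want_vs <- any(c("syto9", "pi") %in% spec$channels)
    render_group <- function(focus) {
      spg <- sp[sp$in_focus == focus, , drop = FALSE]
      seg <- se[if (nrow(se)) se$in_focus == focus else logical(0), ,
                drop = FALSE]
      cov_sp <- if (want_tem) matrix(0, nr, nc) else NULL  # spore coverage
      cov_dna <- if (want_dna) matrix(0, nr, nc) else NULL
      cov_grn <- if (want_vs) matrix(0, nr, nc) else NULL
      cov_red <- if (want_vs) matrix(0, nr, nc) else NULL
      for (i in seq_len(nrow(spg))) {
        gap <- if (spg$split[i]) spec$split_gap else NULL
        p <- ellipse_patch(nr, nc, ps, spg$x_um[i], spg$y_um[i],
                           spg$major_um[i] / 2, spg$minor_um[i] / 2,
                           spg$orientation_deg[i], gap)
        if (is.null(p)) next
        if (want_tem)
          cov_sp[p$r, p$c] <- cov_sp[p$r, p$c] + p$cov
        if (want_dna) {
          # density = amount / area, so the integral is content * dna_gain
          # whatever the spore size
          dens <- spg$dna_content[i] * spec$dna_gain /
            (pi * spg$major_um[i] * spg$minor_um[i] / 4)
          cov_dna[p$r, p$c] <- cov_dna[p$r, p$c] + dens * p$cov
        }
        if (want_vs) {
          grn <- if (spg$viable[i]) 200 else 40
          red <- if (spg$viable[i]) 20 else 200
          cov_grn[p$r, p$c] <- cov_grn[p$r, p$c] + grn * p$cov
          cov_red[p$r, p$c] <- cov_red[p$r, p$c] + red * p$cov
        }
      }
      tem_dev <- NULL
      if (want_tem) {
        cov_se <- matrix(0, nr, nc)
        for (i in seq_len(nrow(seg))) {
          p <- segment_patch(nr, nc, ps, seg$x0_um[i], seg$y0_um[i],
                             seg$x1_um[i], seg$y1_um[i], spec$septum_width)
          if (!is.null(p))
            cov_se[p$r, p$c] <- pmin(cov_se[p$r, p$c] + p$cov, 1)
        }
        bg <- spec$background_level
        tem_dev <- (bg + (spec$spore_level - bg) * pmin(cov_sp, 1)) *
          (1 - cov_se) + spec$septum_level * cov_se - bg
      }
      list(tem_dev = tem_dev, dna = cov_dna, grn = cov_grn, red = cov_red)
    }

    sharp <- render_group(TRUE)
    fuzzy <- render_group(FALSE)
    s_px <- spec$psf_sigma / ps
    blur2 <- function(a, b) gaussian_blur_matrix(a, s_px) +
      gaussian_blur_matrix(b, 4 * s_px)

    channels <- list()
    if ("tem" %in% spec$channels) {
      tem <- spec$background_level + blur2(sharp$tem_dev, fuzzy$tem_dev)
      channels$tem <- pixel_grid(add_noise(tem, spec$noise_model), ps)
    }
    if ("dna" %in% spec$channels) {
      dna <- spec$fluor_background + blur2(sharp$dna, fuzzy$dna)
      channels$dna <- pixel_grid(add_noise(dna, spec$noise_model), ps)
    }
    if ("syto9" %in% spec$channels) {
      grn <- spec$fluor_background + blur2(sharp$grn, fuzzy$grn)
      channels$syto9 <- pixel_grid(add_noise(grn, spec$noise_model), ps)
    }
    if ("pi" %in% spec$channels) {
      red <- spec$fluor_background + blur2(sharp$red, fuzzy$red)
      channels$pi <- pixel_grid(add_noise(red, spec$noise_model), ps)
    }
    structure(list(channels = channels,
                   truth = list(spores = sp, septa = se),
                   spec = spec),
              class = "spore_scene")
  })
}

#' @export
print.spore_scene <- function(x, ...) {
  cat(sprintf("<spore_scene> %d spores, %d septa, channels: %s\n",
              nrow(x$truth$spores), nrow(x$truth$septa),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a scene to disk
#'
#' One multi-page TIFF (one page per channel), ground-truth TSVs and the
#' spec as YAML.
#'
#' @param scene a `spore_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # one common scale across channels so pages stay comparable and in [0,1]
  peak <- max(vapply(scene$channels, function(g) max(g$values), numeric(1)))
  scale <- max(255, ceiling(peak))
  write_pixel_grids(scene$channels, file.path(dir, "scene.tif"),
                    scale = scale)
  write.table(scene$truth$spores, file.path(dir, "truth_spores.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(scene$truth$septa, file.path(dir, "truth_septa.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- scene$spec
  sp$dna_content <- if (is.function(sp$dna_content)) "function"
    else sp$dna_content
  sp$tiff_scale <- scale
  yaml::write_yaml(unclass(sp), file.path(dir, "scene_spec.yaml"))
  invisible(dir)
}

# -- FRAP trace simulation ---------------------------------------------------

#' Specification of simulated FRAP traces
#'
#' Recovery follows I(t) = P - (P - B) exp(-t/tau). `recovery_time` is the
#' time to reach 95% of the recoverable signal, i.e. tau * ln(20) — the
#' same definition [fit_recovery()] reports, so parameter-recovery tests
#' are internally consistent.
#'
#' @param plateau P, the asymptotic intensity.
#' @param bleach_depth B, the intensity immediately after the bleach
#'   (0 <= B < P).
#' @param recovery_time time to 95% recovery, s (> 0).
#' @param sampling_interval s.
#' @param duration total trace length, s.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param n_traces number of traces to draw.
#' @param seed RNG seed.
#' @export
frap_spec <- function(plateau = 1, bleach_depth = 0, recovery_time = 60,
                      sampling_interval = 2, duration = 300,
                      noise_sd = 0.05, n_traces = 1L, seed = 1L) {
  if (recovery_time <= 0) stop("invalid frap_spec: recovery_time must be > 0")
  if (!(bleach_depth >= 0 && bleach_depth < plateau))
    stop("invalid frap_spec: need 0 <= bleach_depth < plateau")
  if (sampling_interval <= 0)
    stop("invalid frap_spec: sampling_interval must be > 0")
  if (duration < sampling_interval)
    stop("invalid frap_spec: duration shorter than one sampling interval")
  structure(list(plateau = plateau, bleach_depth = bleach_depth,
                 recovery_time = recovery_time,
                 sampling_interval = sampling_interval, duration = duration,
                 noise_sd = noise_sd, n_traces = as.integer(n_traces),
                 seed = as.integer(seed)),
            class = "frap_spec")
}

#' Simulate single-exponential FRAP recovery traces
#'
#' @param spec a [frap_spec()].
#' @return a list of `frap_trace` data.frames (`time_s`, `intensity`), with
#'   the planted time constant tau attached as attribute `tau`.
#' @export
simulate_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  tau <- spec$recovery_time / log(20)
  t <- seq(0, spec$duration, by = spec$sampling_interval)
  noiseless <- spec$plateau -
    (spec$plateau - spec$bleach_depth) * exp(-t / tau)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_traces), function(i) {
      y <- noiseless
      if (spec$noise_sd > 0) y <- y + rnorm(length(t), 0, spec$noise_sd)
      structure(data.frame(time_s = t, intensity = y),
                class = c("frap_trace", "data.frame"), tau = tau)
    })
  })
}

# -- colony time-lapse simulation --------------------------------------------

default_grey_trajectories <- function(n_frames) {
  p <- if (n_frames > 1) (seq_len(n_frames) - 1) / (n_frames - 1) else 0
  # darkening starts once aerial growth is underway; logistic ramp
  ramp <- 1 / (1 + exp(-(p - 0.45) * 12))
  list(white = 210 - 5 * ramp,
       `light-grey` = 210 - 45 * ramp,
       grey = 210 - 95 * ramp)
}

#' Specification of a synthetic colony scanner time-lapse
#'
#' Defaults emulate a 7-day flat-bed scan at one frame per 30 minutes
#' (337 frames). Colonies darken according to their planted phenotype
#' class trajectory (grey spore pigment accumulates as sporulation
#' proceeds, lowering the grey value).
#'
#' @param n_frames number of frames (default 337 = 7 days at 30 min plus
#'   the initial frame).
#' @param frame_interval minutes between frames.
#' @param grey_trajectory named list of per-frame mean grey values for
#'   classes `white`, `light-grey`, `grey`; `NULL` for built-in defaults.
#' @param classes planted phenotype class of each colony.
#' @param roi_radius measurement ROI radius, px.
#' @param colony_radius rendered colony radius, px (>= `roi_radius`).
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param background_level scanner background grey value.
#' @param seed RNG seed.
#' @export
colony_spec <- function(n_frames = 337L, frame_interval = 30,
                        grey_trajectory = NULL,
                        classes = c("white", "light-grey", "grey"),
                        roi_radius = 8, colony_radius = 12,
                        noise_sd = 1, background_level = 235, seed = 1L) {
  if (n_frames < 1L) stop("invalid colony_spec: n_frames must be >= 1")
  if (is.null(grey_trajectory))
    grey_trajectory <- default_grey_trajectories(n_frames)
  if (length(grey_trajectory) == 0L ||
      any(!lengths(grey_trajectory)))
    stop("invalid colony_spec: empty grey_trajectory")
  grey_trajectory <- lapply(grey_trajectory, rep_len, n_frames)
  if (any(unlist(grey_trajectory) < 0 | unlist(grey_trajectory) > 255))
    stop("invalid colony_spec: grey values outside representable range")
  if (!all(classes %in% names(grey_trajectory)))
    stop("invalid colony_spec: classes without a trajectory")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 grey_trajectory = grey_trajectory, classes = classes,
                 roi_radius = roi_radius, colony_radius = colony_radius,
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed)),
            class = "colony_spec")
}

#' Simulate a colony scanner image stack
#'
#' @param spec a [colony_spec()].
#' @return list with `stack` (rows x cols x frames array), `colonies`
#'   (data.frame: colony, x_px, y_px, roi_radius, class), `times_min`, and
#'   `spec`.
#' @export
make_colony_stack <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  n <- length(spec$classes)
  pitch <- spec$colony_radius * 3L
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  nr <- as.integer(nrow_g * pitch + pitch)
  nc <- as.integer(ncol_g * pitch + pitch)
  xs <- pitch * (((seq_len(n) - 1L) %% ncol_g) + 1L)
  ys <- pitch * (((seq_len(n) - 1L) %/% ncol_g) + 1L)
  colonies <- data.frame(colony = seq_len(n), x_px = xs, y_px = ys,
                         roi_radius = spec$roi_radius, class = spec$classes)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  with_seed(spec$seed, {
    stack <- array(0, dim = c(nr, nc, spec$n_frames))
    base <- matrix(spec$background_level, nr, nc)
    inside <- vector("list", n)
    for (i in seq_len(n))
      inside[[i]] <- (rr - ys[i])^2 + (cc - xs[i])^2 <=
        spec$colony_radius^2
    for (f in seq_len(spec$n_frames)) {
      frame <- base
      for (i in seq_len(n))
        frame[inside[[i]]] <- spec$grey_trajectory[[spec$classes[i]]][f]
      if (spec$noise_sd > 0)
        frame <- frame + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      stack[, , f] <- frame
    }
    list(stack = stack, colonies = colonies,
         times_min = (seq_len(spec$n_frames) - 1L) * spec$frame_interval,
         spec = spec)
  })
}
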