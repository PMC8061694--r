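# Shift a logical matrix so s(r, c) = m(r + dr, c + dc), FALSE outside.
shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rsrc <- seq_len(nr) + dr
  csrc <- seq_len(nc) + dc
  rok <- rsrc >= 1L & rsrc <= nr
  cok <- csrc >= 1L & csrc <= nc
  out[rok, cok] <- m[rsrc[rok], csrc[cok], drop = FALSE]
  out
}

# Zhang-Suen thinning to a 1-px skeleton.
thin_mask <- function(m) {
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift_logical(m, -1, 0); P3 <- shift_logical(m, -1, 1)
      P4 <- shift_logical(m, 0, 1);  P5 <- shift_logical(m, 1, 1)
      P6 <- shift_logical(m, 1, 0);  P7 <- shift_logical(m, 1, -1)
      P8 <- shift_logical(m, 0, -1); P9 <- shift_logical(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (step == 1) {
        cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) return(m)
  }
}

# Order skeleton pixels into a path by walking from an endpoint; falls back
# to projection ordering on the principal axis when the skeleton branches.
order_skeleton <- function(coords) {
  n <- nrow(coords)
  if (n <= 2) return(seq_len(n))
  key <- coords[, 1] + coords[, 2] * 1e6
  idx_of <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx_of)
  nb_offsets <- expand.grid(dr = -1:1, dc = -1:1)
  nb_offsets <- nb_offsets[!(nb_offsets$dr == 0 & nb_offsets$dc == 0), ]
  neighbours <- function(i) {
    ks <- (coords[i, 1] + nb_offsets$dr) + (coords[i, 2] + nb_offsets$dc) * 1e6
    out <- integer(0)
    for (k in ks) {
      j <- mget(as.character(k), envir = idx_of, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_len(n), function(i) length(neighbours(i)), integer(1))
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- logical(n)
  path <- integer(0)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    path <- c(path, cur)
    nxt <- setdiff(neighbours(cur), which(visited))
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  if (length(path) < 0.9 * n) {
    # branched skeleton: fall back to ordering by principal-axis projection
    cc <- scale(coords, scale = FALSE)
    v <- eigen(crossprod(cc) / n, symmetric = TRUE)$vectors[, 1]
    return(order(cc %*% v))
  }
  path
}

#' Estimate the axis of a spore chain
#'
#' Thins the chain mask to a skeleton, orders it into a polyline and
#' assigns each vertex a local orientation from a principal-axis fit of the
#' skeleton points inside a sliding window. The orientation defines the
#' canonical division plane (perpendicular to the local axis).
#'
#' @param mask a [binary_mask()] containing exactly one connected chain.
#' @param window_um radius of the sliding orientation window, um.
#' @return an object of class `chain_axis`: list with `points_um` (n x 2,
#'   columns x, y) and `orientation_deg` (per vertex, in [0, 180)).
#' @export
estimate_chain_axis <- function(mask, window_um = 1.25) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components(mask$values, 8L)
  ncomp <- max(lab)
  if (ncomp == 0L) stop("chain axis: mask contains no component")
  if (ncomp > 1L)
    stop(sprintf("chain axis: mask contains %d components, expected 1", ncomp))
  sk <- thin_mask(mask$values)
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) < 2) {
    # degenerate skeleton (compact blob): fall back to the mask itself
    idx <- which(mask$values, arr.ind = TRUE)
  }
  ord <- order_skeleton(idx)
  idx <- idx[ord, , drop = FALSE]
  ps <- mask$pixel_size
  pts <- cbind(x = (idx[, 2] - 1) * ps, y = (idx[, 1] - 1) * ps)
  w <- window_um
  n <- nrow(pts)
  orient <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    sel <- d2 <= w * w
    if (sum(sel) < 3) sel <- rank(d2, ties.method = "first") <= 5
    cc <- scale(pts[sel, , drop = FALSE], scale = FALSE)
    v <- eigen(crossprod(cc) / sum(sel), symmetric = TRUE)$vectors[, 1]
    orient[i] <- rad2deg(atan2(v[2], v[1])) %% 180
  }
  structure(list(points_um = pts, orientation_deg = orient, pixel_size = ps),
            class = "chain_axis")
}

# Local axis orientation at a physical point: nearest polyline vertex.
axis_orientation_at <- function(axis, x, y) {
  d2 <- (axis$points_um[, 1] - x)^2 + (axis$points_um[, 2] - y)^2
  axis$orientation_deg[which.min(d2)]
}

#' Rotation angle of a septum relative to the local hyphal axis
#'
#' The rotation angle is the unsigned angle between the septum plane and
#' the canonical plane (the line perpendicular to the local axis), folded
#' into `[0, 90]`: 0 = canonical transverse septum, 90 = longitudinal septum
#' parallel to the hyphal wall.
#'
#' @param segment numeric (x0, y0, x1, y1) in um, or a 2 x 2 matrix of
#'   endpoints (rows = points).
#' @param axis a [estimate_chain_axis()] result, or a single orientation in
#'   degrees.
#' @return rotation angle in degrees, `[0, 90]`.
#' @export
measure_septum_angle <- function(segment, axis) {
  if (is.matrix(segment)) segment <- c(segment[1, ], segment[2, ])
  dx <- segment[3] - segment[1]; dy <- segment[4] - segment[2]
  if (dx == 0 && dy == 0) stop("zero-length septum segment")
  sept_dir <- rad2deg(atan2(dy, dx))
  ax_orient <- if (inherits(axis, "chain_axis")) {
    axis_orientation_at(axis, (segment[1] + segment[3]) / 2,
                        (segment[2] + segment[4]) / 2)
  } else as.numeric(axis)
  90 - fold90(sept_dir - ax_orient)
}

#' Classify a septum rotation angle
#'
#' @param angle_deg rotation angle(s) in degrees, `[0, 90]`.
#' @param canonical_max angles strictly below this are canonical.
#' @param longitudinal_min angles at or above this are longitudinal.
#' @return character vector: "canonical", "diagonal" or "longitudinal".
#' @export
classify_septum_angle <- function(angle_deg, canonical_max = 10,
                                  longitudinal_min = 85) {
  ifelse(angle_deg < canonical_max, "canonical",
         ifelse(angle_deg >= longitudinal_min, "longitudinal", "diagonal"))
}

#' Detect septa in a TEM-like channel and measure their rotation
#'
#' Septa appear as thin dark lines inside the otherwise bright spore
#' chains. The spore mask (intermeans auto-threshold) is dilated and
#' hole-filled into a chain footprint; dark ridge pixels inside the
#' footprint (below `dark_threshold`, default half the estimated
#' background) are grouped into septum candidates, each measured by
#' darkness-weighted second moments, assigned to its chain, and given a
#' rotation angle relative to the local chain axis.
#'
#' @param grid the TEM-like [pixel_grid()].
#' @param dark_threshold intensity below which a pixel counts as septum;
#'   `NULL` for half the median intensity outside the chain footprint.
#' @param min_septum_px discard candidates smaller than this (noise).
#' @param dilate_um chain-footprint dilation radius, um.
#' @param window_um axis orientation window (see [estimate_chain_axis()]).
#' @param canonical_max,longitudinal_min class thresholds, degrees.
#' @return data.frame of class `septum_table`: chain, x_um, y_um,
#'   length_um, angle_deg (rotation), class.
#' @export
detect_septa <- function(grid, dark_threshold = NULL, min_septum_px = 5L,
                         dilate_um = 0.25, window_um = 1.25,
                         canonical_max = 10, longitudinal_min = 85) {
  stopifnot(inherits(grid, "pixel_grid"))
  ps <- grid$pixel_size
  spore_mask <- auto_threshold(grid)
  r <- as.integer(ceiling(dilate_um / ps))
  chain_vals <- fill_holes(binary_mask(dilate_disc(spore_mask$values, r), ps))
  chain_lab <- label_components(chain_vals$values, 8L)
  bg_est <- median(grid$values[chain_lab == 0L])
  if (is.null(dark_threshold)) dark_threshold <- bg_est / 2
  sept_px <- grid$values < dark_threshold & chain_lab != 0L
  slab <- label_components(sept_px, 8L)
  nsep <- max(slab)
  empty <- data.frame(chain = integer(), x_um = numeric(), y_um = numeric(),
                      length_um = numeric(), angle_deg = numeric(),
                      class = character())
  if (nsep == 0L) return(structure(empty, class = c("septum_table",
                                                    "data.frame")))
  # per-chain axes, computed lazily on cropped bounding boxes so the
  # skeletonisation cost scales with the chain, not the field of view
  axes <- vector("list", max(chain_lab))
  get_axis <- function(ci) {
    if (is.null(axes[[ci]])) {
      cidx <- which(chain_lab == ci, arr.ind = TRUE)
      r0 <- max(1L, min(cidx[, 1]) - 2L); r1 <- min(nrow(chain_lab), max(cidx[, 1]) + 2L)
      c0 <- max(1L, min(cidx[, 2]) - 2L); c1 <- min(ncol(chain_lab), max(cidx[, 2]) + 2L)
      cm <- binary_mask(chain_lab[r0:r1, c0:c1, drop = FALSE] == ci, ps)
      ax <- estimate_chain_axis(cm, window_um)
      ax$points_um[, 1] <- ax$points_um[, 1] + (c0 - 1L) * ps
      ax$points_um[, 2] <- ax$points_um[, 2] + (r0 - 1L) * ps
      axes[[ci]] <<- ax
    }
    axes[[ci]]
  }
  recs <- vector("list", nsep)
  idx <- which(slab != 0L)
  rows <- ((idx - 1L) %% nrow(slab)) + 1L
  cols <- ((idx - 1L) %/% nrow(slab)) + 1L
  labs <- slab[idx]
  wts <- pmax(0, 1 - grid$values[idx] / max(bg_est, 1e-9))
  for (k in seq_len(nsep)) {
    sel <- labs == k
    if (sum(sel) < min_septum_px) next
    rr <- rows[sel]; cc <- cols[sel]; w <- wts[sel]
    w <- w / sum(w)
    mx <- sum(cc * w); my <- sum(rr * w)
    vxx <- sum((cc - mx)^2 * w) + 1 / 12
    vyy <- sum((rr - my)^2 * w) + 1 / 12
    vxy <- sum((cc - mx) * (rr - my) * w)
    tr <- vxx + vyy
    disc <- sqrt(max(tr^2 / 4 - (vxx * vyy - vxy^2), 0))
    l1 <- tr / 2 + disc
    dir_deg <- if (abs(vxy) < 1e-12) {
      if (vxx >= vyy) 0 else 90
    } else rad2deg(atan2(l1 - vxx, vxy))
    x_um <- (mx - 1) * ps; y_um <- (my - 1) * ps
    ci <- chain_lab[round(my), round(mx)]
    if (ci == 0L) {
      cidx <- which(chain_lab != 0L)
      crr <- ((cidx - 1L) %% nrow(chain_lab)) + 1L
      ccc <- ((cidx - 1L) %/% nrow(chain_lab)) + 1L
      ci <- chain_lab[cidx[which.min((crr - my)^2 + (ccc - mx)^2)]]
    }
    ax <- get_axis(ci)
    rot <- 90 - fold90(dir_deg - axis_orientation_at(ax, x_um, y_um))
    recs[[k]] <- data.frame(chain = ci, x_um = x_um, y_um = y_um,
                            length_um = 4 * sqrt(l1) * ps, angle_deg = rot,
                            class = classify_septum_angle(rot, canonical_max,
                                                          longitudinal_min))
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- empty
  structure(out, class = c("septum_table", "data.frame"))
}

#' Tally septum classes and split spores
#'
#' Applies the class thresholds and computes counts and percentages:
#' percent rotated of all septa, percent longitudinal of rotated, and
#' percent split of all spores. With empty input the percentages are `NA`
#' (flagged, never divided by zero).
#'
#' @param measurements a `septum_table`, data.frame with an `angle_deg`
#'   column, or a numeric vector of rotation angles.
#' @param split_flags logical vector, one per spore (`NULL` if unknown).
#' @param canonical_max,longitudinal_min class thresholds, degrees.
#' @return an object of class `septum_stats`.
#' @export
classify_and_tally <- function(measurements, split_flags = NULL,
                               canonical_max = 10, longitudinal_min = 85) {
  angles <- if (is.numeric(measurements)) measurements
    else measurements$angle_deg
  cls <- classify_septum_angle(angles, canonical_max, longitudinal_min)
  n <- length(angles)
  n_rot <- sum(cls != "canonical")
  n_lon <- sum(cls == "longitudinal")
  n_spores <- if (is.null(split_flags)) 0L else length(split_flags)
  n_split <- if (is.null(split_flags)) 0L else sum(split_flags)
  structure(list(
    n_septa = n, n_rotated = n_rot,
    pct_rotated = if (n > 0) 100 * n_rot / n else NA_real_,
    n_longitudinal = n_lon,
    pct_longitudinal_of_rotated =
      if (n_rot > 0) 100 * n_lon / n_rot else NA_real_,
    n_spores = n_spores, n_split = n_split,
    pct_split = if (n_spores > 0) 100 * n_split / n_spores else NA_real_),
    class = "septum_stats")
}

#' @export
print.septum_stats <- function(x, ...) {
  cat(sprintf("<septum_stats> %d septa: %d rotated (%s%%), %d longitudinal (%s%% of rotated); %d/%d spores split (%s%%)\n",
              x$n_septa, x$n_rotated, fmt1(x$pct_rotated),
              x$n_longitudinal, fmt1(x$pct_longitudinal_of_rotated),
              x$n_split, x$n_spores, fmt1(x$pct_split)))
  invisible(x)
}

fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))

#' Count physically split spores
#'
#' A spore counts as split when completed fission along an ectopic
#' (longitudinal) plane has severed it into two pieces, i.e. the
#' segmentation mask restricted to the spore's planted footprint falls
#' apart into two or more components of at least `min_part_px` pixels.
#'
#' @param mask the scene's [binary_mask()] (e.g. the auto-threshold of the
#'   TEM-like channel).
#' @param spores data.frame with columns x_um, y_um, major_um, minor_um,
#'   orientation_deg (e.g. the `spores` truth table).
#' @param expand footprint scale factor (slack around the planted ellipse).
#' @param min_part_px minimum component size counted as a spore piece.
#' @return logical vector, one flag per spore row.
#' @export
count_split_spores <- function(mask, spores, expand = 1.15,
                               min_part_px = 5L) {
  stopifnot(inherits(mask, "binary_mask"))
  ps <- mask$pixel_size
  m <- mask$values
  nr <- nrow(m); nc <- ncol(m)
  out <- logical(nrow(spores))
  for (i in seq_len(nrow(spores))) {
    s <- spores[i, ]
    a <- expand * s$major_um / 2
    b <- expand * s$minor_um / 2
    r0 <- max(1L, floor((s$y_um - a) / ps)); r1 <- min(nr, ceiling((s$y_um + a) / ps) + 2L)
    c0 <- max(1L, floor((s$x_um - a) / ps)); c1 <- min(nc, ceiling((s$x_um + a) / ps) + 2L)
    ys <- (seq(r0, r1) - 1) * ps; xs <- (seq(c0, c1) - 1) * ps
    co <- cos(deg2rad(s$orientation_deg)); si <- sin(deg2rad(s$orientation_deg))
    X <- matrix(xs - s$x_um, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys - s$y_um, length(ys), length(xs))
    U <- (X * co + Y * si) / a
    V <- (-X * si + Y * co) / b
    foot <- (U * U + V * V <= 1) & m[r0:r1, c0:c1]
    lab <- label_components(foot, 8L)
    if (max(lab) >= 2L) {
      sizes <- tabulate(lab[lab > 0L])
      out[i] <- sum(sizes >= min_part_px) >= 2L
    }
  }
  out
}

# Bilinear interpolation at physical points (um); clamped to the raster.
interp_bilinear <- function(grid, x_um, y_um) {
  m <- grid$values; ps <- grid$pixel_size
  r <- y_um / ps; c <- x_um / ps          # 0-based fractional indices
  r <- pmin(pmax(r, 0), nrow(m) - 1)
  c <- pmin(pmax(c, 0), ncol(m) - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nrow(m) - 1); c1 <- pmin(c0 + 1, ncol(m) - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    m[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
    m[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
    m[cbind(r1 + 1, c1 + 1)] * fr * fc
}

# Peak prominences for local maxima of y (simple O(n k) scan).
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(is_max, function(i) {
    lmin <- min(y[1:i]); rmin <- min(y[i:n])
    j <- which(y[1:i] > y[i]); if (length(j)) lmin <- min(y[max(j):i])
    j <- which(y[i:n] > y[i]); if (length(j)) rmin <- min(y[i:(i + min(j) - 1)])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = is_max, prominence = prom)
}

#' Cross-hypha intensity profile
#'
#' Averages intensity along a box laid across the hypha: at each position
#' along the profile axis (perpendicular to the hyphal axis) the intensity
#' is averaged over the box width (parallel to the hyphal axis), then
#' peaks are detected by local maxima above a prominence threshold. Two
#' wall-associated foci give two peaks whose separation estimates the
#' hyphal width; a mid-hyphal focus gives a single central peak.
#'
#' @param grid a [pixel_grid()].
#' @param centre (x, y) box centre, um.
#' @param length_um profile length across the hypha, um.
#' @param width_um box width along the hypha, um.
#' @param orientation_deg direction of the hyphal axis, degrees.
#' @param prominence minimal peak prominence; `NULL` for 10% of the
#'   profile's dynamic range.
#' @return an object of class `intensity_profile`: list with
#'   `position_um` (centred on the box), `intensity`, `peaks` (data.frame
#'   position_um, intensity, prominence) and `peak_separation_um`.
#' @export
intensity_profile <- function(grid, centre, length_um, width_um,
                              orientation_deg = 0, prominence = NULL) {
  stopifnot(inherits(grid, "pixel_grid"))
  ps <- grid$pixel_size
  u <- c(cos(deg2rad(orientation_deg)), sin(deg2rad(orientation_deg)))
  v <- c(-u[2], u[1])                       # across the hypha
  half_l <- length_um / 2; half_w <- width_um / 2
  corners_x <- centre[1] + outer(c(-half_l, half_l) * v[1],
                                 c(-half_w, half_w) * u[1], `+`)
  corners_y <- centre[2] + outer(c(-half_l, half_l) * v[2],
                                 c(-half_w, half_w) * u[2], `+`)
  ext_x <- (ncol(grid$values) - 1) * ps
  ext_y <- (nrow(grid$values) - 1) * ps
  if (any(corners_x < 0 | corners_x > ext_x |
          corners_y < 0 | corners_y > ext_y))
    stop("profile box extends outside the image")
  pos <- seq(-half_l, half_l, by = ps)
  off <- seq(-half_w, half_w, by = ps)
  prof <- vapply(pos, function(p) {
    xs <- centre[1] + p * v[1] + off * u[1]
    ys <- centre[2] + p * v[2] + off * u[2]
    mean(interp_bilinear(grid, xs, ys))
  }, numeric(1))
  if (length(prof) < 3) stop("profile too short (need >= 3 samples)")
  if (is.null(prominence)) prominence <- 0.1 * diff(range(prof))
  pk <- find_peaks(prof)
  pk <- pk[pk$prominence > max(prominence, 1e-12), , drop = FALSE]
  peaks <- data.frame(position_um = pos[pk$index],
                      intensity = prof[pk$index],
                      prominence = pk$prominence)
  sep <- if (nrow(peaks) >= 2) diff(range(peaks$position_um)) else NA_real_
  structure(list(position_um = pos, intensity = prof, peaks = peaks,
                 peak_separation_um = sep),
            class = "intensity_profile")
}

#' Write a septum table and stats
#'
#' @param septa a `septum_table`.
#' @param stats a `septum_stats`.
#' @param dir output directory.
#' @export
write_septum_results <- function(septa, stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(septa), file.path(dir, "septa.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(stats), file.path(dir, "septum_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
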