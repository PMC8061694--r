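#' Repeated 5% upscaling
#'
#' Enlarges the raster by `step_fraction` in `n_steps` consecutive bilinear
#' resizes, rounding the pixel dimensions to the nearest integer at every
#' step (20 steps of 5% give a cumulative linear factor of about
#' 1.05^20 = 2.653). The physical field of view is preserved: the pixel
#' size is reduced so that total imaged area is unchanged, which keeps all
#' downstream area measurements on the original calibration.
#'
#' @param grid a [pixel_grid()].
#' @param step_fraction relative enlargement per step.
#' @param n_steps number of consecutive resizes.
#' @return the enlarged `pixel_grid`.
#' @export
upscale_image <- function(grid, step_fraction = 0.05, n_steps = 20L) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (length(grid$values) == 0L) stop("empty grid")
  m <- grid$values
  nr0 <- nrow(m); nc0 <- ncol(m)
  nr <- nr0; nc <- nc0
  for (i in seq_len(n_steps)) {
    nr2 <- as.integer(round(nr * (1 + step_fraction)))
    nc2 <- as.integer(round(nc * (1 + step_fraction)))
    m <- resize_bilinear_matrix(m, nr2, nc2)
    nr <- nr2; nc <- nc2
  }
  # area-preserving calibration (row and column factors can differ by a
  # fraction of a pixel because of per-step rounding)
  ps <- grid$pixel_size * sqrt((nr0 / nr) * (nc0 / nc))
  pixel_grid(m, ps)
}

#' Sobel gradient magnitude
#'
#' Per-pixel gradient magnitude sqrt(Gx^2 + Gy^2) with the standard 3x3
#' Sobel kernels; image borders are handled by edge replication so a flat
#' border produces no spurious response. An ideal unit step yields a
#' maximum response of 4 on the pixels adjacent to the step.
#'
#' @param grid a [pixel_grid()].
#' @return a `pixel_grid` of gradient magnitudes.
#' @export
find_edges <- function(grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (length(grid$values) == 0L) stop("empty grid")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (columns)
  ky <- t(kx)                                                # d/dy (rows)
  gx <- correlate2d(grid$values, kx)
  gy <- correlate2d(grid$values, ky)
  pixel_grid(sqrt(gx^2 + gy^2), grid$pixel_size)
}

#' Iterative intermeans (IsoData) auto-threshold
#'
#' The default automatic threshold of the original analysis platform:
#' starting from the overall mean, iterate
#' t <- (mean(values <= t) + mean(values > t)) / 2 to a fixed point. The
#' mask is TRUE strictly above the threshold. The threshold is
#' shift-equivariant, so the mask is invariant to adding a constant.
#'
#' @param grid a [pixel_grid()].
#' @return a [binary_mask()] with the threshold attached as attribute
#'   `threshold`.
#' @export
auto_threshold <- function(grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  x <- grid$values
  if (diff(range(x)) == 0)
    stop("degenerate input: constant image has no threshold")
  t <- mean(x)
  for (i in 1:1000) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(hi)) { t <- max(x[x < max(x)]); next }
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-10 * max(1, diff(range(x)))) { t <- t_new; break }
    t <- t_new
  }
  m <- binary_mask(x > t, grid$pixel_size)
  attr(m, "threshold") <- t
  m
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions (4-connected, the dual of the 8-connected foreground
#' convention) that do not touch the raster border are set TRUE; cavities
#' open to the border are left unfilled and foreground is unchanged.
#'
#' @param mask a [binary_mask()].
#' @return the filled `binary_mask`.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values
  bg <- label_components(!m, connectivity = 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels != 0L]
  hole <- bg != 0L & !(bg %in% border_labels)
  binary_mask(m | matrix(hole, nrow(m)), mask$pixel_size)
}

#' Combine focus mask and intensity mask
#'
#' Pixel-wise logical AND: an object survives only where it is both "in
#' focus" (edge-derived, hole-filled mask) and above the intensity
#' threshold of the original image.
#'
#' @param filled_edges,thresholded_original [binary_mask()]s of identical
#'   shape.
#' @return the combined `binary_mask`.
#' @export
combine_focus <- function(filled_edges, thresholded_original) {
  stopifnot(inherits(filled_edges, "binary_mask"),
            inherits(thresholded_original, "binary_mask"))
  stopifnot_same_shape(filled_edges, thresholded_original, "masks")
  binary_mask(filled_edges$values & thresholded_original$values,
              filled_edges$pixel_size)
}

# Second-moment summaries of one labelled component. The best-fit ellipse
# has moment-matched semi-axes a = 2 sqrt(l1), b = 2 sqrt(l2) (l1 >= l2
# eigenvalues of the pixel covariance with the 1/12 px^2 grid correction).
component_moments <- function(rows, cols, ps) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  vr <- sum((rows - mr)^2) / n + 1 / 12
  vc <- sum((cols - mc)^2) / n + 1 / 12
  vrc <- sum((rows - mr) * (cols - mc)) / n
  tr <- vr + vc
  det <- vr * vc - vrc * vrc
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  # orientation of the major axis: eigenvector for l1, angle measured from
  # the +x (column) axis towards +y (row), in [0, 180)
  if (abs(vrc) < 1e-12 && vc >= vr) {
    ang <- 0
  } else if (abs(vrc) < 1e-12) {
    ang <- 90
  } else {
    ang <- rad2deg(atan2(l1 - vc, vrc))
  }
  list(n = n, centroid_rc = c(mr, mc),
       major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
       orientation_deg = ang %% 180)
}

# Chain-code perimeter estimate for circularity (even steps 1, odd sqrt(2)),
# computed on the component's 8-connected outer boundary.
component_perimeter <- function(sub) {
  # sub: logical matrix of the component padded with FALSE
  b <- sub & !(rbind(FALSE, sub[-nrow(sub), ]) &
                 rbind(sub[-1, ], FALSE) &
                 cbind(FALSE, sub[, -ncol(sub)]) &
                 cbind(sub[, -1], FALSE))
  idx <- which(b, arr.ind = TRUE)
  if (nrow(idx) < 2) return(4)
  # crude estimate: boundary pixel count scaled by the average chain-code
  # step length of a digital circle
  nrow(idx) * 0.948
}

#' Measure and filter particles in a binary mask
#'
#' Labels 8-connected components and measures each: area (pixel count x
#' pixel_size^2), centroid (um), moment-matched best-fit ellipse axes and
#' orientation, and roundness = 4 area / (pi major_axis^2) (equal to
#' minor/major for an ellipse; 1 for a circle). A particle passes the
#' filter when area >= `min_area` and roundness lies in `roundness_range`.
#' All components are returned with `passes_filter` flags.
#'
#' @param mask a [binary_mask()] with calibrated pixel size.
#' @param min_area um^2.
#' @param roundness_range length-2 numeric.
#' @param shape_measure `"roundness"` (default) or `"circularity"`
#'   (4 pi area / perimeter^2).
#' @return data.frame of class `particle_table` (label, area_um2,
#'   roundness, centroid_x_um, centroid_y_um, major_axis_um,
#'   orientation_deg, passes_filter) with the label raster attached as
#'   attribute `labels` and its calibration as `pixel_size`.
#' @export
analyze_particles <- function(mask, min_area = 0.65,
                              roundness_range = c(0.75, 1),
                              shape_measure = c("roundness", "circularity")) {
  stopifnot(inherits(mask, "binary_mask"))
  shape_measure <- match.arg(shape_measure)
  ps <- mask$pixel_size
  lab <- label_components(mask$values, connectivity = 8L)
  nlab <- max(lab)
  out <- data.frame(label = integer(), area_um2 = numeric(),
                    roundness = numeric(), centroid_x_um = numeric(),
                    centroid_y_um = numeric(), major_axis_um = numeric(),
                    orientation_deg = numeric(), passes_filter = logical())
  if (nlab > 0) {
    idx <- which(lab != 0L)
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    labs <- lab[idx]
    ord <- order(labs)
    rows <- rows[ord]; cols <- cols[ord]; labs <- labs[ord]
    starts <- c(1L, which(diff(labs) != 0L) + 1L, length(labs) + 1L)
    recs <- vector("list", nlab)
    for (k in seq_len(nlab)) {
      sel <- starts[k]:(starts[k + 1L] - 1L)
      mom <- component_moments(rows[sel], cols[sel], ps)
      area <- mom$n * ps^2
      major <- mom$major_px * ps
      shape <- if (shape_measure == "roundness") {
        min(4 * area / (pi * major^2), 1)
      } else {
        r0 <- min(rows[sel]); c0 <- min(cols[sel])
        sub <- matrix(FALSE, diff(range(rows[sel])) + 3L,
                      diff(range(cols[sel])) + 3L)
        sub[cbind(rows[sel] - r0 + 2L, cols[sel] - c0 + 2L)] <- TRUE
        min(4 * pi * mom$n / component_perimeter(sub)^2, 1)
      }
      recs[[k]] <- data.frame(
        label = k, area_um2 = area, roundness = shape,
        centroid_x_um = (mom$centroid_rc[2] - 1) * ps,
        centroid_y_um = (mom$centroid_rc[1] - 1) * ps,
        major_axis_um = major, orientation_deg = mom$orientation_deg,
        passes_filter = area >= min_area &
          shape >= roundness_range[1] & shape <= roundness_range[2])
    }
    out <- do.call(rbind, recs)
  }
  class(out) <- c("particle_table", "data.frame")
  attr(out, "labels") <- lab
  attr(out, "pixel_size") <- ps
  out
}

#' Focus-aware spore detection
#'
#' The full automated spore-measurement pipeline: the image is enlarged by
#' 5% twenty times (bilinear), edges are extracted with a Sobel filter and
#' auto-thresholded, holes in the edge map are filled to produce the
#' "in focus" mask, which is ANDed with the auto-threshold of the
#' (upscaled) original; surviving components are measured and filtered by
#' minimum area and roundness. Areas are reported in um^2 on the original
#' physical calibration regardless of the upscaling.
#'
#' @param grid a calibrated [pixel_grid()].
#' @param min_area minimum particle area, um^2.
#' @param roundness_range accepted roundness interval.
#' @param step_fraction,n_steps upscaling schedule.
#' @param shape_measure see [analyze_particles()].
#' @return a `particle_table` (see [analyze_particles()]).
#' @export
detect_spores <- function(grid, min_area = 0.65, roundness_range = c(0.75, 1),
                          step_fraction = 0.05, n_steps = 20L,
                          shape_measure = "roundness") {
  stopifnot(inherits(grid, "pixel_grid"))
  up <- upscale_image(grid, step_fraction, n_steps)
  edges <- find_edges(up)
  focus <- fill_holes(auto_threshold(edges))
  bright <- auto_threshold(up)
  final <- combine_focus(focus, bright)
  analyze_particles(final, min_area = min_area,
                    roundness_range = roundness_range,
                    shape_measure = shape_measure)
}

#' Write a particle table as TSV
#'
#' @param particles a `particle_table`.
#' @param path output file.
#' @export
write_particles <- function(particles, path) {
  write.table(as.data.frame(particles), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
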