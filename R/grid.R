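#' Calibrated intensity raster
#'
#' A `pixel_grid` is the unit passed between all image operators in
#' sporometry: a 2-D numeric matrix of intensities plus the physical pixel
#' size in micrometres per pixel. Physical coordinates are micrometres with
#' the origin at the centre of the top-left pixel; rows increase downwards
#' (image convention), columns to the right.
#'
#' @param values numeric matrix of finite intensities.
#' @param pixel_size physical size of one pixel, um/px (> 0).
#' @return an object of class `pixel_grid`.
#' @export
pixel_grid <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "pixel_grid")
}

#' Calibrated binary raster
#'
#' Same shape/calibration contract as [pixel_grid()], but logical values.
#'
#' @param values logical matrix.
#' @param pixel_size um/px (> 0).
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.logical(values))
    stop("values must be a logical matrix")
  if (anyNA(values)) stop("values must not contain NA")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "binary_mask")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d px @ %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %.4g um/px, %d foreground px\n",
              nrow(x$values), ncol(x$values), x$pixel_size, sum(x$values)))
  invisible(x)
}

#' @export
dim.pixel_grid <- function(x) dim(x$values)

#' @export
dim.binary_mask <- function(x) dim(x$values)

as_grid_matrix <- function(x) {
  if (inherits(x, "pixel_grid") || inherits(x, "binary_mask")) x$values else x
}

stopifnot_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(as_grid_matrix(a)), dim(as_grid_matrix(b))))
    stop(sprintf("%s must have identical shapes", what))
}

# -- low-level raster utilities ----------------------------------------------

# Pad a matrix by replicating its border rows/columns k times on every side.
pad_replicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# Correlate with a small kernel using replicate border handling; the kernel
# is applied as-is (no flipping), which is what the Sobel convention needs.
correlate2d <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  p <- pad_replicate(m, max(pr, pc))
  off <- max(pr, pc)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (kernel[i, j] == 0) next
      rows <- (off - pr + i - 1L) + seq_len(nrow(m))
      cols <- (off - pc + j - 1L) + seq_len(ncol(m))
      out <- out + kernel[i, j] * p[rows, cols, drop = FALSE]
    }
  }
  out
}

# Separable Gaussian blur with replicate borders; sigma in pixels.
gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, half)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, ncol(p))
  for (i in seq_along(k))
    tmp <- tmp + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k))
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}

#' Gaussian blur of a calibrated grid
#'
#' @param grid a [pixel_grid()].
#' @param sigma_um Gaussian standard deviation in micrometres.
#' @return a blurred `pixel_grid` of the same shape and calibration.
#' @export
gaussian_blur <- function(grid, sigma_um) {
  stopifnot(inherits(grid, "pixel_grid"))
  pixel_grid(gaussian_blur_matrix(grid$values, sigma_um / grid$pixel_size),
             grid$pixel_size)
}

# Bilinear resampling to an explicit target shape. Output pixel centres are
# mapped into input coordinates with the extent-aligned convention
# x_in = (x_out + 0.5) * n_in/n_out - 0.5, so the physical field of view is
# preserved.
resize_bilinear_matrix <- function(m, nr_out, nc_out) {
  nr <- nrow(m); nc <- ncol(m)
  r_in <- (seq_len(nr_out) - 0.5) * nr / nr_out - 0.5
  c_in <- (seq_len(nc_out) - 0.5) * nc / nc_out - 0.5
  r0 <- pmin(pmax(floor(r_in), 0), nr - 1)
  c0 <- pmin(pmax(floor(c_in), 0), nc - 1)
  r1 <- pmin(r0 + 1, nr - 1)
  c1 <- pmin(c0 + 1, nc - 1)
  fr <- pmin(pmax(r_in - r0, 0), 1)
  fc <- pmin(pmax(c_in - c0, 0), 1)
  # gather the four corner grids via index matrices
  i00 <- outer(r0 + 1, (c0) * nr, `+`)
  i10 <- outer(r1 + 1, (c0) * nr, `+`)
  i01 <- outer(r0 + 1, (c1) * nr, `+`)
  i11 <- outer(r1 + 1, (c1) * nr, `+`)
  wr <- matrix(fr, nr_out, nc_out)
  wc <- matrix(fc, nr_out, nc_out, byrow = TRUE)
  v <- m[i00] * (1 - wr) * (1 - wc) + m[i10] * wr * (1 - wc) +
    m[i01] * (1 - wr) * wc + m[i11] * wr * wc
  matrix(v, nr_out, nc_out)
}

# -- connected components and binary morphology ------------------------------

#' Label connected components of a binary mask
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param connectivity 8 (default, foreground convention) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  m <- as_grid_matrix(mask)
  if (!is.logical(m)) m <- m > 0
  .label_components_cpp(m, as.integer(connectivity))
}

# Binary dilation with a disc structuring element of radius r pixels,
# implemented as an OR over shifted copies.
dilate_disc <- function(m, r) {
  if (r <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      if (dr * dr + dc * dc > r * r + 1e-9) next
      # shift without wrap: build an all-FALSE frame and paste
      sh <- matrix(FALSE, nr, nc)
      rsrc <- seq_len(nr) - dr
      csrc <- seq_len(nc) - dc
      rok <- rsrc >= 1L & rsrc <= nr
      cok <- csrc >= 1L & csrc <= nc
      sh[rok, cok] <- m[rsrc[rok], csrc[cok], drop = FALSE]
      out <- out | sh
    }
  }
  out
}

# -- TIFF input/output -------------------------------------------------------

#' Read a (possibly multi-page) TIFF into pixel grids
#'
#' Pages are read on tiff's normalised `[0,1]` scale and multiplied by
#' `scale`, the inverse of the convention used by [write_pixel_grids()],
#' so 8-bit-like intensities round-trip. Calibration is taken from
#' `pixel_size`, or from the TIFF x-resolution tag when present (assuming
#' pixels per centimetre or inch as declared by the unit tag).
#'
#' @param path TIFF file.
#' @param pixel_size um/px; overrides any file tags.
#' @param scale multiplier applied after reading.
#' @return a list of [pixel_grid()]s, one per page.
#' @export
read_pixel_grids <- function(path, pixel_size = NULL, scale = 255) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (is.null(pixel_size)) {
      info <- attributes(p)
      ps <- NA_real_
      if (!is.null(info$x.resolution) && info$x.resolution > 0) {
        unit.um <- switch(as.character(info$resolution.unit %||% "inch"),
                          cm = 1e4, inch = 25400, 25400)
        ps <- unit.um / info$x.resolution
      }
      if (!is.finite(ps))
        stop("pixel_size not given and no usable resolution tag in TIFF")
    } else ps <- pixel_size
    v <- p
    if (length(dim(v)) == 3L) v <- v[, , 1]
    pixel_grid(matrix(as.numeric(v) * scale, nrow(v), ncol(v)), ps)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pixel grids to a multi-page 32-bit TIFF
#'
#' Intensities are divided by `scale` (default 255) so that typical
#' 8-bit-like scenes land in `[0,1]`, and clipped to that range — the
#' storage behaves like any fixed-range sensor format, so pick `scale`
#' at least as large as the brightest pixel.
#'
#' @param grids a `pixel_grid` or list of them.
#' @param path output file.
#' @param scale divisor applied before writing.
#' @export
write_pixel_grids <- function(grids, path, scale = 255) {
  if (inherits(grids, "pixel_grid")) grids <- list(grids)
  mats <- lapply(grids, function(g)
    pmin(pmax(as_grid_matrix(g) / scale, 0), 1))
  tiff::writeTIFF(mats, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
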