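#' Zero the background outside the hyphae
#'
#' Sets every pixel outside the hyphae mask to 0 and leaves pixels inside
#' untouched, giving the sufficiently dark background required before
#' integrating per-spore fluorescence.
#'
#' @param grid a [pixel_grid()].
#' @param hyphae_mask a [binary_mask()] of identical shape.
#' @return the corrected `pixel_grid`.
#' @export
background_correct <- function(grid, hyphae_mask) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(hyphae_mask, "binary_mask"))
  stopifnot_same_shape(grid, hyphae_mask, "grid and mask")
  v <- grid$values
  v[!hyphae_mask$values] <- 0
  pixel_grid(v, grid$pixel_size)
}

#' Integrate fluorescence per detected spore
#'
#' Sums the intensity of `grid` over each particle's pixels. When the
#' particle label raster was produced at a different resolution (e.g. after
#' upscaled detection), each pixel of `grid` is assigned to the label
#' covering its physical position (nearest-neighbour in um), so integrals
#' are always taken on the fluorescence image's native grid.
#'
#' @param grid the fluorescence [pixel_grid()].
#' @param particles a `particle_table` from [analyze_particles()] or
#'   [detect_spores()] (carries its label raster).
#' @return named numeric vector: integrated intensity per particle label.
#' @export
integrate_per_spore <- function(grid, particles) {
  stopifnot(inherits(grid, "pixel_grid"))
  lab <- attr(particles, "labels")
  ps_l <- attr(particles, "pixel_size")
  if (is.null(lab) || is.null(ps_l))
    stop("particles must carry a label raster (see analyze_particles)")
  if (nrow(particles) == 0L)
    return(setNames(numeric(0), character(0)))
  ps_g <- grid$pixel_size
  if (identical(dim(lab), dim(grid$values)) &&
      isTRUE(all.equal(ps_l, ps_g))) {
    lab_g <- lab
  } else {
    nr <- nrow(grid$values); nc <- ncol(grid$values)
    rl <- pmin(pmax(round((seq_len(nr) - 1) * ps_g / ps_l) + 1, 1), nrow(lab))
    cl <- pmin(pmax(round((seq_len(nc) - 1) * ps_g / ps_l) + 1, 1), ncol(lab))
    lab_g <- lab[rl, cl, drop = FALSE]
  }
  sums <- vapply(particles$label, function(l) sum(grid$values[lab_g == l]),
                 numeric(1))
  setNames(sums, particles$label)
}

#' Per-chain median normalization of spore DNA content
#'
#' Divides each spore's raw integrated intensity by the median of its
#' chain, setting the chain median to 1 to cancel chain-to-chain staining
#' variation. Only chains of at least `min_chain_length` spores carry
#' enough data to normalize; shorter chains are excluded (reported with
#' `included = FALSE` and `normalized = NA`). The even-length median is the
#' mean of the two central order statistics, so the median of the
#' normalized values of an included chain is exactly 1.
#'
#' @param raw numeric vector of raw integrated intensities (> 0), or a
#'   data.frame with columns `chain` and `raw` (optional `spore`).
#' @param chain chain membership vector (required when `raw` is numeric).
#' @param min_chain_length minimum spores per chain for inclusion.
#' @return data.frame of class `chain_dna_table`: chain, spore, raw,
#'   normalized, chain_length, included.
#' @export
median_normalize <- function(raw, chain = NULL, min_chain_length = 10L) {
  if (is.data.frame(raw)) {
    df <- raw
    if (!all(c("chain", "raw") %in% names(df)))
      stop("data.frame input needs columns 'chain' and 'raw'")
    if (is.null(df$spore)) df$spore <- seq_len(nrow(df))
  } else {
    if (is.null(chain)) stop("chain membership required")
    if (length(chain) != length(raw))
      stop("raw and chain must have the same length")
    df <- data.frame(chain = chain, spore = seq_along(raw), raw = raw)
  }
  bad <- which(!is.finite(df$raw) | df$raw <= 0)
  if (length(bad))
    stop(sprintf("non-positive raw intensity for spore %s (chain %s)",
                 df$spore[bad[1]], df$chain[bad[1]]))
  df$chain_length <- ave(df$raw, df$chain, FUN = length)
  df$included <- df$chain_length >= min_chain_length
  df$normalized <- NA_real_
  if (any(df$included)) {
    med <- ave(df$raw, df$chain, FUN = median)
    df$normalized[df$included] <- df$raw[df$included] / med[df$included]
  }
  out <- df[, c("chain", "spore", "raw", "normalized", "chain_length",
                "included")]
  class(out) <- c("chain_dna_table", "data.frame")
  out
}

#' Pooled histogram of normalized DNA contents
#'
#' Pools the normalized contents of all included chains into a frequency
#' distribution, and reports per-chain ranges and the pooled variance —
#' the summary used to contrast tight (wild-type-like) against broad
#' (ectopic-division) DNA content distributions.
#'
#' @param tables a `chain_dna_table` or list of them.
#' @param bin_width histogram bin width in chromosome-equivalents.
#' @return list of class `dna_histogram`: `breaks`, `counts`, `mids`,
#'   `per_chain` (chain, n, min, max), `pooled_variance`, `n`.
#' @export
dna_histogram <- function(tables, bin_width = 0.1) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  df <- df[df$included & !is.na(df$normalized), , drop = FALSE]
  if (!nrow(df)) stop("no included chains to pool")
  x <- df$normalized
  breaks <- seq(0, ceiling(max(x) / bin_width + 1e-9) * bin_width,
                by = bin_width)
  h <- hist(x, breaks = breaks, plot = FALSE)
  per_chain <- do.call(rbind, lapply(split(df$normalized, df$chain),
    function(v) data.frame(n = length(v), min = min(v), max = max(v))))
  per_chain <- data.frame(chain = rownames(per_chain), per_chain,
                          row.names = NULL)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 per_chain = per_chain,
                 pooled_variance = if (length(x) > 1) var(x) else 0,
                 n = length(x)),
            class = "dna_histogram")
}

#' @importFrom graphics hist
#' @importFrom stats ave
NULL
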