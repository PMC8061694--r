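#' Mean grey value of a fixed circular ROI through a time-lapse stack
#'
#' Measures the mean intensity inside one circle (identical across frames,
#' pixel-centre-in-circle membership) for every frame of a scanner stack.
#'
#' @param stack rows x cols x frames numeric array, or the result of
#'   [make_colony_stack()].
#' @param centre (x, y) circle centre in pixels.
#' @param radius circle radius in pixels.
#' @param frame_interval minutes between frames.
#' @return an object of class `colony_trace`: list with `times_min` and
#'   `values` (one mean per frame).
#' @export
roi_mean_series <- function(stack, centre, radius, frame_interval = 30) {
  if (is.list(stack) && !is.null(stack$stack)) {
    frame_interval <- stack$spec$frame_interval
    stack <- stack$stack
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  if (centre[1] - radius < 1 || centre[1] + radius > nc ||
      centre[2] - radius < 1 || centre[2] + radius > nr)
    stop("ROI circle exceeds frame bounds")
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- (rr - centre[2])^2 + (cc - centre[1])^2 <= radius^2
  vals <- vapply(seq_len(nf), function(f) mean(stack[, , f][inside]),
                 numeric(1))
  structure(list(times_min = (seq_len(nf) - 1) * frame_interval,
                 values = vals),
            class = "colony_trace")
}

#' Classify the sporulation phenotype of a colony trace
#'
#' Sporulating colonies accumulate the grey spore pigment and darken, i.e.
#' their scanner grey value drops over the time course. The darkening
#' statistic is `initial - final` grey value (`"endpoint"`, default) or
#' `initial - mean` over the whole course (`"integral"`); the colony is
#' classed `grey` when darkening >= `t_hi`, `white` when <= `t_lo`, and
#' `light-grey` in between. Classification is monotone in the darkening.
#'
#' @param trace a [roi_mean_series()] result, or a numeric vector of grey
#'   values.
#' @param t_lo,t_hi darkening thresholds (grey values), `t_lo < t_hi`.
#' @param statistic `"endpoint"` or `"integral"`.
#' @return character class, with the darkening attached as attribute
#'   `darkening`.
#' @export
classify_phenotype <- function(trace, t_lo = 20, t_hi = 65,
                               statistic = c("endpoint", "integral")) {
  statistic <- match.arg(statistic)
  if (t_lo >= t_hi) stop("config error: need t_lo < t_hi")
  v <- if (inherits(trace, "colony_trace")) trace$values else as.numeric(trace)
  if (!length(v)) stop("empty trace")
  darkening <- switch(statistic,
                      endpoint = v[1] - v[length(v)],
                      integral = v[1] - mean(v))
  cls <- if (darkening >= t_hi) "grey"
    else if (darkening <= t_lo) "white"
    else "light-grey"
  attr(cls, "darkening") <- darkening
  cls
}

#' Measure and classify every colony of a scanner stack
#'
#' @param colony_stack result of [make_colony_stack()], or a list with
#'   `stack` and a `colonies` data.frame (colony, x_px, y_px, roi_radius).
#' @param t_lo,t_hi,statistic see [classify_phenotype()].
#' @return data.frame: colony, darkening, class (and `planted` when the
#'   stack carries ground truth).
#' @export
analyze_colonies <- function(colony_stack, t_lo = 20, t_hi = 65,
                             statistic = "endpoint") {
  cols <- colony_stack$colonies
  out <- lapply(seq_len(nrow(cols)), function(i) {
    tr <- roi_mean_series(colony_stack,
                          centre = c(cols$x_px[i], cols$y_px[i]),
                          radius = cols$roi_radius[i])
    cl <- classify_phenotype(tr, t_lo, t_hi, statistic)
    data.frame(colony = cols$colony[i],
               darkening = attr(cl, "darkening"), class = as.character(cl))
  })
  out <- do.call(rbind, out)
  if (!is.null(cols$class)) out$planted <- cols$class
  out
}
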