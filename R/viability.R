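#' Live/dead classification from a Syto9/PI channel pair
#'
#' Integrates the green (Syto9, all cells) and red (propidium iodide,
#' membrane-compromised cells) channels over each detected spore and calls
#' a spore dead when its red integral exceeds `ratio` times its green
#' integral. Ties are classified live, so the rule is deterministic, and
#' verdicts are invariant under equal rescaling of both channels.
#'
#' @param green,red the two [pixel_grid()] channels, aligned and equally
#'   calibrated.
#' @param particles a `particle_table` (see [analyze_particles()]).
#' @param ratio red/green threshold r: dead iff red > r * green.
#' @return list of class `viability_result`: `records` (data.frame: spore,
#'   green, red, verdict) and `pct_dead`.
#' @export
classify_viability <- function(green, red, particles, ratio = 1) {
  stopifnot(inherits(green, "pixel_grid"), inherits(red, "pixel_grid"))
  if (!identical(dim(green$values), dim(red$values)))
    stop("channel shape mismatch")
  if (!isTRUE(all.equal(green$pixel_size, red$pixel_size)))
    stop("channel calibration mismatch")
  g <- integrate_per_spore(green, particles)
  r <- integrate_per_spore(red, particles)
  verdict <- ifelse(r > ratio * g, "dead", "live")
  records <- data.frame(spore = particles$label, green = unname(g),
                        red = unname(r), verdict = verdict)
  structure(list(records = records,
                 pct_dead = if (nrow(records) > 0)
                   100 * mean(verdict == "dead") else NA_real_,
                 ratio = ratio),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result> %d spores, %s%% dead (threshold r = %g)\n",
              nrow(x$records), fmt1(x$pct_dead), x$ratio))
  invisible(x)
}
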