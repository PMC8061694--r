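# Shared fixtures: small synthetic scenes and matching utilities.

tem_scene <- function(...) {
  make_spore_chain_scene(scene_spec(channels = "tem", ...))
}

# Match each detected septum to the nearest planted septum anchor.
match_septa <- function(detected, truth) {
  vapply(seq_len(nrow(detected)), function(i)
    which.min((truth$x_um - detected$x_um[i])^2 +
                (truth$y_um - detected$y_um[i])^2), integer(1))
}

# A particle table for an explicit logical mask (calibrated).
particles_of <- function(mask_values, pixel_size = 0.05, ...) {
  analyze_particles(binary_mask(mask_values, pixel_size), ...)
}

# Logical disc / axis-aligned ellipse masks on an nr x nc raster.
disc_mask <- function(nr, nc, cy, cx, r) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

ellipse_mask <- function(nr, nc, cy, cx, a_col, b_row) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((cc - cx) / a_col)^2 + ((rr - cy) / b_row)^2 <= 1
}
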