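#' Match detected particles to planted spores
#'
#' Assigns each detected particle to the nearest planted spore centroid
#' (within `max_dist_um`), giving detected spores their chain membership
#' and ground-truth attributes for recovery analyses.
#'
#' @param particles a `particle_table`.
#' @param spores truth spore table (columns x_um, y_um, chain, spore, ...).
#' @param max_dist_um maximum centroid distance for a match.
#' @return `particles` with columns `chain`, `truth_spore` (NA when
#'   unmatched) appended.
#' @export
match_particles_to_truth <- function(particles, spores, max_dist_um = 0.6) {
  particles$chain <- NA_integer_
  particles$truth_spore <- NA_integer_
  for (i in seq_len(nrow(particles))) {
    d2 <- (spores$x_um - particles$centroid_x_um[i])^2 +
      (spores$y_um - particles$centroid_y_um[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist_um^2) {
      particles$chain[i] <- spores$chain[j]
      particles$truth_spore[i] <- spores$spore[j]
    }
  }
  particles
}

#' Heuristic chain linking of detected spores
#'
#' Links detected particles into chains by single-linkage on centroid
#' distance: two spores join the same chain when their centroids are
#' within `gap_factor` times the median major-axis length. This is a
#' geometric heuristic for real images without ground truth; prefer an
#' explicit chain assignment when one is available.
#'
#' @param particles a `particle_table`.
#' @param gap_factor linkage distance in units of the median major axis.
#' @return integer chain id per particle row.
#' @export
assign_chains_heuristic <- function(particles, gap_factor = 1.6) {
  n <- nrow(particles)
  if (n == 0) return(integer(0))
  thr <- gap_factor * median(particles$major_axis_um)
  d <- as.matrix(dist(cbind(particles$centroid_x_um,
                            particles$centroid_y_um)))
  chain <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (chain[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (chain[j] > 0L) next
      chain[j] <- cur
      queue <- c(queue, which(d[j, ] <= thr & chain == 0L))
    }
  }
  chain
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full scene analysis pipeline
#'
#' Orchestrates synthetic generation (when `config$scene` is given) or
#' image loading (when `config$inputs` paths are given), followed by spore
#' detection, septum measurement and classification, split-spore counting,
#' DNA quantification and live/dead classification, and assembles a
#' machine-readable summary. Every artifact is stamped with the config
#' hash and seed; re-running with the same config and seed reproduces the
#' summary byte for byte. Percentages in the summary are reported to one
#' decimal place.
#'
#' @param config a list (or YAML file path) with exactly one of:
#'   * `scene`: a [scene_spec()] (or argument list for one), or
#'   * `inputs`: list of TIFF paths (`tem`, optionally `dna`, `syto9`,
#'     `pi`) plus `pixel_size`;
#'   and optional blocks `detection` (min_area, roundness_range), `septa`
#'   (dark_threshold, dilate_um, canonical_max, longitudinal_min), `dna`
#'   (min_chain_length), `viability` (ratio), plus `seed` and `out_dir`.
#' @return list of class `scene_analysis`: `summary`, `particles`,
#'   `septa`, `septum_stats`, `dna`, `viability`, `scene`.
#' @export
run_scene_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$scene) == is.null(config$inputs))
    stop("config must contain exactly one of 'scene' or 'inputs'")
  chash <- config_hash(config[setdiff(names(config),
                                      c("out_dir", "verbose"))])
  seed <- config$seed %||% 1L
  det <- config$detection %||% list()
  sep_par <- config$septa %||% list()
  dna_par <- config$dna %||% list()
  via_par <- config$viability %||% list()

  truth <- NULL
  if (!is.null(config$scene)) {
    scene <- run_stage("synthgen", {
      spec <- config$scene
      if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
      spec$seed <- stage_seed(seed, "synthgen")
      make_spore_chain_scene(spec)
    })
    channels <- scene$channels
    truth <- scene$truth
  } else {
    channels <- run_stage("load", {
      ps <- config$inputs$pixel_size
      chs <- list()
      for (nm in intersect(names(config$inputs), c("tem", "dna", "syto9", "pi")))
        chs[[nm]] <- read_pixel_grids(config$inputs[[nm]], ps)[[1]]
      chs
    })
    scene <- list(channels = channels, truth = NULL)
  }
  if (is.null(channels$tem)) stop("a 'tem' (morphology) channel is required")

  particles <- run_stage("sporeseg", do.call(detect_spores,
    c(list(grid = channels$tem), det)))

  septa <- run_stage("septometry", do.call(detect_septa,
    c(list(grid = channels$tem), sep_par)))

  split_flags <- NULL
  if (!is.null(truth)) {
    split_flags <- run_stage("septometry", count_split_spores(
      auto_threshold(channels$tem), truth$spores))
  }
  stats <- classify_and_tally(septa, split_flags,
    canonical_max = sep_par$canonical_max %||% 10,
    longitudinal_min = sep_par$longitudinal_min %||% 85)

  dna_tab <- NULL
  if (!is.null(channels$dna)) {
    dna_tab <- run_stage("dnaquant", {
      pk <- particles[particles$passes_filter, , drop = FALSE]
      attr(pk, "labels") <- attr(particles, "labels")
      attr(pk, "pixel_size") <- attr(particles, "pixel_size")
      chain <- if (!is.null(truth)) {
        match_particles_to_truth(pk, truth$spores)$chain
      } else assign_chains_heuristic(pk)
      keep <- !is.na(chain)
      raw <- integrate_per_spore(channels$dna, pk)[keep]
      median_normalize(raw, chain[keep],
                       min_chain_length = dna_par$min_chain_length %||% 10L)
    })
  }

  viab <- NULL
  if (!is.null(channels$syto9) && !is.null(channels$pi)) {
    viab <- run_stage("viability", classify_viability(
      channels$syto9, channels$pi, particles[particles$passes_filter, ] |>
        (\(p) { attr(p, "labels") <- attr(particles, "labels")
                attr(p, "pixel_size") <- attr(particles, "pixel_size"); p })(),
      ratio = via_par$ratio %||% 1))
  }

  dna_summary <- if (!is.null(dna_tab) && any(dna_tab$included)) {
    v <- dna_tab$normalized[dna_tab$included]
    list(n_spores = length(v), n_chains = length(unique(
           dna_tab$chain[dna_tab$included])),
         min = round(min(v), 3), max = round(max(v), 3),
         variance = round(var(v), 5))
  } else NULL

  summary <- list(
    config_hash = chash, seed = seed,
    n_particles = nrow(particles),
    n_particles_pass = sum(particles$passes_filter),
    n_septa = stats$n_septa, n_rotated = stats$n_rotated,
    pct_rotated = round1(stats$pct_rotated),
    n_longitudinal = stats$n_longitudinal,
    pct_longitudinal_of_rotated = round1(stats$pct_longitudinal_of_rotated),
    n_spores = stats$n_spores, n_split = stats$n_split,
    pct_split = round1(stats$pct_split),
    pct_dead = if (!is.null(viab)) round1(viab$pct_dead) else NULL,
    dna = dna_summary)

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_particles(particles, file.path(out, "particles.tsv"))
    write_septum_results(septa, stats, out)
    if (!is.null(dna_tab))
      write.table(as.data.frame(dna_tab), file.path(out, "dna.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(viab))
      write.table(viab$records, file.path(out, "viability.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(summary = summary, particles = particles, septa = septa,
                 septum_stats = stats, dna = dna_tab, viability = viab,
                 scene = scene),
            class = "scene_analysis")
}

round1 <- function(x) if (is.null(x) || is.na(x)) x else round(x, 1)

#' @export
print.scene_analysis <- function(x, ...) {
  s <- x$summary
  cat("<scene_analysis>\n")
  cat(sprintf("  particles: %d detected, %d pass filter\n",
              s$n_particles, s$n_particles_pass))
  cat(sprintf("  septa: %d (%s%% rotated; %s%% of rotated longitudinal)\n",
              s$n_septa, fmt1(s$pct_rotated),
              fmt1(s$pct_longitudinal_of_rotated)))
  if (s$n_spores > 0)
    cat(sprintf("  split spores: %d/%d (%s%%)\n", s$n_split, s$n_spores,
                fmt1(s$pct_split)))
  if (!is.null(s$pct_dead))
    cat(sprintf("  dead spores: %s%%\n", fmt1(s$pct_dead)))
  if (!is.null(s$dna))
    cat(sprintf("  DNA content (median-scaled): %g-%g, var %g (n=%d)\n",
                s$dna$min, s$dna$max, s$dna$variance, s$dna$n_spores))
  invisible(x)
}
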