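#' @useDynLib sporometry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rbinom rpois sd var setNames
#' @importFrom utils write.table read.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are reproducible without
# side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# djb2-style rolling hash of a character string, kept in [0, 2^31 - 2]
# (exact in double arithmetic: intermediate values stay below 2^53).
str_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483646
  h
}

#' Derive a per-stage RNG substream seed
#'
#' One global seed is expanded into independent per-stage seeds by hashing
#' the stage name and mixing it with the global seed, so adding a stage
#' never perturbs the streams of earlier stages.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((str_hash(stage) + as.numeric(seed) * 48271) %% 2147483646 + 1)
}

# Short config fingerprint for stamping outputs (rolling hash over the deparsed
# object).
config_hash <- function(x) {
  sprintf("%08x", str_hash(paste(deparse(x), collapse = "\n")))
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Fold an angle difference (degrees) into [0, 90].
fold90 <- function(d) {
  d <- abs(d) %% 180
  ifelse(d > 90, 180 - d, d)
}
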