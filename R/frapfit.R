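#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of I(t) = P - (P - B) exp(-t / tau) to a
#' bleach-recovery trace (Levenberg-Marquardt). Initial values: B = first
#' sample, P = mean of the last 10% of samples, tau = time at which the
#' trace first crosses B + (P - B)(1 - 1/e), by linear interpolation.
#' The reported `recovery_time` is the time to 95% of the recoverable
#' signal, tau * ln(20); the half-time tau * ln(2) is reported alongside,
#' since published "recovery times" may be either.
#'
#' tau is covariant with the time units and invariant under affine
#' transformations a I + b of the intensities.
#'
#' @param trace a `frap_trace` (see [simulate_frap_trace()]) or data.frame
#'   with columns `time_s` and `intensity` (>= 5 samples, strictly
#'   increasing times).
#' @param tol convergence tolerance on the parameters.
#' @return an object of class `frap_fit`: list with `plateau`,
#'   `bleach_depth`, `tau_s`, `recovery_time_s`, `half_time_s`,
#'   `residual_rms`, `n`.
#' @export
fit_recovery <- function(trace, tol = 1e-8) {
  df <- as.data.frame(trace)
  if (!all(c("time_s", "intensity") %in% names(df)))
    stop("trace needs columns time_s and intensity")
  t <- df$time_s; y <- df$intensity
  if (length(t) < 5) stop("trace too short (need >= 5 samples)")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  n10 <- max(1L, ceiling(length(y) * 0.1))
  B0 <- y[1]
  P0 <- mean(y[(length(y) - n10 + 1):length(y)])
  if (P0 <= B0)
    stop("fit failure: trace does not recover (no average increase)")
  target <- B0 + (P0 - B0) * (1 - exp(-1))
  above <- which(y >= target)
  tau0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    t[i - 1] + (t[i] - t[i - 1]) * (target - y[i - 1]) / (y[i] - y[i - 1])
  } else if (length(above)) t[2] else t[length(t)] / 2
  tau0 <- max(tau0, diff(t[1:2]) / 10)
  resid_fn <- function(par)
    y - (par[1] - (par[1] - par[2]) * exp(-t / par[3]))
  fit <- try(minpack.lm::nls.lm(
    par = c(P = P0, B = B0, tau = tau0), fn = resid_fn,
    lower = c(-Inf, -Inf, 1e-12),
    control = minpack.lm::nls.lm.control(ptol = tol, ftol = tol,
                                         maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("fit failure: ", attr(fit, "condition")$message)
  p <- as.list(fit$par)
  if (p$P <= p$B)
    stop("fit failure: fitted plateau does not exceed bleach depth")
  structure(list(plateau = p$P, bleach_depth = p$B, tau_s = p$tau,
                 recovery_time_s = p$tau * log(20),
                 half_time_s = p$tau * log(2),
                 residual_rms = sqrt(mean(fit$fvec^2)),
                 n = length(t)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> tau = %.3g s, recovery time (95%%) = %.3g s, half-time = %.3g s, P = %.3g, B = %.3g, rms = %.3g\n",
    x$tau_s, x$recovery_time_s, x$half_time_s, x$plateau, x$bleach_depth,
    x$residual_rms))
  invisible(x)
}

#' Fit a set of FRAP traces
#'
#' @param traces list of traces (see [fit_recovery()]).
#' @return data.frame: trace, plateau, bleach_depth, tau_s,
#'   recovery_time_s, half_time_s, residual_rms.
#' @export
fit_recovery_set <- function(traces) {
  out <- lapply(seq_along(traces), function(i) {
    f <- fit_recovery(traces[[i]])
    data.frame(trace = i, plateau = f$plateau, bleach_depth = f$bleach_depth,
               tau_s = f$tau_s, recovery_time_s = f$recovery_time_s,
               half_time_s = f$half_time_s, residual_rms = f$residual_rms)
  })
  do.call(rbind, out)
}

#' Read FRAP traces from CSV
#'
#' Expects columns `time_s` and `intensity`, with an optional `trace`
#' column separating multiple traces.
#'
#' @param path CSV file.
#' @return list of `frap_trace` data.frames.
#' @export
read_frap_traces <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(df)))
    stop("CSV needs columns time_s and intensity")
  if (is.null(df$trace)) df$trace <- 1L
  lapply(split(df, df$trace), function(d)
    structure(data.frame(time_s = d$time_s, intensity = d$intensity),
              class = c("frap_trace", "data.frame")))
}

#' @importFrom stats coef residuals
NULL
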