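# Shared helpers: phase wrapping, unit conversions, small validators.

#' Wrap phase angles into [-pi, pi)
#'
#' @param phi numeric array of phase values, radians.
#' @return same shape, wrapped into the half-open interval \eqn{[-\pi, \pi)}.
#' @export
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # %% can return 2*pi - eps for inputs just below -pi due to rounding
  out[out >= pi] <- out[out >= pi] - 2 * pi
  out
}

# 1 cm/s flowing through 1 mm^2 is 10 mm^3/s = 0.6 mL/min
CMS_MM2_TO_ML_MIN <- 0.6
# mL/min integrated over seconds -> microlitres
ML_MIN_S_TO_UL <- 1000 / 60

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Frame midpoint times for n frames spanning one RR interval
frame_times <- function(n_frames, rr_interval) {
  (seq_len(n_frames) - 0.5) / n_frames * rr_interval
}
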