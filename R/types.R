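# Core containers: cine series, ROI masks, flow-measure records.

#' Gated cine phase-contrast series (one slice)
#'
#' @param magnitude numeric array \code{[y, x, t]}, non-negative.
#' @param phase numeric array \code{[y, x, t]}, radians in \eqn{[-\pi, \pi)}.
#' @param venc velocity-encoding limit, cm/s.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness mm.
#' @param rr_interval cardiac period, s.
#' @param sign_convention flow-direction convention; only
#'   \code{"caudal_positive"} (towards the fourth ventricle positive) is
#'   defined.
#' @param seed optional integer provenance seed.
#' @return object of class \code{cine_pc_series}.
#' @export
cine_pc_series <- function(magnitude, phase, venc, pixel_spacing,
                           slice_thickness, rr_interval,
                           sign_convention = "caudal_positive", seed = NULL) {
  if (!is.array(magnitude) || !is.array(phase) || length(dim(magnitude)) != 3L)
    stop("magnitude and phase must be [y, x, t] arrays", call. = FALSE)
  if (!identical(dim(magnitude), dim(phase)))
    stop("magnitude and phase shapes differ", call. = FALSE)
  if (dim(magnitude)[3] < 2L) stop("need at least 2 frames", call. = FALSE)
  if (any(magnitude < 0)) stop("magnitude must be non-negative", call. = FALSE)
  stopifnot_scalar(venc, "venc", positive = TRUE)
  stopifnot_scalar(rr_interval, "rr_interval", positive = TRUE)
  sign_convention <- match.arg(sign_convention, "caudal_positive")
  structure(list(magnitude = magnitude, phase = phase, venc = venc,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 rr_interval = rr_interval, n_frames = dim(magnitude)[3],
                 sign_convention = sign_convention, seed = seed),
            class = "cine_pc_series")
}

#' @export
print.cine_pc_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "cine PC series: %d x %d pixels, %d frames | VENC %g cm/s | %g mm px | RR %g s\n",
    d[1], d[2], d[3], x$venc, x$pixel_spacing, x$rr_interval))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param pixels logical (or 0/1) matrix \code{[y, x]}.
#' @param label \code{"AOS"} (aqueduct lumen) or \code{"NFA"} (static-tissue
#'   no-flow reference area).
#' @return object of class \code{roi_mask}.
#' @export
roi_mask <- function(pixels, label = c("AOS", "NFA")) {
  label <- match.arg(label)
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix", call. = FALSE)
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("mask values must be binary (0/1)", call. = FALSE)
    pixels <- pixels > 0
  }
  if (!is.logical(pixels)) stop("mask must be logical or 0/1", call. = FALSE)
  structure(list(pixels = pixels, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask [%s]: %d px on a %d x %d grid\n", x$label,
              sum(x$pixels), nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

as_mask_matrix <- function(m, label = NULL) {
  if (inherits(m, "roi_mask")) {
    if (!is.null(label) && m$label != label)
      stop(sprintf("expected a %s mask, got %s", label, m$label),
           call. = FALSE)
    m$pixels
  } else if (is.matrix(m)) {
    m > 0
  } else stop("expected an roi_mask or a matrix", call. = FALSE)
}

MEASURE_NAMES <- c("csa_avg", "vmean_sys_peak", "vmean_dia_peak", "vmean_avg",
                   "vmax_sys_peak", "vmax_dia_peak",
                   "fr_sys_peak", "fr_dia_peak", "fr_avg",
                   "caudal_volume", "cranial_volume", "net_volume")

#' Cycle summary flow measures
#'
#' The twelve scalar measures retained for statistical analysis: cycle-average
#' cross-sectional area (mm^2); systolic/diastolic peaks and cycle average of
#' the spatial-mean velocity (cm/s); systolic/diastolic peaks of the signed
#' maximal velocity (cm/s); peaks and average of the flow rate (mL/min); and
#' caudal (>= 0), cranial (<= 0, signed) and net displaced volumes per cardiac
#' cycle (microlitres). The cycle average of Vmax is deliberately not a
#' measure: near flow reversal the maximal-magnitude pixel is ill-defined.
#'
#' @param csa_avg,vmean_sys_peak,vmean_dia_peak,vmean_avg numeric scalars.
#' @param vmax_sys_peak,vmax_dia_peak,fr_sys_peak,fr_dia_peak,fr_avg numeric
#'   scalars.
#' @param caudal_volume,cranial_volume,net_volume numeric scalars.
#' @param rr_interval cardiac period, s (carried for consistency checks).
#' @return object of class \code{flow_measures} (a named list).
#' @export
flow_measures <- function(csa_avg, vmean_sys_peak, vmean_dia_peak, vmean_avg,
                          vmax_sys_peak, vmax_dia_peak,
                          fr_sys_peak, fr_dia_peak, fr_avg,
                          caudal_volume, cranial_volume, net_volume,
                          rr_interval = NA_real_) {
  out <- list(csa_avg = csa_avg,
              vmean_sys_peak = vmean_sys_peak,
              vmean_dia_peak = vmean_dia_peak, vmean_avg = vmean_avg,
              vmax_sys_peak = vmax_sys_peak, vmax_dia_peak = vmax_dia_peak,
              fr_sys_peak = fr_sys_peak, fr_dia_peak = fr_dia_peak,
              fr_avg = fr_avg, caudal_volume = caudal_volume,
              cranial_volume = cranial_volume, net_volume = net_volume)
  stopifnot(all(vapply(out, is.numeric, TRUE)))
  if (caudal_volume < -1e-9) stop("caudal_volume must be >= 0", call. = FALSE)
  if (cranial_volume > 1e-9)
    stop("cranial_volume is stored signed (<= 0)", call. = FALSE)
  attr(out, "rr_interval") <- rr_interval
  class(out) <- "flow_measures"
  out
}

#' @export
print.flow_measures <- function(x, digits = 3, ...) {
  cat("flow measures (one cardiac cycle):\n")
  cat(sprintf("  CSA avg           %8.*f mm^2\n", digits, x$csa_avg))
  cat(sprintf("  Vmean sys/dia/avg %8.*f / %.*f / %.*f cm/s\n", digits,
              x$vmean_sys_peak, digits, x$vmean_dia_peak, digits, x$vmean_avg))
  cat(sprintf("  Vmax  sys/dia     %8.*f / %.*f cm/s\n", digits,
              x$vmax_sys_peak, digits, x$vmax_dia_peak))
  cat(sprintf("  FR    sys/dia/avg %8.*f / %.*f / %.*f mL/min\n", digits,
              x$fr_sys_peak, digits, x$fr_dia_peak, digits, x$fr_avg))
  cat(sprintf("  volume caudal/cranial/net %.*f / %.*f / %.*f uL\n", digits,
              x$caudal_volume, digits, x$cranial_volume, digits,
              x$net_volume))
  invisible(x)
}

#' @export
as.data.frame.flow_measures <- function(x, ...) {
  as.data.frame(unclass(x)[MEASURE_NAMES], ...)
}
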