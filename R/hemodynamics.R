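# Per-frame time courses and the twelve cycle summary measures.

#' Per-frame hydrodynamic time courses
#'
#' For every frame: cross-sectional area (pixel count times pixel area,
#' mm^2), spatial-mean velocity over the mask (cm/s), signed maximal velocity
#' (the value at the pixel of largest |v|, cm/s), and flow rate
#' Vmean x CSA converted to mL/min. Requires background-corrected maps
#' (processing-order contract).
#'
#' @param vmaps background-corrected [velocity_maps()].
#' @param masks logical array \code{[y, x, t]} (from [propagate_mask()]), or
#'   a single mask/segmentation result, which is propagated unchanged.
#' @return object of class \code{time_courses}: \code{csa}, \code{vmean},
#'   \code{vmax}, \code{flow_rate}, \code{times} (frame midpoints, s).
#' @export
compute_timecourses <- function(vmaps, masks) {
  stopifnot(inherits(vmaps, "velocity_maps"))
  if (!vmaps$corrected)
    stop("velocity maps must be background-corrected before quantification",
         call. = FALSE)
  T_ <- dim(vmaps$v)[3]
  if (!(is.array(masks) && length(dim(masks)) == 3L))
    masks <- propagate_mask(masks, T_)
  stopifnot(identical(dim(masks), dim(vmaps$v)))
  csa <- vmean <- vmax <- numeric(T_)
  for (k in seq_len(T_)) {
    mk <- masks[, , k]
    if (!any(mk)) stop(sprintf("empty mask at frame %d", k), call. = FALSE)
    vals <- vmaps$v[, , k][mk]
    csa[k] <- sum(mk) * vmaps$pixel_spacing^2
    vmean[k] <- mean(vals)
    vmax[k] <- vals[which.max(abs(vals))]
  }
  structure(list(csa = csa, vmean = vmean, vmax = vmax,
                 flow_rate = vmean * csa * CMS_MM2_TO_ML_MIN,
                 times = frame_times(T_, vmaps$rr_interval),
                 rr_interval = vmaps$rr_interval),
            class = "time_courses")
}

#' Systolic and diastolic peaks of a per-frame series
#'
#' The systolic peak is the maximum signed value, the diastolic peak the
#' minimum signed value (reported negative for biphasic flow; for an
#' all-positive series it is simply the smallest value — no sign is
#' enforced). Ties break to the earliest frame.
#'
#' @param x numeric per-frame series.
#' @return list with \code{sys}, \code{dia} (values) and \code{sys_frame},
#'   \code{dia_frame} (indices).
#' @export
find_peaks <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  list(sys = max(x), dia = min(x),
       sys_frame = which.max(x), dia_frame = which.min(x))
}

#' Integrate the flow-rate curve into displaced volumes
#'
#' Caudal volume integrates the positive part of the flow rate, cranial the
#' negative part (kept signed, <= 0), net is their signed sum. Integration is
#' the trapezoidal rule on the frame midpoints with periodic closure over the
#' RR interval (for uniformly gated frames this equals the frame mean times
#' the period).
#'
#' @param tc a [compute_timecourses()] result, or a numeric flow-rate series
#'   (mL/min) with \code{rr_interval} supplied.
#' @param rr_interval cardiac period, s (taken from \code{tc} if present).
#' @return named numeric vector \code{c(caudal, cranial, net)} in
#'   microlitres per cycle.
#' @export
integrate_volumes <- function(tc, rr_interval = NULL) {
  if (inherits(tc, "time_courses")) {
    fr <- tc$flow_rate
    rr_interval <- rr_interval %||% tc$rr_interval
    if (is.unsorted(tc$times, strictly = TRUE))
      stop("frame times must be strictly increasing", call. = FALSE)
  } else fr <- as.numeric(tc)
  stopifnot_scalar(rr_interval, "rr_interval", positive = TRUE)
  # periodic trapezoid on uniform midpoints: mean * period
  dt <- rr_interval / length(fr)
  caudal <- sum(pmax(fr, 0)) * dt * ML_MIN_S_TO_UL
  cranial <- sum(pmin(fr, 0)) * dt * ML_MIN_S_TO_UL
  c(caudal = caudal, cranial = cranial, net = caudal + cranial)
}

#' Reynolds number of the aqueductal jet
#'
#' \eqn{Re = \rho V D / \mu} with the circular-equivalent diameter
#' \eqn{D = 2\sqrt{CSA/\pi}}. Values far below ~2000 justify the laminar
#' (parabolic-profile) assumption that places the maximal velocity at the
#' lumen center.
#'
#' @param vmax_peak peak velocity, cm/s.
#' @param csa cross-sectional area, mm^2.
#' @param density fluid density, kg/m^3 (CSF ~ water).
#' @param viscosity dynamic viscosity, mPa s.
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(vmax_peak, csa, density = 1000, viscosity = 1.0) {
  stopifnot_scalar(csa, "csa", positive = TRUE)
  d_m <- 2 * sqrt(csa / pi) / 1000          # mm -> m
  density * abs(vmax_peak) / 100 * d_m / (viscosity * 1e-3)
}

#' Assemble the twelve cycle summary measures
#'
#' @param tc a [compute_timecourses()] result.
#' @param rr_interval cardiac period, s (defaults to the one carried by
#'   \code{tc}).
#' @return a [flow_measures()] object.
#' @export
summarize_measures <- function(tc, rr_interval = NULL) {
  stopifnot(inherits(tc, "time_courses"))
  rr <- rr_interval %||% tc$rr_interval
  pk_vmean <- find_peaks(tc$vmean)
  pk_vmax <- find_peaks(tc$vmax)
  pk_fr <- find_peaks(tc$flow_rate)
  vol <- integrate_volumes(tc, rr)
  flow_measures(
    csa_avg = mean(tc$csa),
    vmean_sys_peak = pk_vmean$sys, vmean_dia_peak = pk_vmean$dia,
    vmean_avg = mean(tc$vmean),
    vmax_sys_peak = pk_vmax$sys, vmax_dia_peak = pk_vmax$dia,
    fr_sys_peak = pk_fr$sys, fr_dia_peak = pk_fr$dia,
    fr_avg = mean(tc$flow_rate),
    caudal_volume = vol[["caudal"]], cranial_volume = vol[["cranial"]],
    net_volume = vol[["net"]], rr_interval = rr)
}

#' Quantify a series end-to-end with one segmentation strategy
#'
#' Convenience pipeline: phase to velocity, NFA background correction,
#' reference-frame selection, segmentation, propagation, time courses and
#' summary measures.
#'
#' @param series a [cine_pc_series()].
#' @param strategy segmentation strategy name (see [segment_strategy()]).
#' @param nfa optional no-flow-area [roi_mask()]; proposed automatically
#'   (anterior box) when NULL.
#' @param seed_jitter operator click jitter \code{c(dy, dx)}, pixels.
#' @param alpha region-growing inclusion fraction.
#' @return list with \code{measures} ([flow_measures()]), \code{timecourses},
#'   \code{segmentation}, \code{vmaps}, \code{nfa}, \code{ref_frame}.
#' @export
quantify_series <- function(series, strategy = "REGION_GROW", nfa = NULL,
                            seed_jitter = c(0L, 0L), alpha = 0.2) {
  vm_raw <- phase_to_velocity(series)
  # rough lumen footprint: pixels whose peak-over-time |v| reaches half the
  # global maximum; bootstraps the NFA proposal and the frame-search window
  peak_map <- apply(abs(vm_raw$v), c(1, 2), max)
  rough <- peak_map >= 0.5 * max(peak_map)
  window <- mask_dilate(rough, 2L)
  if (is.null(nfa)) nfa <- propose_nfa(rough)
  vm <- background_correct(vm_raw, nfa)
  k <- select_reference_frame(vm, window)
  seg <- segment_strategy(vm, strategy, ref_frame = k, window = window,
                          seed_jitter = seed_jitter, alpha = alpha)
  masks <- propagate_mask(seg, vm)
  tc <- compute_timecourses(vm, masks)
  list(measures = summarize_measures(tc), timecourses = tc,
       segmentation = seg, vmaps = vm, nfa = nfa, ref_frame = k)
}
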