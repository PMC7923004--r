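# Phase-to-velocity conversion and static-tissue background correction.

#' Velocity map container
#'
#' @param v numeric array \code{[y, x, t]}, cm/s, caudal positive.
#' @param venc velocity-encoding limit, cm/s.
#' @param pixel_spacing mm.
#' @param rr_interval s.
#' @param corrected has the NFA background correction been applied?
#' @param nfa_reference per-frame offset actually subtracted, cm/s (or NULL).
#' @return object of class \code{velocity_maps}.
#' @export
velocity_maps <- function(v, venc, pixel_spacing, rr_interval,
                          corrected = FALSE, nfa_reference = NULL) {
  stopifnot(is.array(v), length(dim(v)) == 3L)
  if (!corrected && max(abs(v)) > venc + 1e-9)
    stop("|v| exceeds VENC in uncorrected maps", call. = FALSE)
  structure(list(v = v, venc = venc, pixel_spacing = pixel_spacing,
                 rr_interval = rr_interval, corrected = corrected,
                 nfa_reference = nfa_reference),
            class = "velocity_maps")
}

#' @export
print.velocity_maps <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("velocity maps: %d x %d x %d frames, VENC %g cm/s, %s\n",
              d[1], d[2], d[3], x$venc,
              if (x$corrected) "background-corrected" else "uncorrected"))
  invisible(x)
}

#' Convert phase to through-plane velocity
#'
#' Phase-contrast encoding is linear up to the VENC limit:
#' \eqn{v = VENC \cdot \phi / \pi} per pixel and frame, signed with caudal
#' flow positive.
#'
#' @param series a [cine_pc_series()].
#' @return uncorrected [velocity_maps()].
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "cine_pc_series"))
  velocity_maps(v = series$venc * series$phase / pi, venc = series$venc,
                pixel_spacing = series$pixel_spacing,
                rr_interval = series$rr_interval, corrected = FALSE)
}

#' Subtract the static-tissue (NFA) background offset
#'
#' For every frame, the mean velocity over the no-flow area is subtracted
#' from every pixel of that frame, removing smooth eddy-current-like phase
#' offsets. The per-frame offsets actually subtracted are stored in
#' \code{nfa_reference}. Per-frame (rather than cycle-pooled) subtraction is
#' used: it reduces to the pooled form when the offset is static.
#'
#' @param vmaps a [velocity_maps()].
#' @param nfa the no-flow-area [roi_mask()] (label \code{"NFA"}, nonempty).
#' @param aos optional aqueduct mask; an NFA overlapping it is rejected.
#' @return corrected [velocity_maps()].
#' @export
background_correct <- function(vmaps, nfa, aos = NULL) {
  stopifnot(inherits(vmaps, "velocity_maps"))
  nfa_px <- as_mask_matrix(nfa, label = "NFA")
  if (!any(nfa_px)) stop("NFA mask is empty", call. = FALSE)
  if (!is.null(aos)) {
    aos_px <- as_mask_matrix(aos)
    if (any(nfa_px & aos_px))
      stop("NFA mask overlaps the AoS mask", call. = FALSE)
  }
  T_ <- dim(vmaps$v)[3]
  offsets <- vapply(seq_len(T_),
                    function(k) mean(vmaps$v[, , k][nfa_px]), 0)
  v <- vmaps$v - rep(offsets, each = prod(dim(vmaps$v)[1:2]))
  velocity_maps(v = v, venc = vmaps$venc,
                pixel_spacing = vmaps$pixel_spacing,
                rr_interval = vmaps$rr_interval, corrected = TRUE,
                nfa_reference = offsets)
}

#' Flag pixels at phase-wrap (aliasing) risk
#'
#' Reports pixels whose phase magnitude is within \code{tol} of \eqn{\pi},
#' i.e. velocities at the VENC ceiling where wrapping corrupts the sign.
#' Detection only: no unwrapping is attempted.
#'
#' @param series a [cine_pc_series()].
#' @param tol phase tolerance, radians.
#' @return data.frame with columns \code{frame}, \code{y}, \code{x},
#'   \code{phase} (empty when no pixel is at risk).
#' @export
detect_aliasing <- function(series, tol = 0.02) {
  stopifnot(inherits(series, "cine_pc_series"))
  risk <- abs(series$phase) >= pi - tol
  idx <- which(risk, arr.ind = TRUE)
  data.frame(frame = as.integer(idx[, 3]), y = as.integer(idx[, 1]),
             x = as.integer(idx[, 2]), phase = series$phase[risk])
}

#' Propose an anterior static-tissue (NFA) box
#'
#' Places a square no-flow reference region a few pixels anterior to (above,
#' lower row indices than) the aqueduct ROI — the customary placement, whose
#' exact position is non-critical for smooth offset fields.
#'
#' @param aos the aqueduct [roi_mask()] (or logical matrix).
#' @param offset_px gap between the AoS centroid and the box center, pixels.
#' @param size box side, pixels.
#' @return an [roi_mask()] labeled \code{"NFA"}.
#' @export
propose_nfa <- function(aos, offset_px = 8L, size = 5L) {
  px <- as_mask_matrix(aos)
  if (!any(px)) stop("AoS mask is empty", call. = FALSE)
  idx <- which(px, arr.ind = TRUE)
  cy <- round(mean(idx[, 1])); cx <- round(mean(idx[, 2]))
  half <- (size - 1L) %/% 2L
  y0 <- max(1L, cy - offset_px - half)
  rows <- y0:(y0 + size - 1L)
  cols <- max(1L, cx - half):(min(ncol(px), cx + half))
  out <- matrix(FALSE, nrow(px), ncol(px))
  out[rows[rows <= nrow(px)], cols] <- TRUE
  out <- out & !px
  roi_mask(out, label = "NFA")
}
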