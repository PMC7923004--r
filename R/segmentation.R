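# Aqueduct segmentation: three functional emulations of the interaction
# styles of commercial PC-MRI packages — border-seeded local thresholding,
# manual-contour refinement (Otsu), and seeded region growing — all operating
# on background-corrected |v| of a single reference frame, with 4-connectivity
# throughout (prevents diagonal leakage through the thin partial-volume rind).

#' Segmentation seed point
#'
#' @param position \code{c(y, x)} pixel indices (1-based).
#' @param kind \code{"BORDER"} (a clicked lumen-border pixel) or
#'   \code{"INTERIOR"} (a clicked pixel inside the lumen).
#' @param frame reference frame index.
#' @return object of class \code{seed_point}.
#' @export
seed_point <- function(position, kind = c("INTERIOR", "BORDER"),
                       frame = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 2L, all(position >= 1))
  structure(list(position = as.integer(position), kind = kind,
                 frame = frame), class = "seed_point")
}

# 4-connected component of `mask` containing (y, x), by vectorized frontier
# expansion (images here are small, <= ~256^2).
connected_component <- function(mask, seed) {
  ny <- nrow(mask); nx <- ncol(mask)
  if (!mask[seed[1], seed[2]]) return(matrix(FALSE, ny, nx))
  comp <- matrix(FALSE, ny, nx)
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-ny, ]
    grown[-ny, ] <- grown[-ny, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -nx]
    grown[, -nx] <- grown[, -nx] | comp[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# all 4-connected components above threshold; returns label matrix (0 = bg)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  remaining <- mask
  while (any(remaining)) {
    seed <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- connected_component(remaining, seed)
    cur <- cur + 1L
    lab[comp] <- cur
    remaining <- remaining & !comp
  }
  lab
}

is_connected4 <- function(mask) {
  if (!any(mask)) return(FALSE)
  seed <- which(mask, arr.ind = TRUE)[1, ]
  sum(connected_component(mask, seed)) == sum(mask)
}

#' Morphological dilation / erosion of a binary mask
#'
#' Diamond (4-connected) structuring element applied \code{r} times;
#' used for the contour-refinement search region and for ROI-size
#' sensitivity experiments.
#'
#' @param mask [roi_mask()] or logical matrix.
#' @param r radius in pixels.
#' @return logical matrix.
#' @export
mask_dilate <- function(mask, r = 1L) {
  px <- as_mask_matrix(mask)
  out <- EBImage::dilate(px * 1, EBImage::makeBrush(2L * as.integer(r) + 1L,
                                                    shape = "diamond"))
  matrix(out > 0, nrow(px), ncol(px))
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, r = 1L) {
  px <- as_mask_matrix(mask)
  out <- EBImage::erode(px * 1, EBImage::makeBrush(2L * as.integer(r) + 1L,
                                                   shape = "diamond"))
  matrix(out > 0, nrow(px), ncol(px))
}

seg_result <- function(mask_px, strategy, reference_frame, parameters) {
  mask <- roi_mask(mask_px, label = "AOS")
  structure(list(mask = mask, strategy = strategy,
                 reference_frame = reference_frame,
                 parameters = parameters),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation [%s] @ frame %d: %d px\n", x$strategy,
              x$reference_frame, sum(x$mask$pixels)))
  invisible(x)
}

#' Select the reference frame of peak flow
#'
#' Emulates the visual selection of the frame with the highest CSF contrast:
#' returns the frame maximizing the 99th percentile of |v| within a search
#' window, with deterministic tie-break to the lowest frame index.
#'
#' @param vmaps a [velocity_maps()].
#' @param window logical matrix / [roi_mask()] restricting the search, or
#'   NULL for the whole image.
#' @return integer frame index.
#' @export
select_reference_frame <- function(vmaps, window = NULL) {
  stopifnot(inherits(vmaps, "velocity_maps"))
  win <- if (is.null(window)) matrix(TRUE, dim(vmaps$v)[1], dim(vmaps$v)[2])
         else as_mask_matrix(window)
  if (!any(win)) stop("search window is empty", call. = FALSE)
  score <- vapply(seq_len(dim(vmaps$v)[3]), function(k)
    stats::quantile(abs(vmaps$v[, , k][win]), 0.99, names = FALSE), 0)
  which.max(score)   # which.max takes the first (lowest) index on ties
}

check_corrected <- function(vmaps) {
  if (!vmaps$corrected)
    stop("velocity maps must be background-corrected before segmentation/",
         "quantification", call. = FALSE)
}

resolve_frame <- function(vmaps, seed, ref_frame) {
  ref_frame %||% seed$frame %||% select_reference_frame(vmaps)
}

#' Border-seeded local thresholding (Jim-style interaction)
#'
#' The operator identifies one pixel of the lumen border; the threshold is
#' \eqn{\tau = |v|} at that pixel on the reference frame, and the mask is the
#' 4-connected component of \eqn{\{|v| \ge \tau\}} containing the highest-|v|
#' pixel within 3 px of the seed.
#'
#' @param vmaps background-corrected [velocity_maps()].
#' @param seed a \code{BORDER} [seed_point()] (or \code{c(y, x)}).
#' @param ref_frame reference frame; defaults to the seed's frame or
#'   [select_reference_frame()].
#' @param size_cap maximum admissible component size, pixels; a larger
#'   component means the threshold is degenerate (seed in parenchyma).
#' @return a \code{segmentation_result}.
#' @export
segment_border_threshold <- function(vmaps, seed, ref_frame = NULL,
                                     size_cap = 200L) {
  check_corrected(vmaps)
  if (!inherits(seed, "seed_point")) seed <- seed_point(seed, "BORDER")
  k <- resolve_frame(vmaps, seed, ref_frame)
  av <- abs(vmaps$v[, , k])
  pos <- seed$position
  tau <- av[pos[1], pos[2]]
  # local anchor: highest-|v| pixel within a 3-px radius of the seed
  ny <- nrow(av); nx <- ncol(av)
  ys <- max(1, pos[1] - 3):min(ny, pos[1] + 3)
  xs <- max(1, pos[2] - 3):min(nx, pos[2] + 3)
  nb <- as.matrix(expand.grid(y = ys, x = xs))
  nb <- nb[(nb[, 1] - pos[1])^2 + (nb[, 2] - pos[2])^2 <= 9, , drop = FALSE]
  anchor <- nb[which.max(av[nb]), ]
  comp <- connected_component(av >= tau & av > 0, anchor)
  n_px <- sum(comp)
  if (n_px == 0L || n_px > size_cap)
    stop(sprintf("threshold degenerate: component of %d px at tau = %.3g",
                 n_px, tau), call. = FALSE)
  seg_result(comp, "BORDER_THRESHOLD", k,
             list(tau = tau, seed = pos, size_cap = size_cap))
}

#' Seeded region growing (SPIN-style interaction)
#'
#' Grows 4-connectedly from an interior seed on the reference frame,
#' including pixels with \eqn{|v| \ge \alpha |v(seed)|}.
#'
#' @inheritParams segment_border_threshold
#' @param seed an \code{INTERIOR} [seed_point()] (or \code{c(y, x)}); must
#'   lie on a pixel with nonzero velocity.
#' @param alpha inclusion fraction of the seed velocity, in [0, 1];
#'   \code{alpha = 0} grows to the full footprint of nonzero velocity.
#' @return a \code{segmentation_result}.
#' @export
segment_region_grow <- function(vmaps, seed, alpha = 0.2, ref_frame = NULL) {
  check_corrected(vmaps)
  if (!inherits(seed, "seed_point")) seed <- seed_point(seed, "INTERIOR")
  k <- resolve_frame(vmaps, seed, ref_frame)
  av <- abs(vmaps$v[, , k])
  pos <- seed$position
  sv <- av[pos[1], pos[2]]
  if (sv == 0)
    stop("region-growing seed lies on a zero-velocity pixel", call. = FALSE)
  comp <- connected_component(av >= alpha * sv & av > 0, pos)
  seg_result(comp, "REGION_GROW", k,
             list(alpha = alpha, seed = pos, seed_velocity = sv))
}

#' Refine a manually drawn contour by Otsu thresholding (Segment-style)
#'
#' The manual initial mask, dilated by 2 px, defines a local search region;
#' an Otsu threshold on |v| (reference frame) within that region separates
#' lumen from background, and the largest 4-connected above-threshold
#' component is returned. Because a laminar profile spreads the within-lumen
#' velocity histogram into a ramp (so a linear-domain split lands well inside
#' the lumen), Otsu is computed on \code{log(|v| + 0.03 max)} — the standard
#' log-domain form for strongly skewed intensity histograms — which stably
#' separates the static background from moving CSF. If Otsu degenerates
#' (uniform |v|, or no pixel above threshold) the initial mask is returned
#' with a warning.
#'
#' @inheritParams segment_border_threshold
#' @param initial the manually drawn [roi_mask()] (or logical matrix),
#'   nonempty and overlapping the lumen.
#' @return a \code{segmentation_result}.
#' @export
refine_contour <- function(vmaps, initial, ref_frame = NULL) {
  check_corrected(vmaps)
  init <- as_mask_matrix(initial)
  if (!any(init)) stop("initial mask is empty", call. = FALSE)
  k <- ref_frame %||% select_reference_frame(vmaps)
  av <- abs(vmaps$v[, , k])
  if (!any(av[init] > 0))
    stop("initial mask is disjoint from any moving pixel", call. = FALSE)
  region <- mask_dilate(init, 2L)
  vals <- av[region]
  fallback <- function(msg) {
    warning(paste0("Otsu refinement degenerate (", msg,
                   "); returning the initial contour"), call. = FALSE)
    seg_result(init, "CONTOUR_REFINE", k, list(otsu = NA_real_))
  }
  if (diff(range(vals)) < 1e-12) return(fallback("uniform |v|"))
  floor_ <- 0.03 * max(vals)
  lv <- log(vals + floor_)
  th <- exp(EBImage::otsu(matrix(lv), range = range(lv), levels = 256L)) -
    floor_
  above <- region & av > th
  if (!any(above)) return(fallback("no pixel above threshold"))
  lab <- label_components(above)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  seg_result(comp, "CONTOUR_REFINE", k, list(otsu = th))
}

#' Copy a segmentation to every time frame
#'
#' The ROI drawn on the reference frame is used unchanged at all frames (no
#' per-frame re-fit); an optional edit callback stands in for manual
#' per-frame adjustment.
#'
#' @param result a \code{segmentation_result} or [roi_mask()].
#' @param vmaps a [velocity_maps()] (supplies the frame count), or an
#'   integer frame count.
#' @param adjust optional \code{function(mask_px, frame)} returning an edited
#'   logical matrix for that frame.
#' @return logical array \code{[y, x, t]}.
#' @export
propagate_mask <- function(result, vmaps, adjust = NULL) {
  px <- if (inherits(result, "segmentation_result")) result$mask$pixels
        else as_mask_matrix(result)
  T_ <- if (is.numeric(vmaps)) as.integer(vmaps) else dim(vmaps$v)[3]
  out <- array(px, dim = c(dim(px), T_))
  if (!is.null(adjust))
    for (k in seq_len(T_)) out[, , k] <- adjust(out[, , k], k)
  out
}

#' Propose interior and border seed clicks automatically
#'
#' Stands in for the operator's clicks in batch runs: the interior seed is
#' the highest-|v| pixel on the reference frame; the border seed is the pixel
#' near the lumen whose |v| is closest to \code{border_level} of the maximum
#' (the visually apparent lumen edge, where signal fades towards background).
#'
#' @param vmaps background-corrected [velocity_maps()].
#' @param ref_frame reference frame (defaults to [select_reference_frame()]).
#' @param window optional search window (logical matrix or [roi_mask()]).
#' @param border_level fraction of the peak |v| defining the visible border.
#' @return list with \code{interior} and \code{border} [seed_point()]s.
#' @export
propose_seeds <- function(vmaps, ref_frame = NULL, window = NULL,
                          border_level = 0.15) {
  check_corrected(vmaps)
  k <- ref_frame %||% select_reference_frame(vmaps, window)
  av <- abs(vmaps$v[, , k])
  if (!is.null(window)) av[!as_mask_matrix(window)] <- 0
  pos <- which(av == max(av), arr.ind = TRUE)[1, ]
  border <- border_click(av, pos, border_level)
  list(interior = seed_point(c(pos[1], pos[2]), "INTERIOR", frame = k),
       border = seed_point(border, "BORDER", frame = k))
}

# Emulated operator border click: among pixels below half-max within 6 px of
# the lumen center `pos`, pick the one with |v| closest to `level` of the
# peak, or (when a `target` position is given, e.g. a jittered click) the
# valid border candidate nearest to that target.
border_click <- function(av, pos, border_level, target = NULL) {
  level <- border_level * av[pos[1], pos[2]]
  ys <- max(1, pos[1] - 6):min(nrow(av), pos[1] + 6)
  xs <- max(1, pos[2] - 6):min(ncol(av), pos[2] + 6)
  cand <- as.matrix(expand.grid(y = ys, x = xs))
  # plausible clicks: visibly below the lumen core but not pure background
  keep <- av[cand] < 0.5 * av[pos[1], pos[2]] &
    av[cand] >= 0.05 * av[pos[1], pos[2]]
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(c(pos[1], pos[2]))
  if (is.null(target)) {
    unname(cand[which.min(abs(av[cand] - level)), ])
  } else {
    d2 <- (cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2
    best <- d2 == min(d2)
    sub <- cand[best, , drop = FALSE]
    unname(sub[which.min(abs(av[sub] - level)), ])
  }
}

#' Run one of the three segmentation strategies by name
#'
#' Convenience dispatcher used by the cohort simulator and the analysis
#' scripts: proposes seeds automatically (optionally jittered, emulating
#' operator click variability), builds the strategy-specific initialization
#' and returns its result.
#'
#' For \code{"CONTOUR_REFINE"} the manual initial contour is emulated as a
#' generous hand drawing — the 30%-of-peak region around the interior seed
#' dilated by 2 px — which the refinement then tightens (operators typically
#' overdraw the visible lumen and let the tool shed the rind).
#'
#' @param vmaps background-corrected [velocity_maps()].
#' @param strategy \code{"BORDER_THRESHOLD"}, \code{"CONTOUR_REFINE"} or
#'   \code{"REGION_GROW"}.
#' @param ref_frame reference frame (defaults to [select_reference_frame()]).
#' @param seed_jitter integer vector \code{c(dy, dx)} added to the proposed
#'   seed click, pixels.
#' @param alpha region-growing inclusion fraction.
#' @param window optional search window.
#' @return a \code{segmentation_result}.
#' @export
segment_strategy <- function(vmaps,
                             strategy = c("BORDER_THRESHOLD",
                                          "CONTOUR_REFINE", "REGION_GROW"),
                             ref_frame = NULL, seed_jitter = c(0L, 0L),
                             alpha = 0.2, window = NULL) {
  strategy <- match.arg(strategy)
  k <- ref_frame %||% select_reference_frame(vmaps, window)
  seeds <- propose_seeds(vmaps, ref_frame = k, window = window)
  jit <- function(sp) {
    p <- sp$position + as.integer(seed_jitter)
    p[1] <- min(max(p[1], 1L), dim(vmaps$v)[1])
    p[2] <- min(max(p[2], 1L), dim(vmaps$v)[2])
    seed_point(p, sp$kind, frame = k)
  }
  switch(strategy,
    BORDER_THRESHOLD = {
      av <- abs(vmaps$v[, , k])
      ip <- seeds$interior$position
      bp <- border_click(av, ip, 0.15,
                         target = jit(seeds$border)$position)
      segment_border_threshold(vmaps, seed_point(bp, "BORDER", frame = k),
                               ref_frame = k)
    },
    REGION_GROW = segment_region_grow(vmaps, jit(seeds$interior),
                                      alpha = alpha, ref_frame = k),
    CONTOUR_REFINE = {
      av <- abs(vmaps$v[, , k])
      ip <- jit(seeds$interior)$position
      core <- connected_component(av >= 0.3 * av[ip[1], ip[2]] & av > 0, ip)
      refine_contour(vmaps, mask_dilate(core, 2L), ref_frame = k)
    })
}
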