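# On-disk formats: 4D NIfTI pairs (magnitude/phase, X x Y x 1 x T) with a JSON
# sidecar for acquisition metadata; 2D byte NIfTI masks with a JSON label
# sidecar; plain CSV measure tables. Internal arrays are [y, x, t]; the
# (x, y, 1, t) NIfTI layout is handled here only.

SIDECAR_KEYS <- c("venc_cm_s", "pixel_spacing_mm", "slice_thickness_mm",
                  "rr_interval_s", "n_frames", "sign_convention")

series_paths <- function(path) {
  list(mag = paste0(path, "_mag.nii.gz"),
       phs = paste0(path, "_phase.nii.gz"),
       json = paste0(path, ".json"))
}

to_nifti4d <- function(arr_yxt, pixel_spacing, slice_thickness, tr) {
  a <- aperm(arr_yxt, c(2, 1, 3))           # x, y, t
  dim(a) <- c(dim(a)[1], dim(a)[2], 1L, dim(a)[3])
  img <- RNifti::asNifti(a)
  RNifti::`pixdim<-`(img, c(pixel_spacing, pixel_spacing, slice_thickness, tr))
}

from_nifti4d <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 4L) dim(a) <- dim(a)[c(1, 2, 4)]
  aperm(a, c(2, 1, 3))                       # back to y, x, t
}

#' Write / read a cine PC series as NIfTI pair + JSON sidecar
#'
#' \code{write_series} produces \code{<path>_mag.nii.gz},
#' \code{<path>_phase.nii.gz} (shape X x Y x 1 x T) and \code{<path>.json}
#' holding VENC, pixel spacing, slice thickness, RR interval, frame count,
#' sign convention and provenance seed. \code{read_series} validates the
#' sidecar, checks shape agreement and wraps phase into \eqn{[-\pi, \pi)}.
#'
#' @param series a [cine_pc_series()].
#' @param path file prefix (no extension).
#' @return \code{write_series}: the path prefix, invisibly.
#'   \code{read_series}: a \code{cine_pc_series}.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "cine_pc_series"))
  p <- series_paths(path)
  tr <- series$rr_interval / series$n_frames
  RNifti::writeNifti(to_nifti4d(series$magnitude, series$pixel_spacing,
                                series$slice_thickness, tr), p$mag)
  RNifti::writeNifti(to_nifti4d(series$phase, series$pixel_spacing,
                                series$slice_thickness, tr), p$phs)
  meta <- list(venc_cm_s = series$venc,
               pixel_spacing_mm = series$pixel_spacing,
               slice_thickness_mm = series$slice_thickness,
               rr_interval_s = series$rr_interval,
               n_frames = series$n_frames,
               sign_convention = series$sign_convention,
               seed = series$seed)
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  p <- series_paths(path)
  if (!file.exists(p$json))
    stop(sprintf("missing sidecar: %s", p$json), call. = FALSE)
  meta <- jsonlite::read_json(p$json)
  missing <- setdiff(SIDECAR_KEYS, names(meta))
  if (length(missing))
    stop(sprintf("sidecar %s lacks required key(s): %s", p$json,
                 paste(missing, collapse = ", ")), call. = FALSE)
  mag <- from_nifti4d(RNifti::readNifti(p$mag))
  phs <- from_nifti4d(RNifti::readNifti(p$phs))
  if (!identical(dim(mag), dim(phs)))
    stop("magnitude and phase stacks have different shapes", call. = FALSE)
  cine_pc_series(magnitude = mag, phase = wrap_phase(phs),
                 venc = meta$venc_cm_s,
                 pixel_spacing = meta$pixel_spacing_mm,
                 slice_thickness = meta$slice_thickness_mm,
                 rr_interval = meta$rr_interval_s,
                 sign_convention = meta$sign_convention,
                 seed = meta$seed %||% NULL)
}

#' Write / read an ROI mask as 2D byte NIfTI + JSON label sidecar
#'
#' @param mask an [roi_mask()].
#' @param path file prefix (no extension); writes \code{<path>.nii.gz} and
#'   \code{<path>.json}.
#' @return \code{write_mask}: path prefix, invisibly; \code{read_mask}: an
#'   \code{roi_mask}. Files holding values other than 0/1 are rejected.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- t(mask$pixels) * 1L                  # x, y
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  jsonlite::write_json(list(label = mask$label), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(paste0(path, ".nii.gz")))
  if (length(dim(arr)) > 2L) dim(arr) <- dim(arr)[1:2]
  if (!all(arr %in% c(0, 1)))
    stop("mask file contains non-binary values", call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  roi_mask(t(arr) > 0, label = meta$label)
}

#' Write / read a flow-measures table as CSV
#'
#' One row per (subject, software strategy, repeat); id columns first, then
#' the twelve measures, written at full double precision.
#'
#' @param table data.frame with id columns and the twelve measure columns.
#' @param path CSV file path.
#' @return \code{write_measures}: path, invisibly; \code{read_measures}: the
#'   data.frame.
#' @export
write_measures <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(MEASURE_NAMES, names(table))
  if (length(missing))
    stop(sprintf("measure table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ids <- setdiff(names(table), MEASURE_NAMES)
  tab <- table[, c(ids, MEASURE_NAMES)]
  for (m in MEASURE_NAMES) tab[[m]] <- format(tab[[m]], digits = 17,
                                              scientific = TRUE, trim = TRUE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (m in intersect(MEASURE_NAMES, names(tab)))
    tab[[m]] <- as.numeric(tab[[m]])
  tab
}
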