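# Segmentation-overlap (Dice) and repeatability (ICC) statistics with the
# customary strength / quality classification bands.

DSC_LEVELS <- c("slight", "fair", "moderate", "substantial", "almost_perfect")
ICC_LEVELS <- c("poor", "insufficient", "acceptable", "good", "excellent")

#' Classify an agreement value into its standard band
#'
#' Dice bands: almost perfect (0.8, 1], substantial (0.6, 0.8], moderate
#' (0.4, 0.6], fair (0.2, 0.4], slight [0, 0.2]. ICC grades: excellent
#' > 0.90, good (0.70, 0.90], acceptable (0.50, 0.70], insufficient
#' (0.30, 0.50], poor <= 0.30 (negative ICCs map to poor). Bands are total on
#' [0, 1] (DSC) and [-1, 1] (ICC); edges follow the inclusive upper bounds of
#' the published band lists.
#'
#' @param value numeric value(s).
#' @param scheme \code{"DSC"} or \code{"ICC"}.
#' @return factor of band labels.
#' @export
classify <- function(value, scheme = c("DSC", "ICC")) {
  scheme <- match.arg(scheme)
  if (scheme == "DSC") {
    if (any(value < 0 | value > 1)) stop("DSC must lie in [0, 1]",
                                         call. = FALSE)
    cut(value, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
        labels = DSC_LEVELS)
  } else {
    if (any(value > 1)) stop("ICC cannot exceed 1", call. = FALSE)
    cut(value, breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf),
        labels = ICC_LEVELS)
  }
}

#' Dice similarity coefficient of two masks
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)}. Two empty masks are defined as
#' identical (DSC 1).
#'
#' @param a,b [roi_mask()]s or logical matrices on the same grid.
#' @return object of class \code{dice_result}: \code{dsc} and its
#'   \code{strength} band.
#' @export
dice <- function(a, b) {
  pa <- as_mask_matrix(a); pb <- as_mask_matrix(b)
  if (!identical(dim(pa), dim(pb)))
    stop("masks are on different grids", call. = FALSE)
  na <- sum(pa); nb <- sum(pb)
  dsc <- if (na + nb == 0L) 1 else 2 * sum(pa & pb) / (na + nb)
  structure(list(dsc = dsc, strength = as.character(classify(dsc, "DSC"))),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("DSC = %.4f (%s)\n", x$dsc, x$strength))
  invisible(x)
}

#' Intraclass correlation for repeated measurements
#'
#' Single-measure two-way ICC from the two-way ANOVA decomposition of an
#' n-subjects x k-repeats table. The default absolute-agreement form,
#' ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)), targets
#' repeatability of one operator's repeated measurements; the consistency
#' form ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE) is available as a switch.
#' The p-value tests ICC > 0 via the subject-effect F test
#' (F = MSR/MSE on n-1 and (n-1)(k-1) degrees of freedom).
#'
#' @param measurements numeric matrix (or data.frame), subjects in rows,
#'   repeats in columns; n >= 3, k >= 2, no missing cells.
#' @param type \code{"agreement"} (ICC(A,1)) or \code{"consistency"}
#'   (ICC(C,1)).
#' @return object of class \code{icc_result}: \code{icc}, \code{p_value},
#'   \code{grade}, \code{type}, mean squares.
#' @export
icc_repeatability <- function(measurements, type = c("agreement",
                                                     "consistency")) {
  type <- match.arg(type)
  x <- as.matrix(measurements)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L)
    stop("need at least 3 subjects and 2 repeats", call. = FALSE)
  if (anyNA(x)) stop("missing cells are not supported", call. = FALSE)
  g <- mean(x)
  sst <- sum((x - g)^2)
  if (sst < 1e-24) stop("degenerate: zero total variance", call. = FALSE)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- switch(type,
    agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    consistency = (msr - mse) / (msr + (k - 1) * mse))
  f <- if (mse <= 0) Inf else msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, p_value = p,
                 grade = as.character(classify(icc, "ICC")), type = type,
                 ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.4f (%s), p = %.3g [n = %d, k = %d]\n",
              if (x$type == "agreement") "A" else "C", x$icc, x$grade,
              x$p_value, x$n, x$k))
  invisible(x)
}
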