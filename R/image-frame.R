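#' Validate an RGB image frame
#'
#' Frames are plain numeric arrays of dimension `height x width x 3` with
#' channel values on the unit interval, the layout returned by
#' [png::readPNG()]. All pipeline stages consume and produce this
#' representation; working in floating point end-to-end avoids accumulating
#' quantisation error through the multi-stage pipeline.
#'
#' @param frame numeric array, `V x U x 3`, values in `[0, 1]`.
#' @return the validated frame, invisibly unchanged.
#' @export
validate_frame <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frame must be a height x width x 3 numeric array", call. = FALSE)
  if (dim(frame)[1] < 1L || dim(frame)[2] < 1L)
    stop("frame must have at least one row and one column", call. = FALSE)
  if (!is.numeric(frame) || anyNA(frame) || any(!is.finite(frame)))
    stop("frame contains non-finite pixel values", call. = FALSE)
  if (min(frame) < 0 || max(frame) > 1)
    stop("frame values must lie in [0, 1]", call. = FALSE)
  invisible(frame)
}

#' Convert between 8-bit integer and unit-interval pixel values
#'
#' `frame_from_8bit()` divides by 255; `frame_to_8bit()` rounds back. The
#' round trip is the identity for all 256 levels.
#'
#' @param x integer-valued array or matrix in `0..255` (`frame_from_8bit`)
#'   or unit-interval values (`frame_to_8bit`).
#' @return array of the same shape.
#' @export
frame_from_8bit <- function(x) {
  if (min(x) < 0 || max(x) > 255) stop("8-bit values must lie in 0..255", call. = FALSE)
  x / 255
}

#' @rdname frame_from_8bit
#' @export
frame_to_8bit <- function(x) {
  as.integer(round(pmin(pmax(x, 0), 1) * 255))
}

#' Quantise a frame to 8-bit precision
#'
#' Rounds unit-interval values to the nearest of the 256 representable
#' 8-bit levels, mimicking real acquisition before a frame enters the
#' pipeline.
#'
#' @param frame numeric array or matrix in `[0, 1]`.
#' @return same shape, values quantised to `k/255`.
#' @export
quantize_frame <- function(frame) {
  q <- round(pmin(pmax(frame, 0), 1) * 255) / 255
  if (!is.null(dim(frame))) dim(q) <- dim(frame)
  q
}

#' Luma coefficients
#'
#' Weights of the RGB-to-luminance combination
#' `H = a*R + b*G + c*B`. The defaults are the BT.601 weights
#' `a = 0.299`, `b = 0.587`, `c = 0.114`, which sum to one so that
#' achromatic pixels keep their gray level.
#'
#' @param a,b,c red, green and blue weights.
#' @return named list of class `luma_coefficients`.
#' @export
luma_coefficients <- function(a = 0.299, b = 0.587, c = 0.114) {
  if (!all(is.finite(c(a, b, c))) || any(c(a, b, c) < 0))
    stop("luma coefficients must be finite and non-negative", call. = FALSE)
  if (abs(a + b + c - 1) > 1e-9)
    stop("luma coefficients must sum to 1", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "luma_coefficients")
}

#' Pixelwise luminance of an RGB frame
#'
#' `H(u,v) = a*R + b*G + c*B` with the BT.601 weights by default. This is
#' the raw (full-range) luminance used by the contrast-enhancement branch
#' and the smoke classifier, distinct from the studio-range Y plane of
#' [rgb_to_ycbcr()].
#'
#' @inheritParams validate_frame
#' @param coeffs a [luma_coefficients()] object.
#' @return numeric matrix `V x U` in `[0, 1]`.
#' @export
luminance <- function(frame, coeffs = luma_coefficients()) {
  validate_frame(frame)
  coeffs$a * frame[, , 1] + coeffs$b * frame[, , 2] + coeffs$c * frame[, , 3]
}

#' Mean luminance of a frame
#'
#' The scalar `lambda = sum(H) / (U*V)` that the enhancement branch
#' subtracts from every channel.
#'
#' @inheritParams luminance
#' @return scalar in `[0, 1]`.
#' @export
mean_luminance <- function(frame, coeffs = luma_coefficients()) {
  mean(luminance(frame, coeffs))
}
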