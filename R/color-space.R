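# RGB <-> YCbCr conversion. The studio-range ITU-R BT.601 matrices are the
# default: the weight intervals (16-128, 128-235) and the stretch bounds
# P = 15, Q = 236 used downstream are 8-bit studio-range luma values, so this
# convention makes those constants directly meaningful on the Y plane.

bt601 <- list(
  kr = 0.299, kg = 0.587, kb = 0.114,
  # Cb/Cr projection rows of the analysis matrix (full range, offset 0.5)
  cb = c(-0.168735891647856, -0.331264108352144, 0.5),
  cr = c(0.5, -0.418687589158345, -0.081312410841655)
)

#' Convert an RGB frame to YCbCr planes
#'
#' Uses the ITU-R BT.601 primaries. With the `"studio"` convention the luma
#' plane is scaled into `[16/255, 235/255]` and chroma into
#' `[16/255, 240/255]` around the midpoint `128/255`; `"full"` keeps the
#' unit range. The Y plane of the studio transform is an affine map of the
#' raw luminance returned by [luminance()].
#'
#' @inheritParams validate_frame
#' @param range `"studio"` (default) or `"full"` quantisation convention.
#' @return a list of class `ycbcr_frame` with matrices `Y`, `Cb`, `Cr` and
#'   the `range` convention.
#' @export
rgb_to_ycbcr <- function(frame, range = c("studio", "full")) {
  validate_frame(frame)
  range <- match.arg(range)
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  y  <- bt601$kr * r + bt601$kg * g + bt601$kb * b
  cb <- bt601$cb[1] * r + bt601$cb[2] * g + bt601$cb[3] * b
  cr <- bt601$cr[1] * r + bt601$cr[2] * g + bt601$cr[3] * b
  if (range == "studio") {
    y  <- (16 + 219 * y) / 255
    cb <- (128 + 224 * cb) / 255
    cr <- (128 + 224 * cr) / 255
  } else {
    cb <- cb + 0.5
    cr <- cr + 0.5
  }
  structure(list(Y = y, Cb = cb, Cr = cr, range = range),
            class = "ycbcr_frame")
}

#' Convert YCbCr planes back to an RGB frame
#'
#' Inverse of [rgb_to_ycbcr()]; out-of-gamut values produced by plane
#' manipulation (blending, stretching) are clipped to `[0, 1]`.
#'
#' @param ycc a `ycbcr_frame` list with `Y`, `Cb`, `Cr` and `range`.
#' @return an RGB frame array.
#' @export
ycbcr_to_rgb <- function(ycc) {
  if (!is.list(ycc) || !all(c("Y", "Cb", "Cr", "range") %in% names(ycc)))
    stop("ycc must be a ycbcr_frame with Y, Cb, Cr and range", call. = FALSE)
  if (!ycc$range %in% c("studio", "full"))
    stop("unknown range convention: ", ycc$range, call. = FALSE)
  if (ycc$range == "studio") {
    y  <- (255 * ycc$Y - 16) / 219
    cb <- (255 * ycc$Cb - 128) / 224
    cr <- (255 * ycc$Cr - 128) / 224
  } else {
    y  <- ycc$Y
    cb <- ycc$Cb - 0.5
    cr <- ycc$Cr - 0.5
  }
  # invert [kr kg kb; cb; cr] analytically (standard BT.601 synthesis)
  r <- y + 1.402 * cr
  b <- y + 1.772 * cb
  g <- (y - bt601$kr * r - bt601$kb * b) / bt601$kg
  out <- array(0, dim = c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  clip01(out)
}
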