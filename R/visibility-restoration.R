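# Restoration branch: atmospheric light and veil estimation, inversion of
# the haze model, and joint bilateral denoising of the recovered radiance.

#' Veil-estimation parameters
#'
#' @param window median-filter half-size in pixels (the filter window is
#'   `(2*window+1)^2`).
#' @param p_factor veil strength in `(0, 1]`; scales the estimated veil
#'   below the pixelwise min-channel bound.
#' @param white_balance_A if `TRUE` (default) the atmospheric light is fixed
#'   at 1.0, the white-balanced-frame assumption of fast visibility
#'   restoration; `FALSE` enables the bright-pixel estimator.
#' @return list of class `veil_params`.
#' @export
veil_params <- function(window = 7L, p_factor = 0.95, white_balance_A = TRUE) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (p_factor <= 0 || p_factor > 1) stop("p_factor must be in (0, 1]", call. = FALSE)
  structure(list(window = as.integer(window), p_factor = p_factor,
                 white_balance_A = isTRUE(white_balance_A)),
            class = "veil_params")
}

#' Estimate the atmospheric light
#'
#' With `white_balance_A` set the frame is assumed white-balanced and
#' `A = 1`. Otherwise `A` is the mean of the top 0.1% brightest values of
#' the darkest-channel map (the pixelwise minimum over R, G, B), which in
#' dense smoke converges to the ambient light level.
#'
#' @inheritParams validate_frame
#' @param params a [veil_params()] object.
#' @return scalar atmospheric light in `(0, 1]`.
#' @export
estimate_atmospheric_light <- function(frame, params = veil_params()) {
  validate_frame(frame)
  if (params$white_balance_A) return(1.0)
  m <- pmin(frame[, , 1], frame[, , 2], frame[, , 3])
  k <- max(1L, ceiling(0.001 * length(m)))
  mean(sort(as.vector(m), decreasing = TRUE)[seq_len(k)])
}

#' Estimate the atmospheric veil
#'
#' Median-of-median construction on the darkest-channel map `M`:
#' `W = median_window(M)`, `B = W - median_window(|M - W|)`,
#' `X = clip(min(p_factor * B, M), 0, A)`. The local deviation term pulls
#' the veil down near strong structure so object detail is not mistaken for
#' smoke; the clamp to `M` guarantees the veil never exceeds the darkest
#' channel, and the result never exceeds `A`.
#'
#' @inheritParams estimate_atmospheric_light
#' @param A scalar atmospheric light.
#' @return veil matrix satisfying `0 <= X <= min(M, A)`.
#' @export
estimate_veil <- function(frame, A = 1.0, params = veil_params()) {
  validate_frame(frame)
  if (2L * params$window + 1L > min(dim(frame)[1:2]))
    stop("median window larger than the frame", call. = FALSE)
  m <- pmin(frame[, , 1], frame[, , 2], frame[, , 3])
  w <- cpp_median_window(m, params$window)
  b <- w - cpp_median_window(abs(m - w), params$window)
  x <- pmin(params$p_factor * b, m)
  x[x < 0] <- 0
  pmin(x, A)
}

#' Invert the haze model
#'
#' Scene-radiance recovery `F = A * (I - X) / (A - X)` per channel with the
#' shared veil. Where the denominator falls below `eps` it is clamped (with
#' a warning) rather than raising an error, since fully opaque pixels carry
#' no recoverable radiance; output is clipped to `[0, 1]`.
#'
#' @inheritParams estimate_veil
#' @param X veil matrix from [estimate_veil()] or
#'   [veil_from_transmission()].
#' @param eps denominator floor.
#' @return recovered RGB frame.
#' @export
recover_radiance <- function(frame, X, A = 1.0, eps = 1e-3) {
  validate_frame(frame)
  if (!identical(dim(X), dim(frame)[1:2]))
    stop("veil does not match the frame size", call. = FALSE)
  denom <- A - X
  n_clamped <- sum(denom < eps)
  if (n_clamped > 0L) {
    warning(n_clamped, " pixel(s) at or beyond opaque fog; denominator clamped",
            call. = FALSE)
    denom[denom < eps] <- eps
  }
  out <- frame
  for (ch in 1:3) out[, , ch] <- A * (frame[, , ch] - X) / denom
  clip01(out)
}

#' Joint-bilateral-filter parameters
#'
#' @param sigma_s spatial standard deviation in pixels.
#' @param sigma_c range standard deviation in unit-interval intensity.
#' @param radius window half-size in pixels; default `3 * sigma_s`.
#' @return list of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_s = 3, sigma_c = 0.1,
                             radius = ceiling(3 * sigma_s)) {
  if (sigma_s <= 0 || sigma_c <= 0) stop("sigmas must be > 0", call. = FALSE)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  structure(list(sigma_s = sigma_s, sigma_c = sigma_c,
                 radius = as.integer(radius)),
            class = "bilateral_params")
}

#' Joint (cross) bilateral filter
#'
#' Edge-preserving denoising of the recovered radiance: the spatial Gaussian
#' acts on the filtered image while the range Gaussian is driven by the
#' luminance of a guide image (the original hazy frame, whose edges are
#' trustworthy where the recovery amplified noise). Each output pixel is a
#' convex combination of its neighbourhood, normalised so the weights sum to
#' one; neighbourhoods are truncated at frame borders.
#'
#' @param image RGB frame to filter (recovered radiance `F`).
#' @param guide RGB frame supplying the range term (original frame `I`).
#' @param params a [bilateral_params()] object.
#' @param coeffs luma coefficients used for the guide's luminance.
#' @return filtered RGB frame.
#' @export
joint_bilateral_filter <- function(image, guide = image,
                                   params = bilateral_params(),
                                   coeffs = luma_coefficients()) {
  validate_frame(image)
  validate_frame(guide)
  if (!identical(dim(image), dim(guide)))
    stop("image and guide dimensions differ", call. = FALSE)
  g <- luminance(guide, coeffs)
  cpp_joint_bilateral(image, g, params$sigma_s, params$sigma_c, params$radius)
}

#' Full visibility-restoration branch
#'
#' Atmospheric light, veil, haze inversion and joint bilateral denoising in
#' one call.
#'
#' @inheritParams estimate_atmospheric_light
#' @param veil a [veil_params()] object.
#' @param bilateral a [bilateral_params()] object.
#' @return list with `image` (denoised restored frame), `restored` (before
#'   denoising), `veil` matrix and `A`.
#' @export
restore_visibility <- function(frame, veil = veil_params(),
                               bilateral = bilateral_params()) {
  A <- estimate_atmospheric_light(frame, veil)
  X <- estimate_veil(frame, A, veil)
  restored <- recover_radiance(frame, X, A)
  denoised <- joint_bilateral_filter(restored, frame, bilateral)
  list(image = denoised, restored = restored, veil = X, A = A)
}
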