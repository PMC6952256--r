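# Fusion of the enhancement and restoration branches in YCbCr space:
# edge-aware illumination estimation, smoke-level weight maps, weighted
# channel blending, histogram stretching of the fused luma, recombination.

#' Blending configuration
#'
#' The weight-1 intervals are 8-bit studio-range luma values: in heavy
#' smoke, pixels whose illumination falls in 16-128 receive full weight; in
#' thin smoke the interval is 128-235. Outside an interval the weight decays
#' linearly to the floor `eps` over `transition_width` luma levels, which
#' softens the hard intervals to avoid seams. `P` and `Q` bound the
#' histogram stretch of the fused luma.
#'
#' @param smoke_level `"thin"`, `"heavy"` or `"auto"` (resolved per frame by
#'   [classify_smoke()]).
#' @param heavy_interval,thin_interval weight-1 intervals, 8-bit luma.
#' @param P,Q stretch bounds, 8-bit luma (defaults 15 and 236).
#' @param transition_width soft-edge width in 8-bit luma levels.
#' @param eps weight floor, prevents a zero weight sum at any pixel.
#' @return list of class `blend_config`.
#' @export
blend_config <- function(smoke_level = c("auto", "thin", "heavy"),
                         heavy_interval = c(16, 128),
                         thin_interval = c(128, 235),
                         P = 15, Q = 236, transition_width = 16,
                         eps = 1e-4) {
  smoke_level <- match.arg(smoke_level)
  stopifnot(P < Q, all(c(heavy_interval, thin_interval, P, Q) >= 0),
            all(c(heavy_interval, thin_interval) <= 255), Q <= 255,
            transition_width > 0, eps > 0, eps < 1)
  structure(list(smoke_level = smoke_level,
                 heavy_interval = heavy_interval,
                 thin_interval = thin_interval,
                 P = P, Q = Q, transition_width = transition_width,
                 eps = eps),
            class = "blend_config")
}

#' Edge-aware illumination estimation
#'
#' Smooths a luma plane with the domain-transform recursive filter (RF
#' variant): causal/anticausal first-order passes over rows then columns,
#' repeated for `iterations` with a per-iteration sigma schedule, the
#' feedback coefficient adapting to local gradients so illumination does not
#' bleed across strong edges. An RGB frame input is reduced to its
#' luminance first.
#'
#' @param x luma matrix in `[0, 1]`, or an RGB frame.
#' @param sigma_spatial spatial standard deviation in pixels (default 30).
#' @param sigma_range range standard deviation in unit-interval intensity
#'   (default 0.2); smaller values preserve more edges.
#' @param iterations number of filtering iterations (default 3).
#' @return illumination matrix in `[0, 1]`, same size as the input plane.
#' @export
estimate_illumination <- function(x, sigma_spatial = 30, sigma_range = 0.2,
                                  iterations = 3L) {
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop("sigmas must be > 0", call. = FALSE)
  if (length(dim(x)) == 3L) x <- luminance(x)
  if (!is.matrix(x)) stop("x must be a luma matrix or an RGB frame", call. = FALSE)
  g <- cpp_domain_transform_rf(x, x, sigma_spatial, sigma_range,
                               as.integer(iterations))
  pmin(pmax(g, 0), 1)
}

#' Smoke-level weight map
#'
#' Maps an illumination plane to blending weights: 1 where `255 * G` lies in
#' the smoke level's weight-1 interval, decaying linearly to the floor `eps`
#' over `transition_width` luma levels outside it.
#'
#' @param G illumination matrix in `[0, 1]` (from
#'   [estimate_illumination()]).
#' @param level `"thin"` or `"heavy"` (an unresolved `"auto"` is rejected;
#'   resolve it with [classify_smoke()] first).
#' @param cfg a [blend_config()] object.
#' @return weight matrix with values in `[eps, 1]`.
#' @export
smoke_weight <- function(G, level, cfg = blend_config()) {
  if (!level %in% c("thin", "heavy"))
    stop("smoke level must be resolved to 'thin' or 'heavy'", call. = FALSE)
  iv <- if (level == "heavy") cfg$heavy_interval else cfg$thin_interval
  x <- 255 * G
  dist <- pmax(iv[1] - x, x - iv[2], 0)
  ramp <- pmax(0, 1 - dist / cfg$transition_width)
  w <- cfg$eps + (1 - cfg$eps) * ramp
  dim(w) <- dim(G)
  w
}

#' Classify a frame's smoke level
#'
#' Heavy if the frame's mean 8-bit luminance is strictly below 128,
#' otherwise thin. Deterministic.
#'
#' @inheritParams luminance
#' @return `"thin"` or `"heavy"`.
#' @export
classify_smoke <- function(frame, coeffs = luma_coefficients()) {
  if (255 * mean_luminance(frame, coeffs) < 128) "heavy" else "thin"
}

#' Blend the two branches in YCbCr space
#'
#' Converts the restored branch `J` and the enhanced branch `L` to
#' studio-range YCbCr and fuses each plane as the weighted average
#' `O_e = (WJ * J_e + WL * L_e) / (WJ + WL)`, `e` in `{Y, Cb, Cr}`. The
#' weight floor guarantees a positive denominator, and every fused value is
#' a convex combination of the two branch values.
#'
#' @param J restored-branch RGB frame.
#' @param L enhanced-branch RGB frame.
#' @param WJ,WL weight matrices from [smoke_weight()].
#' @return a `ycbcr_frame` with the fused planes.
#' @export
blend_channels <- function(J, L, WJ, WL) {
  d <- dim(J)[1:2]
  if (!identical(dim(L)[1:2], d) || !identical(dim(WJ), d) ||
      !identical(dim(WL), d))
    stop("branches and weight maps must share dimensions", call. = FALSE)
  jy <- rgb_to_ycbcr(J)
  ly <- rgb_to_ycbcr(L)
  tot <- WJ + WL
  structure(list(Y  = (WJ * jy$Y  + WL * ly$Y)  / tot,
                 Cb = (WJ * jy$Cb + WL * ly$Cb) / tot,
                 Cr = (WJ * jy$Cr + WL * ly$Cr) / tot,
                 range = "studio"),
            class = "ycbcr_frame")
}

#' Stretch the fused luma histogram
#'
#' Affine map of the plane's global extrema onto the 8-bit bounds `[P, Q]`
#' (defaults 15 and 236), restoring full-range contrast to the fused luma.
#' A constant plane has no contrast to stretch and is returned filled with
#' the midpoint `(P + Q) / 2`, with a warning.
#'
#' @param Y luma matrix.
#' @param cfg a [blend_config()] object supplying `P` and `Q`.
#' @return stretched luma matrix with extrema exactly `P/255` and `Q/255`.
#' @export
stretch_histogram <- function(Y, cfg = blend_config()) {
  o_min <- min(Y); o_max <- max(Y)
  if (o_max - o_min < .Machine$double.eps) {
    warning("constant luma plane: returning the stretch midpoint", call. = FALSE)
    return(matrix((cfg$P + cfg$Q) / 2 / 255, nrow(Y), ncol(Y)))
  }
  (cfg$P + (Y - o_min) / (o_max - o_min) * (cfg$Q - cfg$P)) / 255
}

#' Recombine stretched luma with the fused chroma
#'
#' Assembles the final defogged RGB frame from the stretched Y plane and
#' the blended Cb/Cr planes (studio-range inverse transform, clipped to
#' gamut).
#'
#' @param Y,Cb,Cr plane matrices sharing dimensions.
#' @return defogged RGB frame.
#' @export
recombine <- function(Y, Cb, Cr) {
  if (!identical(dim(Y), dim(Cb)) || !identical(dim(Y), dim(Cr)))
    stop("planes must share dimensions", call. = FALSE)
  ycbcr_to_rgb(structure(list(Y = Y, Cb = Cb, Cr = Cr, range = "studio"),
                         class = "ycbcr_frame"))
}
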