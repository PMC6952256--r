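# Image quality: single-scale SSIM, statistical naturalness, and the hybrid
# score psi = gamma*S + (1-gamma)*N.

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM on luminance: 11 x 11 Gaussian window with
#' sigma 1.5, stabilisers `K1 = 0.01`, `K2 = 0.03`, dynamic range 1.0, mean
#' over the local SSIM map. Local statistics use replicated borders. Inputs
#' may be RGB frames (reduced to luminance) or luma matrices.
#'
#' @param test,reference frames or luma matrices of equal dimensions.
#' @param K1,K2 stabilising constants.
#' @param window_size,window_sigma Gaussian window size and sigma.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(test, reference, K1 = 0.01, K2 = 0.03,
                 window_size = 11L, window_sigma = 1.5) {
  x <- if (length(dim(test)) == 3L) luminance(test) else test
  y <- if (length(dim(reference)) == 3L) luminance(reference) else reference
  if (!identical(dim(x), dim(y)))
    stop("test and reference dimensions differ", call. = FALSE)
  w <- EBImage::makeBrush(window_size, shape = "gaussian", sigma = window_sigma)
  w <- w / sum(w)
  f <- function(z) EBImage::filter2(z, w, boundary = "replicate")
  mu_x <- f(x); mu_y <- f(y)
  sxx <- f(x * x) - mu_x^2
  syy <- f(y * y) - mu_y^2
  sxy <- f(x * y) - mu_x * mu_y
  C1 <- K1^2; C2 <- K2^2  # dynamic range L = 1
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Naturalness-prior parameters
#'
#' Priors fitted to large natural-image corpora: mean brightness follows a
#' Gaussian (mu 115.94, sigma 27.99 on the 8-bit scale) and contrast - the
#' mean local luma standard deviation divided by `contrast_scale` - follows
#' a Beta(4.4, 10.1) density.
#'
#' @param mean_mu,mean_sigma Gaussian prior on mean 8-bit luma.
#' @param beta_shape1,beta_shape2 Beta prior shapes on normalised contrast.
#' @param contrast_scale divisor mapping 8-bit luma standard deviation onto
#'   the Beta support.
#' @return named list of class `naturalness_params`.
#' @export
naturalness_params <- function(mean_mu = 115.94, mean_sigma = 27.99,
                               beta_shape1 = 4.4, beta_shape2 = 10.1,
                               contrast_scale = 64.29) {
  structure(list(mean_mu = mean_mu, mean_sigma = mean_sigma,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 contrast_scale = contrast_scale),
            class = "naturalness_params")
}

#' Statistical naturalness score
#'
#' No-reference score in `[0, 1]` rating a frame's brightness and contrast
#' against natural-image priors, following the statistical-naturalness
#' construction of the tone-mapped-image quality index:
#' `N = P_m(mean luma) * P_d(contrast) / K`, where the contrast statistic
#' is the mean of local (`block x block`, default 11) luma standard
#' deviations scaled by `contrast_scale`, `P_m` is the Gaussian brightness
#' prior, `P_d` the Beta contrast prior and `K` the product of the two
#' density maxima so an ideally bright, ideally contrasted frame scores 1.
#' Washed-out smoky frames (bright mean, attenuated local contrast) fall in
#' both priors' tails and score near 0.
#'
#' @inheritParams luminance
#' @param params a [naturalness_params()] object.
#' @param block side of the non-overlapping blocks over which local
#'   standard deviations are taken.
#' @return scalar in `[0, 1]`.
#' @export
naturalness <- function(frame, params = naturalness_params(),
                        coeffs = luma_coefficients(), block = 11L) {
  h <- if (length(dim(frame)) == 3L) luminance(frame, coeffs) else frame
  naturalness_from_stats(255 * mean(h), 255 * mean_block_sd(h, block), params)
}

#' @rdname naturalness
#' @param mean_luma mean luminance on the 8-bit scale.
#' @param contrast mean local luma standard deviation, 8-bit scale.
#' @export
naturalness_from_stats <- function(mean_luma, contrast,
                                   params = naturalness_params()) {
  d <- contrast / params$contrast_scale
  pm <- stats::dnorm(mean_luma, params$mean_mu, params$mean_sigma)
  pd <- if (d >= 0 && d <= 1) stats::dbeta(d, params$beta_shape1, params$beta_shape2) else 0
  mode_d <- (params$beta_shape1 - 1) /
    (params$beta_shape1 + params$beta_shape2 - 2)
  k <- stats::dnorm(params$mean_mu, params$mean_mu, params$mean_sigma) *
    stats::dbeta(mode_d, params$beta_shape1, params$beta_shape2)
  (pm * pd) / k
}

# mean of per-block standard deviations over non-overlapping blocks;
# trailing partial blocks are included as-is (single-pixel blocks, which
# have no deviation, are excluded).
mean_block_sd <- function(h, block) {
  bi <- (seq_len(nrow(h)) - 1L) %/% block
  bj <- (seq_len(ncol(h)) - 1L) %/% block
  idx <- bi[row(h)] * (max(bj) + 1L) + bj[col(h)]
  counts <- tabulate(idx + 1L)
  sds <- tapply(as.vector(h), idx, stats::sd)
  mean(sds[counts[as.integer(names(sds)) + 1L] > 1L])
}

#' Hybrid quality score
#'
#' `psi = gamma * S + (1 - gamma) * N`: an affine combination of structural
#' similarity and naturalness balancing structure preservation against
#' perceptual naturalness. The default `gamma = 0.6` weights structure
#' slightly above naturalness.
#'
#' @param S SSIM value(s).
#' @param N naturalness value(s).
#' @param gamma blend coefficient in `[0, 1]`.
#' @return `psi`, vectorised over `S` and `N`.
#' @export
hybrid_quality <- function(S, N, gamma = 0.6) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must be in [0, 1]", call. = FALSE)
  gamma * S + (1 - gamma) * N
}

#' Score a defogged sequence
#'
#' Per-frame SSIM of each defogged frame against the corresponding original
#' (the clinically available reference), naturalness of the defogged frame,
#' and the hybrid score; aggregates are arithmetic means. When simulated
#' clean ground truth is supplied, SSIM against truth is reported in a
#' separate column.
#'
#' @param defogged,originals equal-length lists of RGB frames.
#' @param gamma hybrid blend coefficient.
#' @param clean optional list of ground-truth frames (simulation only).
#' @param params a [naturalness_params()] object.
#' @return object of class `quality_report`: list with `per_frame`
#'   (data.frame of `frame`, `ssim`, `naturalness`, `psi`, optionally
#'   `ssim_truth`), `aggregates` (means) and `gamma`.
#' @export
evaluate_sequence <- function(defogged, originals, gamma = 0.6, clean = NULL,
                              params = naturalness_params()) {
  if (length(defogged) != length(originals))
    stop("defogged and original sequences differ in length", call. = FALSE)
  if (!is.null(clean) && length(clean) != length(defogged))
    stop("ground-truth sequence length mismatch", call. = FALSE)
  n <- length(defogged)
  ids <- names(defogged) %||% sprintf("frame_%04d", seq_len(n))
  S <- vapply(seq_len(n), function(i) ssim(defogged[[i]], originals[[i]]),
              numeric(1))
  N <- vapply(seq_len(n), function(i) naturalness(defogged[[i]], params),
              numeric(1))
  per_frame <- data.frame(frame = ids, ssim = S, naturalness = N,
                          psi = hybrid_quality(S, N, gamma),
                          stringsAsFactors = FALSE)
  if (!is.null(clean))
    per_frame$ssim_truth <- vapply(seq_len(n),
      function(i) ssim(defogged[[i]], clean[[i]]), numeric(1))
  aggregates <- as.list(colMeans(per_frame[, -1, drop = FALSE]))
  structure(list(per_frame = per_frame, aggregates = aggregates,
                 gamma = gamma),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality report: %d frame(s), gamma = %.2f\n",
              nrow(x$per_frame), x$gamma))
  cat(sprintf("  mean SSIM        %.4f\n", x$aggregates$ssim))
  cat(sprintf("  mean naturalness %.4f\n", x$aggregates$naturalness))
  cat(sprintf("  mean psi         %.4f\n", x$aggregates$psi))
  if (!is.null(x$aggregates$ssim_truth))
    cat(sprintf("  mean SSIM vs ground truth %.4f\n", x$aggregates$ssim_truth))
  invisible(x)
}

#' Export a quality report
#'
#' Writes the per-frame table as CSV and, optionally, the aggregates as
#' JSON.
#'
#' @param report a `quality_report`.
#' @param csv path for the per-frame CSV.
#' @param json optional path for the aggregate JSON.
#' @return `csv`, invisibly.
#' @export
write_quality_report <- function(report, csv, json = NULL) {
  utils::write.csv(report$per_frame, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report$aggregates, json, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv)
}
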