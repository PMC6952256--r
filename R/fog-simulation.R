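# Forward Koschmieder haze model and the synthetic smoke simulator that
# provides ground truth (clean frame + transmission field) for benchmarking.

#' Transmission map from scene depth
#'
#' Beer-Lambert attenuation `T = exp(-k * d)`: the fraction of unscattered
#' light reaching the camera through a medium with scattering factor `k`
#' over distance `d`.
#'
#' @param k scattering factor per unit depth, `>= 0`.
#' @param depth matrix of camera-to-object distances, `>= 0`.
#' @return transmission matrix with values in `(0, 1]`.
#' @export
transmission_from_depth <- function(k, depth) {
  if (!is.finite(k) || k < 0) stop("k must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depth must be finite and >= 0 everywhere", call. = FALSE)
  exp(-k * depth)
}

#' Composite fog onto a clean frame (Koschmieder's law)
#'
#' `I = F*T + A*(1 - T)` per channel, optionally with additive Gaussian
#' sensor noise, clipped to the unit interval. Deterministic for a given
#' `seed`; the caller's RNG state is preserved.
#'
#' @param clean haze-free RGB frame (scene radiance `F`).
#' @param transmission matrix `T` in `[0, 1]`, same raster size as `clean`.
#' @param A atmospheric light: scalar in `(0, 1]` or per-channel triple.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed for the noise; `NULL` uses the current RNG.
#' @return hazy RGB frame.
#' @export
apply_fog <- function(clean, transmission, A, noise_sigma = 0, seed = NULL) {
  validate_frame(clean)
  d <- dim(clean)
  if (!identical(dim(transmission), d[1:2]))
    stop("transmission map does not match the frame size", call. = FALSE)
  if (min(transmission) < 0 || max(transmission) > 1)
    stop("transmission values must lie in [0, 1]", call. = FALSE)
  if (any(A <= 0) || any(A > 1) || !length(A) %in% c(1L, 3L))
    stop("A must be a scalar or triple in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  A <- rep(A, length.out = 3L)
  hazy <- clean
  for (ch in 1:3)
    hazy[, , ch] <- clean[, , ch] * transmission + A[ch] * (1 - transmission)
  if (noise_sigma > 0) {
    noise <- with_local_seed(seed, rnorm(length(hazy), sd = noise_sigma))
    hazy <- hazy + noise
  }
  clip01(hazy)
}

#' Atmospheric veil of a transmission field
#'
#' `X = A * (1 - T)`: the additive haze layer. Estimating `X` sidesteps
#' explicit depth estimation; the relation inverts exactly as
#' `T = 1 - X/A`.
#'
#' @inheritParams apply_fog
#' @return veil matrix with values in `[0, A]`.
#' @export
veil_from_transmission <- function(transmission, A) {
  if (length(A) != 1L || A <= 0 || A > 1)
    stop("A must be a scalar in (0, 1]", call. = FALSE)
  if (min(transmission) < 0 || max(transmission) > 1)
    stop("transmission values must lie in [0, 1]", call. = FALSE)
  A * (1 - transmission)
}

#' Synthetic endoscopic scene with a known transmission field
#'
#' Generates a clean frame with controllable high-frequency structure and a
#' transmission field emulating surgical smoke. Scene kinds: `"vessels"`
#' (vignetted pinkish tissue, dark meandering vessel curves, sparse specular
#' glints and fine texture - the closest to a real endoscopic view),
#' `"gradient"` (smooth illumination ramp) and `"checker"` (hard edges for
#' filter tests). Smoke kinds: `"homogeneous"` (constant transmission at the
#' midpoint of `[t_min, t_max]`) or `"plume"` (Gaussian-smoothed white noise
#' rescaled to `[t_min, t_max]`, reproducing inhomogeneous smoke).
#' Outputs are bitwise reproducible for a given seed.
#'
#' @param width,height raster size in pixels, at least 16 x 16.
#' @param scene_kind one of `"vessels"`, `"gradient"`, `"checker"`.
#' @param smoke_kind one of `"plume"`, `"homogeneous"`.
#' @param seed integer seed.
#' @param t_min,t_max transmission bounds of the smoke field.
#' @param smoothness Gaussian sigma (pixels) of the plume field; larger is
#'   smoother. Default `min(width, height) / 6`.
#' @return list with `clean` (RGB frame) and `transmission` (matrix).
#' @export
generate_scene <- function(width, height,
                           scene_kind = c("vessels", "gradient", "checker"),
                           smoke_kind = c("plume", "homogeneous"),
                           seed = 1L, t_min = 0.15, t_max = 0.5,
                           smoothness = NULL) {
  scene_kind <- match.arg(scene_kind)
  smoke_kind <- match.arg(smoke_kind)
  if (width < 16L || height < 16L)
    stop("scene must be at least 16 x 16 pixels", call. = FALSE)
  if (t_min < 0 || t_max > 1 || t_min > t_max)
    stop("need 0 <= t_min <= t_max <= 1", call. = FALSE)
  smoothness <- smoothness %||% (min(width, height) / 6)
  with_local_seed(seed, {
    clean <- switch(scene_kind,
      vessels  = scene_vessels(width, height),
      gradient = scene_gradient(width, height),
      checker  = scene_checker(width, height)
    )
    transmission <- if (smoke_kind == "homogeneous") {
      matrix((t_min + t_max) / 2, height, width)
    } else {
      plume_field(width, height, t_min, t_max, smoothness)
    }
    list(clean = clean, transmission = transmission)
  })
}

# Gaussian smoothing with the brush capped to the raster size (EBImage's
# default 6-sigma support can exceed small frames).
gauss_smooth <- function(m, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(m))
  if (r > cap) r <- cap - (1L - cap %% 2L)  # largest odd size that fits
  EBImage::gblur(m, sigma = sigma, radius = r)
}

# Smoothed-white-noise transmission field rescaled to [t_min, t_max].
plume_field <- function(width, height, t_min, t_max, smoothness) {
  n <- matrix(rnorm(width * height), height, width)
  s <- gauss_smooth(n, smoothness)
  rng <- range(s)
  if (rng[2] - rng[1] < .Machine$double.eps) return(matrix((t_min + t_max) / 2, height, width))
  t_min + (s - rng[1]) / (rng[2] - rng[1]) * (t_max - t_min)
}

# smooth random field in [-1, 1], used to modulate tissue colour
smooth_noise <- function(width, height, sigma) {
  s <- gauss_smooth(matrix(rnorm(width * height), height, width), sigma)
  rng <- range(s)
  if (rng[2] - rng[1] < .Machine$double.eps) return(matrix(0, height, width))
  2 * (s - rng[1]) / (rng[2] - rng[1]) - 1
}

scene_vessels <- function(width, height) {
  u <- matrix(rep(seq_len(width), each = height), height, width)
  v <- matrix(rep(seq_len(height), width), height, width)
  cx <- width / 2; cy <- height / 2
  vign <- 1 - 0.45 * (((u - cx) / (width / 2))^2 + ((v - cy) / (height / 2))^2) / 2
  f1 <- smooth_noise(width, height, min(width, height) / 5)
  f2 <- smooth_noise(width, height, min(width, height) / 5)
  frame <- array(0, dim = c(height, width, 3L))
  frame[, , 1] <- (0.64 + 0.10 * f1) * vign
  frame[, , 2] <- (0.30 + 0.08 * f2) * vign
  frame[, , 3] <- (0.26 + 0.06 * f1) * vign
  # dark meandering vessels: random-walk curves stamped as small discs
  n_vessels <- max(5L, round(0.03 * sqrt(width * height)))
  vcol <- c(0.36, 0.09, 0.09)
  for (k in seq_len(n_vessels)) {
    x <- runif(1, 1, width); y <- runif(1, 1, height)
    ang <- runif(1, 0, 2 * pi)
    r <- sample(1:2, 1)
    for (s in seq_len(round(0.8 * max(width, height)))) {
      ang <- ang + rnorm(1, sd = 0.25)
      x <- x + cos(ang); y <- y + sin(ang)
      if (x < 1 || x > width || y < 1 || y > height) break
      ii <- max(1, round(y) - r):min(height, round(y) + r)
      jj <- max(1, round(x) - r):min(width, round(x) + r)
      for (ch in 1:3)
        frame[ii, jj, ch] <- 0.3 * frame[ii, jj, ch] + 0.7 * vcol[ch] * vign[ii, jj]
    }
  }
  # sparse specular glints from wet tissue
  n_glints <- max(3L, round(width * height / 20000))
  for (k in seq_len(n_glints)) {
    gi <- sample(seq_len(height), 1); gj <- sample(seq_len(width), 1)
    ii <- max(1, gi - 1):min(height, gi + 1)
    jj <- max(1, gj - 1):min(width, gj + 1)
    for (ch in 1:3) frame[ii, jj, ch] <- 0.96
  }
  frame <- frame + array(rnorm(length(frame), sd = 0.015), dim = dim(frame))
  clip01(frame)
}

scene_gradient <- function(width, height) {
  ramp <- matrix(rep(seq(0.15, 0.85, length.out = width), each = height),
                 height, width)
  tilt <- matrix(rep(seq(-0.05, 0.05, length.out = height), width),
                 height, width)
  frame <- array(0, dim = c(height, width, 3L))
  frame[, , 1] <- ramp
  frame[, , 2] <- clip01(0.55 * ramp + tilt)
  frame[, , 3] <- 0.5 * ramp
  clip01(frame)
}

scene_checker <- function(width, height) {
  cell <- max(4L, round(min(width, height) / 8))
  u <- matrix(rep(seq_len(width), each = height), height, width)
  v <- matrix(rep(seq_len(height), width), height, width)
  odd <- ((u - 1) %/% cell + (v - 1) %/% cell) %% 2 == 1
  c1 <- c(0.70, 0.35, 0.30); c2 <- c(0.30, 0.45, 0.40)
  frame <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) frame[, , ch] <- ifelse(odd, c1[ch], c2[ch])
  frame
}

#' Smoke presets and the hazy-frame fixture generator
#'
#' `smoke_preset()` returns the transmission bounds emulating thin
#' (`T` in `[0.6, 0.9]`) and heavy (`T` in `[0.15, 0.5]`) surgical smoke
#' under near-white atmospheric light. `simulate_smoke_frame()` draws a
#' scene, composites fog with mild sensor noise and quantises the hazy frame
#' to 8 bits, mimicking real acquisition before it enters the pipeline.
#'
#' @param level `"thin"` or `"heavy"`.
#' @return `smoke_preset()`: list with `t_min`, `t_max`, `A`, `noise_sigma`.
#' @export
smoke_preset <- function(level = c("thin", "heavy")) {
  level <- match.arg(level)
  if (level == "thin")
    list(t_min = 0.6, t_max = 0.9, A = 0.95, noise_sigma = 0.003)
  else
    list(t_min = 0.15, t_max = 0.5, A = 0.95, noise_sigma = 0.003)
}

#' @rdname smoke_preset
#' @inheritParams generate_scene
#' @param preset a [smoke_preset()] list (or its name).
#' @return `simulate_smoke_frame()`: list with `clean`, `transmission`,
#'   `hazy` (8-bit quantised), `A`, `noise_sigma`, `seed`.
#' @export
simulate_smoke_frame <- function(width, height, preset = "heavy",
                                 scene_kind = "vessels",
                                 smoke_kind = "plume", seed = 1L) {
  if (is.character(preset)) preset <- smoke_preset(preset)
  sc <- generate_scene(width, height, scene_kind, smoke_kind, seed = seed,
                       t_min = preset$t_min, t_max = preset$t_max)
  hazy <- apply_fog(sc$clean, sc$transmission, preset$A,
                    noise_sigma = preset$noise_sigma, seed = seed + 1L)
  list(clean = sc$clean, transmission = sc$transmission,
       hazy = quantize_frame(hazy), A = preset$A,
       noise_sigma = preset$noise_sigma, seed = seed)
}
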