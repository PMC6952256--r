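test_that("illumination estimation fixes constants and respects hard edges", {
  cm <- matrix(0.37, 10, 14)
  expect_equal(estimate_illumination(cm), cm)
  # vanishing range sigma: every gradient blocks diffusion -> identity
  set.seed(21)
  rnd <- matrix(runif(120, 0.1, 0.9), 10, 12)
  expect_equal(estimate_illumination(rnd, sigma_range = 1e-9), rnd)
  expect_error(estimate_illumination(rnd, sigma_spatial = 0), "sigmas")
  # RGB input is reduced to luminance first
  fr <- random_frame(2)
  expect_equal(estimate_illumination(fr), estimate_illumination(luminance(fr)))
})

test_that("one recursive pass over a row matches a direct evaluation", {
  x <- c(rep(0.2, 10), rep(0.8, 10))
  sigma_s <- 5; sigma_r <- 0.3
  # independent single-row oracle: causal then anticausal first-order filter
  a <- exp(-sqrt(2) / sigma_s)           # 1 iteration: sigma_1 = sigma_s
  d <- c(NA, 1 + (sigma_s / sigma_r) * abs(diff(x)))
  J <- x
  for (j in 2:20) J[j] <- J[j] + a^d[j] * (J[j - 1] - J[j])
  for (j in 19:1) J[j] <- J[j] + a^d[j + 1] * (J[j + 1] - J[j])
  got <- estimate_illumination(matrix(x, nrow = 1), sigma_spatial = sigma_s,
                               sigma_range = sigma_r, iterations = 1L)
  expect_equal(as.vector(got), J, tolerance = 1e-12)
})

test_that("smoke weights honour the 8-bit intervals and soft edges", {
  cfg <- blend_config(transition_width = 16)
  w_at <- function(l8, level) smoke_weight(matrix(l8 / 255, 1, 1), level, cfg)[1, 1]
  expect_equal(w_at(64, "heavy"), 1)     # inside 16-128
  expect_equal(w_at(150, "thin"), 1)     # inside [128, 235]
  expect_equal(w_at(250, "heavy"), cfg$eps)  # far beyond the soft edge
  expect_equal(w_at(136, "heavy"), cfg$eps + (1 - cfg$eps) * 0.5)  # mid-ramp
  G <- matrix(runif(100), 10, 10)
  W <- smoke_weight(G, "thin", cfg)
  expect_true(all(W >= cfg$eps) && all(W <= 1))
  expect_error(smoke_weight(G, "auto", cfg), "resolved")
})

test_that("smoke classification thresholds mean 8-bit luminance at 128", {
  expect_identical(classify_smoke(const_frame(64 / 255)), "heavy")
  expect_identical(classify_smoke(const_frame(200 / 255)), "thin")
  expect_identical(classify_smoke(const_frame(128 / 255)), "thin")  # strict-less
})

test_that("channel blending is the weighted mean of the branch planes", {
  h <- 6; w <- 6
  # gray levels chosen so the studio Y planes are 0.8 and 0.4 exactly
  J <- const_frame((0.8 * 255 - 16) / 219, h, w)
  L <- const_frame((0.4 * 255 - 16) / 219, h, w)
  W1 <- matrix(1, h, w)
  out <- blend_channels(J, L, 3 * W1, W1)
  expect_equal(out$Y, matrix(0.7, h, w))
  eq <- blend_channels(J, L, W1, W1)
  jy <- rgb_to_ycbcr(J); ly <- rgb_to_ycbcr(L)
  expect_equal(eq$Y, (jy$Y + ly$Y) / 2)
  expect_equal(eq$Cb, (jy$Cb + ly$Cb) / 2)
  # one-sided weights reproduce the dominant branch
  eps <- 1e-4
  onesided <- blend_channels(J, L, W1, matrix(eps, h, w))
  expect_lt(max(abs(onesided$Y - jy$Y)), 2 * eps)
  expect_error(blend_channels(J, L, W1, matrix(1, 2, 2)), "dimensions")
})

test_that("blended planes stay between the branch planes", {
  J <- random_frame(5, 12, 12); L <- random_frame(6, 12, 12)
  set.seed(7)
  WJ <- matrix(runif(144, 1e-4, 1), 12, 12)
  WL <- matrix(runif(144, 1e-4, 1), 12, 12)
  out <- blend_channels(J, L, WJ, WL)
  jy <- rgb_to_ycbcr(J); ly <- rgb_to_ycbcr(L)
  for (pl in c("Y", "Cb", "Cr")) {
    lo <- pmin(jy[[pl]], ly[[pl]]); hi <- pmax(jy[[pl]], ly[[pl]])
    expect_true(all(out[[pl]] >= lo - 1e-12) && all(out[[pl]] <= hi + 1e-12))
  }
})

test_that("histogram stretching maps extrema onto P and Q", {
  cfg <- blend_config()          # P = 15, Q = 236
  y <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  out <- stretch_histogram(y, cfg)
  expect_equal(out[y == 0], 15 / 255)
  expect_equal(out[y == 1], 236 / 255)
  expect_equal(out[y == 0.5], (15 + 0.5 * 221) / 255)   # affine midpoint
  # rank preservation on a random plane
  set.seed(8)
  y2 <- matrix(runif(100), 10, 10)
  out2 <- stretch_histogram(y2, cfg)
  expect_identical(order(as.vector(out2)), order(as.vector(y2)))
  expect_warning(out3 <- stretch_histogram(matrix(0.4, 4, 4), cfg), "constant")
  expect_equal(out3, matrix((15 + 236) / 2 / 255, 4, 4))
})

test_that("recombination inverts the colour transform and clips to gamut", {
  fr <- quantize_frame(random_frame(9, 10, 10))
  ycc <- rgb_to_ycbcr(fr)
  expect_lt(max(abs(recombine(ycc$Y, ycc$Cb, ycc$Cr) - fr)), 2 / 255)
  # neutral chroma yields an achromatic frame
  gray <- recombine(matrix(seq(16, 235, length.out = 16) / 255, 4, 4),
                    matrix(128 / 255, 4, 4), matrix(128 / 255, 4, 4))
  expect_equal(gray[, , 1], gray[, , 2])
  expect_equal(gray[, , 2], gray[, , 3])
  # gamut-exceeding plane combinations still land in [0, 1]
  hot <- recombine(matrix(235 / 255, 4, 4), matrix(240 / 255, 4, 4),
                   matrix(16 / 255, 4, 4))
  expect_true(min(hot) >= 0 && max(hot) <= 1)
  expect_error(recombine(matrix(0.5, 2, 2), matrix(0.5, 2, 3),
                         matrix(0.5, 2, 2)), "dimensions")
})
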