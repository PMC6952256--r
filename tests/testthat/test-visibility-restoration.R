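test_that("atmospheric light estimation follows the configured convention", {
  expect_identical(estimate_atmospheric_light(random_frame(1)), 1.0)
  est <- veil_params(white_balance_A = FALSE)
  expect_equal(estimate_atmospheric_light(const_frame(0.63), est), 0.63)
  # synthetic heavy smoke with known A: bright-pixel estimator lands close
  fx <- simulate_smoke_frame(120, 90, "heavy", seed = 2)
  expect_lt(abs(estimate_atmospheric_light(fx$hazy, est) - fx$A), 0.05)
})

test_that("veil estimation respects its bounds and the constant-frame form", {
  expect_equal(estimate_veil(const_frame(0, 20, 20)), matrix(0, 20, 20))
  cf <- const_frame(0.4, h = 20, w = 20)
  expect_equal(estimate_veil(cf, 1, veil_params(p_factor = 0.95)),
               matrix(0.95 * 0.4, 20, 20))
  fr <- random_frame(9, 24, 24)
  X <- estimate_veil(fr)
  minmap <- pmin(fr[, , 1], fr[, , 2], fr[, , 3])
  expect_true(all(X <= minmap + 1e-12))
  expect_true(all(X >= 0) && all(X <= 1))
  expect_error(estimate_veil(random_frame(1, 8, 8), 1, veil_params(window = 7)),
               "window")
})

test_that("radiance recovery inverts the haze model", {
  fr <- random_frame(2)
  expect_equal(recover_radiance(fr, matrix(0, 16, 16), 1), fr)
  one <- const_frame(0.6)
  expect_equal(recover_radiance(one, matrix(0.5, 8, 8), 1), const_frame(0.2))
  # exact inverse pair with the true veil
  sc <- generate_scene(48, 32, seed = 5, t_min = 0.1, t_max = 0.9)
  hz <- apply_fog(sc$clean, sc$transmission, 0.9)
  X <- veil_from_transmission(sc$transmission, 0.9)
  rec <- recover_radiance(hz, X, 0.9)
  keep <- rep(sc$transmission > 0.05, 3)
  expect_lt(max(abs(rec - sc$clean)[keep]), 1e-6)
  # opaque pixels clamp the denominator with a warning, not an error
  expect_warning(recover_radiance(one, matrix(0.9999, 8, 8), 1), "clamped")
})

test_that("joint bilateral filtering is a convex neighbourhood combination", {
  cf <- const_frame(0.42, h = 12, w = 12)
  expect_equal(joint_bilateral_filter(cf, cf), cf)
  fr <- random_frame(3, 12, 12)
  expect_equal(joint_bilateral_filter(fr, fr, bilateral_params(radius = 0)), fr)
  # output lies within the min/max of each pixel's neighbourhood
  r <- 2L
  out <- joint_bilateral_filter(fr, fr, bilateral_params(sigma_s = 1.5,
                                                         sigma_c = 0.2,
                                                         radius = r))
  for (ch in 1:3) {
    plane <- fr[, , ch]
    for (i in seq_len(12)) for (j in seq_len(12)) {
      nb <- plane[max(1, i - r):min(12, i + r), max(1, j - r):min(12, j + r)]
      expect_gte(out[i, j, ch], min(nb) - 1e-12)
      expect_lte(out[i, j, ch], max(nb) + 1e-12)
    }
  }
  expect_error(joint_bilateral_filter(fr, random_frame(1, 8, 8)), "dimensions")
})

test_that("a flat range kernel reduces to truncated Gaussian convolution", {
  fr <- random_frame(4, 10, 12)
  sigma_s <- 1.2; r <- 3L
  out <- joint_bilateral_filter(fr, fr,
                                bilateral_params(sigma_s = sigma_s,
                                                 sigma_c = 1e6, radius = r))
  # independent direct-convolution oracle with border renormalisation
  oracle <- fr
  for (i in 1:10) for (j in 1:12) {
    ii <- max(1, i - r):min(10, i + r)
    jj <- max(1, j - r):min(12, j + r)
    w <- outer(ii - i, jj - j, function(a, b) exp(-(a^2 + b^2) / (2 * sigma_s^2)))
    for (ch in 1:3)
      oracle[i, j, ch] <- sum(w * fr[ii, jj, ch]) / sum(w)
  }
  expect_lt(max(abs(out - oracle)), 1e-6)
})

test_that("the range kernel preserves step edges", {
  st <- array(0.2, c(16, 30, 3)); st[, 16:30, ] <- 0.8
  f <- joint_bilateral_filter(st, st, bilateral_params(sigma_s = 3,
                                                       sigma_c = 0.02,
                                                       radius = 9))
  expect_lt(max(abs(f - st)), 1e-9)
})

test_that("restoration improves structure over the hazy input in heavy smoke", {
  fx <- simulate_smoke_frame(160, 120, "heavy", seed = 6)
  res <- restore_visibility(fx$hazy)
  expect_gt(ssim(res$image, fx$clean), ssim(fx$hazy, fx$clean))
  # veil invariants hold on the estimated veil too
  minmap <- pmin(fx$hazy[, , 1], fx$hazy[, , 2], fx$hazy[, , 3])
  expect_true(all(res$veil <= minmap + 1e-12))
  expect_true(all(res$veil <= res$A))
})
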