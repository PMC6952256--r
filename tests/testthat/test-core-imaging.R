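test_that("luminance evaluates the weighted channel sum", {
  expect_equal(luminance(const_frame(100 / 255))[1, 1], 100 / 255)
  expect_equal(luminance(rgb_frame(1, 0, 0))[1, 1], 0.299)
  expect_equal(luminance(rgb_frame(0, 1, 0))[1, 1], 0.587)
  expect_equal(luminance(rgb_frame(0, 0, 1))[1, 1], 0.114)
})

test_that("luminance is linear in the frame", {
  f1 <- random_frame(1); f2 <- random_frame(2)
  for (alpha in c(0, 0.3, 0.7, 1)) {
    mix <- alpha * f1 + (1 - alpha) * f2
    expect_equal(luminance(mix),
                 alpha * luminance(f1) + (1 - alpha) * luminance(f2))
  }
})

test_that("invalid frames are rejected", {
  bad <- const_frame(0.5)
  bad[1, 1, 1] <- NaN
  expect_error(luminance(bad), "non-finite")
  expect_error(validate_frame(const_frame(1.5)), "\\[0, 1\\]")
  expect_error(validate_frame(matrix(0.5, 4, 4)), "array")
})

test_that("luma coefficients must sum to one", {
  co <- luma_coefficients()
  expect_equal(co$a + co$b + co$c, 1, tolerance = 1e-9)
  expect_error(luma_coefficients(0.5, 0.5, 0.5), "sum to 1")
})

test_that("mean luminance averages over all pixels", {
  expect_equal(mean_luminance(const_frame(0.5)), 0.5)
  fr <- const_frame(0, h = 2, w = 2)
  for (ch in 1:3) fr[, , ch] <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_equal(mean_luminance(fr), 0.25)  # gray pixels: luma equals the level
  two <- const_frame(0, h = 1, w = 2); two[1, 2, ] <- 1
  expect_equal(mean_luminance(two), 0.5)
})

test_that("8-bit round trip is the identity for all 256 levels", {
  lv <- 0:255
  expect_identical(frame_to_8bit(frame_from_8bit(lv)), lv)
  q <- quantize_frame(runif(1000))
  expect_true(all(abs(q * 255 - round(q * 255)) < 1e-9))
})

test_that("studio-range YCbCr maps the reference points", {
  blk <- rgb_to_ycbcr(const_frame(0))
  expect_equal(blk$Y[1, 1], 16 / 255)
  expect_equal(blk$Cb[1, 1], 128 / 255)
  expect_equal(blk$Cr[1, 1], 128 / 255)
  gry <- rgb_to_ycbcr(const_frame(0.4))
  expect_equal(gry$Cb[1, 1], 128 / 255)
  expect_equal(gry$Cr[1, 1], 128 / 255)
  # Y plane is the studio-scaled raw luminance
  fr <- random_frame(3)
  ycc <- rgb_to_ycbcr(fr)
  expect_equal(ycc$Y, (16 + 219 * luminance(fr)) / 255)
  # studio ranges hold for arbitrary valid input
  expect_true(min(ycc$Y) >= 16 / 255 - 1e-12 && max(ycc$Y) <= 235 / 255 + 1e-12)
  expect_true(min(ycc$Cb, ycc$Cr) >= 16 / 255 - 1e-12)
  expect_true(max(ycc$Cb, ycc$Cr) <= 240 / 255 + 1e-12)
})

test_that("YCbCr conversions invert within quantisation tolerance", {
  set.seed(42)
  px <- array(runif(10000 * 3), dim = c(100, 100, 3))
  for (rng in c("studio", "full")) {
    back <- ycbcr_to_rgb(rgb_to_ycbcr(px, range = rng))
    expect_lt(max(abs(back - px)), 2 / 255)
  }
  bad <- rgb_to_ycbcr(px)
  bad$range <- "cinema"
  expect_error(ycbcr_to_rgb(bad), "unknown range")
})

test_that("frames survive PNG and TIFF round trips", {
  fr <- quantize_frame(random_frame(7, 12, 10))
  p <- tempfile(fileext = ".png")
  write_frame(fr, p)
  expect_equal(read_frame(p), fr)
  tf <- tempfile(fileext = ".tiff")
  write_frame(fr, tf, bits = 16L)
  expect_lt(max(abs(read_frame(tf) - fr)), 1 / 65535 + 1e-9)
  # grayscale input is replicated to three channels
  g <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 6, 6), g)
  gr <- read_frame(g)
  expect_identical(dim(gr), c(6L, 6L, 3L))
  unlink(c(p, tf, g))
})

test_that("frame directories read and write as ordered sequences", {
  dir <- tempfile("seq")
  frames <- lapply(1:3, function(s) quantize_frame(random_frame(s, 8, 8)))
  write_frames(frames, dir)
  back <- read_frames(dir)
  expect_length(back, 3)
  expect_equal(unname(back), frames)
  # unreadable files are skipped with a warning
  writeLines("not a png", file.path(dir, "frame_0000.png"))
  expect_warning(back2 <- read_frames(dir), "skipping")
  expect_length(back2, 3)
  unlink(dir, recursive = TRUE)
})
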