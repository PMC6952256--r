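# fixtures built in code: tiny frames and planes used across the suite

const_frame <- function(value, h = 8, w = 8) {
  array(value, dim = c(h, w, 3))
}

# constant frame with per-channel values
rgb_frame <- function(r, g, b, h = 8, w = 8) {
  fr <- array(0, dim = c(h, w, 3))
  fr[, , 1] <- r; fr[, , 2] <- g; fr[, , 3] <- b
  fr
}

random_frame <- function(seed, h = 16, w = 16) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

# mid-contrast textured luma plane (checkerboard with two gray levels)
textured_plane <- function(h = 32, w = 32, lo = 0.3, hi = 0.7, cell = 4) {
  u <- matrix(rep(seq_len(w), each = h), h, w)
  v <- matrix(rep(seq_len(h), w), h, w)
  ifelse(((u - 1) %/% cell + (v - 1) %/% cell) %% 2 == 0, lo, hi)
}
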