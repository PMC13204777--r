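# Independent brute-force oracles and small fixtures shared by the tests.
# The oracles deliberately use plain nested loops so they share no code
# with the implementation they check.

# direct 2-D convolution with replicate padding (flipped kernel)
conv2_oracle <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  rr <- nrow(w) %/% 2; rc <- ncol(w) %/% 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in seq_len(nrow(w))) {
        for (b in seq_len(ncol(w))) {
          ii <- min(max(i - (a - rr - 1L), 1L), nr)
          jj <- min(max(j - (b - rc - 1L), 1L), nc)
          acc <- acc + w[a, b] * x[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# direct box sum over a (2r+1)^2 window with replicate padding
box_sum_oracle <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in (i - r):(i + r)) {
        for (b in (j - r):(j + r)) {
          acc <- acc + m[min(max(a, 1L), nr), min(max(b, 1L), nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# direct spatio-temporal convolution with the full separable inhibition
# kernel W_I = W_SP * W_TP + W_SN * W_TN (replicate space, zero-padded time)
st_inhibition_oracle <- function(stack, wsp, wsn, wtp, wtn) {
  d <- dim(stack)
  L <- max(length(wtp), length(wtn))
  wtp <- c(wtp, rep(0, L - length(wtp)))
  wtn <- c(wtn, rep(0, L - length(wtn)))
  out <- array(0, dim = d)
  rr <- nrow(wsp) %/% 2
  for (t in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- 0
        for (a in seq_len(nrow(wsp))) {
          for (b in seq_len(ncol(wsp))) {
            ii <- min(max(i - (a - rr - 1L), 1L), d[1])
            jj <- min(max(j - (b - rr - 1L), 1L), d[2])
            for (l in seq_along(wtp)) {
              ts <- t - (l - 1L)
              if (ts >= 1L) {
                wk <- wsp[a, b] * wtp[l] + wsn[a, b] * wtn[l]
                acc <- acc + wk * stack[ii, jj, ts]
              }
            }
          }
        }
        out[i, j, t] <- acc
      }
    }
  }
  out
}

# small fast scene for end-to-end unit tests: 140 x 80 px, 15 frames,
# background drifting right, one pseudo-object, one independent mover
mini_scene <- function(seed = 1L, ...) {
  objects <- dplyr::bind_rows(
    object_spec("P", x = 25, y = 20, luminance = 0, velocity = 150,
                locked = TRUE),
    object_spec("D", x = 115, y = 55, luminance = 0, velocity = -150))
  scene_config(width = 140L, height = 80L, fps = 30, duration = 500,
               bg_velocity = 150, texture_scale = 8, seed = seed,
               objects = objects, ...)
}

expect_all_near <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)), tol)
}
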