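# Lobula stage: the feedback Hassenstein-Reichardt correlator producing
# the LC11 small-object response.

# Feedback kernel over strictly past lags 1..L: bin-integrated gamma
# (centred frame-period bins), renormalized to unit sum.
feedback_taps <- function(n4, tau4, length, dt = 1) {
  edges <- (seq_len(length + 1L) - 0.5) * dt
  g <- diff(stats::pgamma(edges, shape = n4 + 1, rate = n4 / tau4))
  g / sum(g)
}
#
# Each half-correlator multiplies an undelayed channel with the delayed
# opposite-polarity channel, after adding a gamma-filtered feedback of its
# own past output scaled by k. Feedback uses strictly past frames (lags
# >= 1), so each frame is an explicit function of the history and the
# recursion never becomes an implicit fixed-point equation.

#' Run the feedback correlator over a sequence
#'
#' Computes, frame by frame with persistent state,
#' \deqn{LC11_1(t) = (S_{Tm3} + k F_1)(S_{Tm1} + k F_1), \quad
#'       LC11_2(t) = (S_{Tm2} + k F_2)(S_{Mi1} + k F_2),}
#' where `F_i(t)` is the unit-sum gamma-weighted sum of that pathway's own
#' outputs at lags 1..L, and returns the signed response
#' `LC11 = LC11_1 - LC11_2`. The two pathways keep separate feedback
#' buffers. With `k = 0` the recursion reduces exactly to the feedforward
#' product correlator.
#'
#' @param medulla List with `H x W x T` arrays `tm3`, `tm2`, `mi1`, `tm1`
#'   (from the medulla stage).
#' @param k Feedback gain (default 0.01, >= 0).
#' @param n4,tau4 Feedback gamma order and time constant in frames
#'   (defaults 10 and 0.75, i.e. 25 ms at 30 FPS).
#' @param length Feedback kernel lags; default `ceiling(3 * tau4 / dt) + 2`
#'   capped at the sequence length.
#' @param dt Temporal sampling step per lag (frames).
#' @return List of `H x W x T` arrays `lc11_1`, `lc11_2` and the signed
#'   `lc11`.
#' @export
run_lc11 <- function(medulla, k = 0.01, n4 = 10, tau4 = 0.75,
                     length = NULL, dt = 1) {
  if (k < 0) abort("`k` must be non-negative.")
  d <- dim(medulla$tm3)
  if (!identical(d, dim(medulla$tm2)) || !identical(d, dim(medulla$mi1)) ||
      !identical(d, dim(medulla$tm1))) {
    abort("all medulla maps must share one shape.")
  }
  tt <- d[3]
  # the kernel support is independent of the sequence length so that
  # truncating a sequence reproduces its early frames bit for bit
  if (is.null(length)) length <- max(2L, ceiling(3 * tau4 / dt) + 2L)
  g <- feedback_taps(n4, tau4, length, dt)

  lc1 <- array(0, dim = d)
  lc2 <- array(0, dim = d)
  for (t in seq_len(tt)) {
    f1 <- matrix(0, d[1], d[2])
    f2 <- matrix(0, d[1], d[2])
    if (k > 0) {
      jmax <- min(length, t - 1L)
      for (j in seq_len(jmax)) {
        f1 <- f1 + g[j] * lc1[, , t - j]
        f2 <- f2 + g[j] * lc2[, , t - j]
      }
    }
    lc1[, , t] <- (medulla$tm3[, , t] + k * f1) * (medulla$tm1[, , t] + k * f1)
    lc2[, , t] <- (medulla$tm2[, , t] + k * f2) * (medulla$mi1[, , t] + k * f2)
  }
  list(lc11_1 = lc1, lc11_2 = lc2, lc11 = lc1 - lc2)
}

#' One correlator step
#'
#' Single-frame update of the feedback correlator given explicit ring
#' buffers of past pathway outputs (oldest to newest). Exposed for tests
#' and streaming use; [run_lc11()] is the sequence-level driver.
#'
#' @param tm3,tm2,mi1,tm1 `H x W` matrices for the current frame.
#' @param buf1,buf2 `H x W x n` arrays of past `lc11_1` / `lc11_2` maps
#'   (may have zero slices at the sequence start), or `NULL` for none.
#' @inheritParams run_lc11
#' @return List with `lc11` (signed map), `lc11_1`, `lc11_2`.
#' @export
lc11_step <- function(tm3, tm2, mi1, tm1, buf1 = NULL, buf2 = NULL,
                      k = 0.01, n4 = 10, tau4 = 0.75, length = NULL, dt = 1) {
  if (!all(dim(tm3) == dim(tm2)) || !all(dim(tm3) == dim(mi1)) ||
      !all(dim(tm3) == dim(tm1))) {
    abort("all input maps must share one shape.")
  }
  nbuf <- if (is.null(buf1)) 0L else dim(buf1)[3]
  if (is.null(length)) length <- max(2L, ceiling(3 * tau4 / dt) + 2L)
  g <- feedback_taps(n4, tau4, length, dt)
  f1 <- matrix(0, nrow(tm3), ncol(tm3))
  f2 <- matrix(0, nrow(tm3), ncol(tm3))
  if (k > 0 && nbuf > 0L) {
    for (j in seq_len(min(length, nbuf))) {
      f1 <- f1 + g[j] * buf1[, , nbuf - j + 1L]
      f2 <- f2 + g[j] * buf2[, , nbuf - j + 1L]
    }
  }
  a <- (tm3 + k * f1) * (tm1 + k * f1)
  b <- (tm2 + k * f2) * (mi1 + k * f2)
  list(lc11 = a - b, lc11_1 = a, lc11_2 = b)
}
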