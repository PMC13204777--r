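# Discrete realizations of the model's continuous kernels, plus the
# spatial/temporal convolution engines every stage shares.
#
# Conventions:
#  * 1-D kernels are causal: taps[1] is lag 0 (current frame), taps[j] lag j-1.
#  * 2-D kernels are square with odd side, centre at offset (0, 0).
#  * norm_policy records how the sampled taps were renormalized:
#    "unit_sum" (sum == 1), "zero_sum" (sum == 0) or "raw".

new_kernel1d <- function(taps, dt = 1, norm_policy = c("unit_sum", "zero_sum", "raw")) {
  norm_policy <- match.arg(norm_policy)
  taps <- as.numeric(taps)
  if (length(taps) < 1L || !all(is.finite(taps))) {
    abort("1-D kernel taps must be a non-empty finite numeric vector.")
  }
  structure(list(taps = taps, dt = dt, norm_policy = norm_policy),
            class = "msod_kernel1d")
}

new_kernel2d <- function(weights, norm_policy = c("unit_sum", "zero_sum", "raw")) {
  norm_policy <- match.arg(norm_policy)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights) || nrow(weights) %% 2L == 0L) {
    abort("2-D kernels must be square with odd side length.")
  }
  if (!all(is.finite(weights))) abort("2-D kernel weights must be finite.")
  structure(list(weights = weights, radius = (nrow(weights) - 1L) %/% 2L,
                 norm_policy = norm_policy),
            class = "msod_kernel2d")
}

#' @export
print.msod_kernel1d <- function(x, ...) {
  cat(sprintf("<msod 1-D kernel: %d taps, dt = %g, %s, sum = %.3g>\n",
              length(x$taps), x$dt, x$norm_policy, sum(x$taps)))
  invisible(x)
}

#' @export
print.msod_kernel2d <- function(x, ...) {
  cat(sprintf("<msod 2-D kernel: %dx%d, %s, sum = %.3g>\n",
              nrow(x$weights), ncol(x$weights), x$norm_policy, sum(x$weights)))
  invisible(x)
}

gaussian2d_raw <- function(sigma, radius) {
  off <- -radius:radius
  g1 <- exp(-off^2 / (2 * sigma^2))
  outer(g1, g1) / (2 * pi * sigma^2)
}

#' Discrete 2-D Gaussian kernel
#'
#' Samples the isotropic Gaussian \eqn{G_\sigma(x, y) =
#' \exp(-(x^2+y^2)/2\sigma^2) / 2\pi\sigma^2} at integer pixel offsets and
#' renormalizes the taps to unit sum, so spatial blurring preserves the
#' mean luminance of uniform regions.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Kernel half-width in pixels; must cover at least
#'   `ceiling(3 * sigma)` so less than 0.1% of the continuous mass is
#'   truncated. Default `ceiling(3 * sigma)`.
#' @return A 2-D kernel object with `(2 * radius + 1)^2` unit-sum weights.
#' @examples
#' k <- make_gaussian2d(1)
#' sum(k$weights)
#' @export
make_gaussian2d <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  if (radius < ceiling(3 * sigma)) {
    abort("`radius` must be at least ceiling(3 * sigma).")
  }
  w <- gaussian2d_raw(sigma, radius)
  new_kernel2d(w / sum(w), "unit_sum")
}

#' Difference-of-Gaussians kernel and its rectified halves
#'
#' Builds the centre-surround inhibition kernel `DOG = G_sigma2 - G_sigma3`
#' (each Gaussian unit-sum before subtraction, so the difference is exactly
#' zero-sum), together with its positive part `W_SP = max(DOG, 0)` (spatial
#' excitation) and negative part `W_SN = min(DOG, 0)` (spatial inhibition).
#' The narrow Gaussian must be narrower than the wide one so the centre is
#' excitatory.
#'
#' @param sigma2 Centre standard deviation in pixels (default 1.5).
#' @param sigma3 Surround standard deviation in pixels (default 2.0);
#'   must exceed `sigma2`.
#' @param radius Shared half-width; default `ceiling(3 * sigma3)`.
#' @return A list with 2-D kernel elements `dog`, `w_sp`, `w_sn`
#'   (`dog$weights == w_sp$weights + w_sn$weights`).
#' @export
make_dog <- function(sigma2 = 1.5, sigma3 = 2.0, radius = ceiling(3 * sigma3)) {
  if (!is.numeric(sigma2) || sigma2 <= 0 || !is.numeric(sigma3) || sigma3 <= 0) {
    abort("`sigma2` and `sigma3` must be positive.")
  }
  if (sigma3 <= sigma2) abort("`sigma3` must be strictly greater than `sigma2`.")
  g2 <- gaussian2d_raw(sigma2, radius); g2 <- g2 / sum(g2)
  g3 <- gaussian2d_raw(sigma3, radius); g3 <- g3 / sum(g3)
  dog <- g2 - g3
  list(dog  = new_kernel2d(dog, "zero_sum"),
       w_sp = new_kernel2d(pmax(dog, 0), "raw"),
       w_sn = new_kernel2d(pmin(dog, 0), "raw"))
}

#' Continuous temporal band-pass impulse response
#'
#' Evaluates \eqn{H(t) = (n_2!\,t^{n_1} - n_1!\,t^{n_2})
#' \exp(-t) / (n_1!\,n_2!)}: an early positive lobe (luminance-change
#' excitation) followed by a slow negative lobe, with \eqn{H(0) = 0} and
#' zero net area. Used directly by tests and by [make_bandpass()].
#'
#' @param t Time points (same unit as the sampling step).
#' @param n1,n2 Low/high time constants, `n2 > n1`.
#' @return `H(t)` at each `t`.
#' @export
bandpass_continuous <- function(t, n1 = 1, n2 = 6) {
  (factorial(n2) * t^n1 - factorial(n1) * t^n2) * exp(-t) /
    (factorial(n1) * factorial(n2))
}

#' Calibrated sampling step of the band-pass filter
#'
#' The filter's zero-crossing time is \eqn{t^* = (n_2!/n_1!)^{1/(n_2-n_1)}}
#' (its excitatory phase spans `[0, t*]`, the inhibitory phase about
#' `[t*, 4 t*]`). The calibrated step is `2 t*` filter time-units per
#' frame, which makes the discrete step response of [make_bandpass()] a
#' single-frame transient — the discrete realization of a consecutive-frame
#' luminance difference.
#'
#' @param n1,n2 Time constants, `n2 > n1`.
#' @return Time-units per frame.
#' @export
bandpass_step <- function(n1 = 1, n2 = 6) {
  2 * (factorial(n2) / factorial(n1))^(1 / (n2 - n1))
}

#' Discrete temporal band-pass kernel
#'
#' Integrates the band-pass impulse response ([bandpass_continuous()]) over
#' centred frame-period bins (`tap j` integrates `H` over
#' `[(j - 1/2) dt, (j + 1/2) dt]`, clipped at 0) and rescales the negative
#' taps so the discrete sum is exactly zero: a temporally constant input is
#' annihilated, a step input produces a transient confined to about one
#' frame at the calibrated `dt`, and the full inhibitory rebound is kept.
#'
#' @param n1,n2 Time constants, `n2 > n1` (defaults 1 and 6).
#' @param length Number of taps; must extend until `|H|` has decayed below
#'   1e-6 of its peak (8 lags suffice at the defaults).
#' @param dt Sampling step in filter time-units per lag; default the
#'   calibrated [bandpass_step()].
#' @return A zero-sum 1-D kernel with a positive lag-0 tap.
#' @export
make_bandpass <- function(n1 = 1, n2 = 6, length = 8L, dt = NULL) {
  if (!is.numeric(n1) || n1 <= 0 || !is.numeric(n2) || n2 <= 0) {
    abort("`n1` and `n2` must be positive.")
  }
  if (n2 <= n1) abort("`n2` must be strictly greater than `n1`.")
  if (is.null(dt)) dt <- bandpass_step(n1, n2)
  edges <- c(0, (seq_len(length) - 0.5) * dt)
  h <- vapply(seq_len(length), function(j) {
    stats::integrate(bandpass_continuous, edges[j], edges[j + 1],
                     n1 = n1, n2 = n2, rel.tol = 1e-12,
                     abs.tol = 1e-14)$value
  }, numeric(1))
  if (abs(h[length]) > 1e-6 * max(abs(h))) {
    abort("`length` too short: |H| has not decayed below 1e-6 of its peak.")
  }
  pos <- sum(h[h > 0])
  neg <- -sum(h[h < 0])
  if (pos > 0 && neg > 0) h[h < 0] <- h[h < 0] * (pos / neg)
  new_kernel1d(h, dt, "zero_sum")
}

#' Discrete exponential low-pass kernel
#'
#' Integrates \eqn{(1/\lambda) \exp(-t/\lambda)} over causal frame-period
#' bins, truncates, and renormalizes to unit sum. These are the temporal
#' excitatory/inhibitory
#' lobes paired with the rectified DoG halves in the lamina lateral
#' inhibition (fast lambda with the excitatory centre, slow lambda with the
#' inhibitory surround).
#'
#' @param lambda Time constant (> 0) in time units.
#' @param length Taps; default covers 99.9% of the continuous mass.
#' @param dt Sampling step per lag.
#' @return A unit-sum 1-D kernel with strictly decreasing taps.
#' @export
make_exp_lowpass <- function(lambda, length = NULL, dt = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    abort("`lambda` must be a single positive number.")
  }
  if (is.null(length)) length <- max(2L, ceiling(-lambda * log(0.001) / dt) + 1L)
  # forward bins keep the taps strictly decreasing (the monotone shape is
  # the point of this kernel); tap j integrates over [j dt, (j+1) dt]
  h <- diff(stats::pexp(0:length * dt, rate = 1 / lambda))
  new_kernel1d(h / sum(h), dt, "unit_sum")
}

#' Continuous gamma kernel
#'
#' Evaluates \eqn{\Gamma_{n,\tau}(t) = n^n t^n \exp(-n t / \tau) /
#' ((n-1)!\,\tau^{n+1})}, a delay kernel with unit integral and mode at
#' `t = tau`.
#'
#' @param t Time points.
#' @param n Order (integer >= 1); larger n concentrates the delay.
#' @param tau Time constant; the position of the peak.
#' @return Kernel values at `t`.
#' @export
gamma_continuous <- function(t, n, tau) {
  n^n * t^n * exp(-n * t / tau) / (factorial(n - 1) * tau^(n + 1))
}

#' Discrete gamma delay kernel
#'
#' Integrates the continuous gamma kernel ([gamma_continuous()]) over
#' centred frame-period bins (tap `j` integrates over
#' `[(j - 1/2) dt, (j + 1/2) dt]`, clipped at 0), truncates and
#' renormalizes to unit sum, so a temporally constant signal passes through
#' unchanged while transients are delayed by about `tau` — including
#' sub-sample `tau`, whose mass the bin integral splits between the nearest
#' lags instead of vanishing.
#'
#' @param n Order (integer >= 1).
#' @param tau Time constant (> 0) in time units.
#' @param length Taps; default covers `3 * tau` plus two lags (callers
#'   working on short sequences may cap it at the sequence length).
#' @param dt Sampling step per lag.
#' @return A unit-sum 1-D kernel.
#' @export
make_gamma <- function(n, tau, length = NULL, dt = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    abort("`tau` must be a single positive number.")
  }
  if (is.null(length)) length <- ceiling(3 * tau / dt) + 2L
  length <- max(2L, as.integer(length))
  # gamma_continuous is the gamma density with shape n + 1, rate n / tau
  edges <- c(0, (seq_len(length) - 0.5) * dt)
  h <- diff(stats::pgamma(edges, shape = n + 1, rate = n / tau))
  new_kernel1d(h / sum(h), dt, "unit_sum")
}

#' Spatial convolution with replicate padding
#'
#' "Same"-size 2-D convolution of a response map with a square kernel.
#' Borders use replicate padding (the nearest valid pixel), so unit-sum
#' kernels map constant frames to themselves everywhere, including edges.
#' Backed by a compiled direct convolution; tests verify agreement with a
#' pure-R nested-loop oracle to below 1e-9.
#'
#' @param map Numeric matrix (rows = y, columns = x).
#' @param kernel A 2-D kernel from [make_gaussian2d()], [make_dog()], etc.,
#'   or a plain square odd-sided numeric matrix.
#' @return Matrix of the same dimensions as `map`.
#' @export
convolve_spatial <- function(map, kernel) {
  w <- if (inherits(kernel, "msod_kernel2d")) kernel$weights else as.matrix(kernel)
  if (!is.matrix(map)) abort("`map` must be a matrix.")
  if (nrow(map) < nrow(w) || ncol(map) < ncol(w)) {
    abort("kernel is larger than the map.")
  }
  conv2_replicate_cpp(map, w)
}

#' Causal temporal convolution (current-frame output)
#'
#' Computes \eqn{\sum_{j \ge 0} k_j \, x_{t-j}} at the newest time point of
#' a history, using only present and past samples. Histories shorter than
#' the kernel are zero-padded at the start, matching the model's zero
#' initial state.
#'
#' @param history Past values oldest to newest: a numeric vector (one
#'   pixel) or a 3-D array with time as the last dimension.
#' @param kernel A 1-D kernel.
#' @return A scalar (vector history) or matrix (array history).
#' @export
convolve_temporal_causal <- function(history, kernel) {
  taps <- if (inherits(kernel, "msod_kernel1d")) kernel$taps else as.numeric(kernel)
  if (is.array(history) && length(dim(history)) == 3L) {
    d <- dim(history)
    out <- matrix(0, d[1], d[2])
    for (j in seq_along(taps)) {
      t_idx <- d[3] - (j - 1L)
      if (t_idx < 1L) break
      out <- out + taps[j] * history[, , t_idx]
    }
    out
  } else {
    x <- as.numeric(history)
    n <- length(x)
    acc <- 0
    for (j in seq_along(taps)) {
      t_idx <- n - (j - 1L)
      if (t_idx < 1L) break
      acc <- acc + taps[j] * x[t_idx]
    }
    acc
  }
}

#' Causal temporal filtering of a full frame stack
#'
#' Applies [convolve_temporal_causal()] at every frame of an `H x W x T`
#' stack (zero-padded start), returning the filtered stack. Implemented as
#' one banded matrix product so full-resolution sequences filter in
#' milliseconds.
#'
#' @param stack 3-D numeric array, time last.
#' @param kernel A 1-D kernel.
#' @return Array of the same dimensions.
#' @export
filter_temporal <- function(stack, kernel) {
  taps <- if (inherits(kernel, "msod_kernel1d")) kernel$taps else as.numeric(kernel)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L) abort("`stack` must be a 3-D array.")
  tt <- d[3]
  band <- matrix(0, tt, tt)
  for (t in seq_len(tt)) {
    jmax <- min(length(taps), t)
    band[t - seq_len(jmax) + 1L, t] <- taps[seq_len(jmax)]
  }
  out <- matrix(stack, ncol = tt) %*% band
  dim(out) <- d
  out
}
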