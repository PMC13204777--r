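test_that("Gaussian kernels are unit-sum, symmetric and isotropic", {
  for (sig in c(1, 1.5, 2)) {
    k <- make_gaussian2d(sig)
    w <- k$weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, w[rev(seq_len(nrow(w))), ], tolerance = 0)   # y flip
    expect_equal(w, w[, rev(seq_len(ncol(w)))], tolerance = 0)   # x flip
    expect_equal(w, t(w), tolerance = 0)                         # x <-> y
    c0 <- k$radius + 1L
    expect_equal(which(w == max(w), arr.ind = TRUE)[1, ], c(row = c0, col = c0))
  }
  expect_error(make_gaussian2d(-1), "positive")
  expect_error(make_gaussian2d(2, radius = 3), "radius")
})

test_that("Gaussian weight ratios follow the continuous profile", {
  sig <- 1
  k <- make_gaussian2d(sig)
  c0 <- k$radius + 1L
  # ratio of centre to a 1-px offset is exp(1 / (2 sigma^2)), unaffected by
  # the unit-sum renormalization
  expect_equal(k$weights[c0, c0] / k$weights[c0, c0 + 1L],
               exp(1 / (2 * sig^2)), tolerance = 1e-12)
})

test_that("DoG kernel is zero-sum with rectified halves that reassemble", {
  dogs <- make_dog(1.5, 2.0)
  expect_lt(abs(sum(dogs$dog$weights)), 1e-9)
  expect_true(all(dogs$w_sp$weights >= 0))
  expect_true(all(dogs$w_sn$weights <= 0))
  expect_equal(dogs$dog$weights, dogs$w_sp$weights + dogs$w_sn$weights)
  c0 <- dogs$dog$radius + 1L
  expect_gt(dogs$dog$weights[c0, c0], 0)  # narrow Gaussian wins at centre
  expect_error(make_dog(2.0, 1.5), "greater")
})

test_that("continuous band-pass has H(0) = 0, zero area, sign change at (n2!/n1!)^(1/(n2-n1))", {
  expect_identical(bandpass_continuous(0), 0)
  expect_lt(abs(stats::integrate(bandpass_continuous, 0, 60,
                                 rel.tol = 1e-12)$value), 1e-9)
  tzero <- 720^(1 / 5)
  tt <- seq(0.01, 20, by = 0.001)
  h <- bandpass_continuous(tt)
  crossings <- tt[which(diff(sign(h)) != 0)]
  expect_length(crossings, 1L)
  expect_equal(crossings[1], tzero, tolerance = 2e-3)
  expect_true(all(h[tt < tzero - 1e-3] > 0))
})

test_that("discrete band-pass is zero-sum with a one-frame step transient", {
  k <- make_bandpass()
  expect_lt(abs(sum(k$taps)), 1e-9)
  expect_gt(k$taps[1], 0)
  # step response after the first frame is a small residue of the tail
  step <- cumsum(k$taps)
  expect_lt(max(abs(step[-1])) / step[1], 0.12)
  expect_error(make_bandpass(6, 1), "greater")
  expect_error(make_bandpass(length = 2L), "decayed")
})

test_that("exponential kernels are unit-sum, decreasing, ordered by lambda", {
  k3 <- make_exp_lowpass(3)
  k9 <- make_exp_lowpass(9)
  for (k in list(k3, k9)) {
    expect_equal(sum(k$taps), 1, tolerance = 1e-12)
    expect_true(all(diff(k$taps) < 0))
  }
  # the faster kernel concentrates more mass at lag 0
  expect_gt(k3$taps[1], k9$taps[1])
  expect_error(make_exp_lowpass(0), "positive")
})

test_that("gamma kernel integrates to one and peaks at tau (continuous and discrete)", {
  for (case in list(c(5, 25), c(10, 25), c(3, 4))) {
    n <- case[1]; tau <- case[2]
    expect_equal(stats::integrate(gamma_continuous, 0, 40 * tau, n = n,
                                  tau = tau, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-6)
    opt <- stats::optimize(gamma_continuous, c(0, 5 * tau), n = n, tau = tau,
                           maximum = TRUE)
    expect_equal(opt$maximum, tau, tolerance = 1e-3 * tau)
  }
  k <- make_gamma(5, 25, length = 120)
  expect_equal(sum(k$taps), 1, tolerance = 1e-12)
  expect_equal(which.max(k$taps) - 1L, 25L)
  expect_error(make_gamma(0, 25), "positive integer")
  expect_error(make_gamma(5, -1), "positive")
})

test_that("default truncation keeps at least 99.9% of continuous mass", {
  # exponential: mass kept at the default length
  for (lam in c(3, 9)) {
    k <- make_exp_lowpass(lam)
    kept <- stats::pexp(length(k$taps) * k$dt, rate = 1 / lam)
    expect_gt(kept, 0.999)
  }
  # gamma at the pipeline's delay scale
  k <- make_gamma(5, 0.75)
  kept <- stats::pgamma((length(k$taps) - 0.5) * k$dt, shape = 6, rate = 5 / 0.75)
  expect_gt(kept, 0.999)
  # band-pass |mass| beyond the default support is negligible
  tail_mass <- stats::integrate(function(t) abs(bandpass_continuous(t)),
                                8 * bandpass_step(), 200,
                                rel.tol = 1e-9)$value
  total_mass <- stats::integrate(function(t) abs(bandpass_continuous(t)),
                                 0, 200, rel.tol = 1e-9)$value
  expect_lt(tail_mass / total_mass, 0.001)
})

test_that("spatial convolution: constant, impulse and error cases", {
  g <- make_gaussian2d(1)
  cmap <- matrix(7.5, 20, 20)
  expect_all_near(convolve_spatial(cmap, g), cmap, 1e-12)

  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- convolve_spatial(imp, g)
  expect_equal(out[(8 - 3):(8 + 3), (8 - 3):(8 + 3)], g$weights,
               tolerance = 1e-12)

  expect_error(convolve_spatial(matrix(0, 3, 3), make_gaussian2d(2)), "larger")
})

test_that("spatial convolution matches the nested-loop oracle on random maps", {
  set.seed(42)
  for (rep in 1:5) {
    x <- matrix(rnorm(18 * 22), 18, 22)
    w <- matrix(rnorm(25), 5, 5)
    expect_all_near(convolve_spatial(x, w), conv2_oracle(x, w), 1e-9)
  }
})

test_that("causal temporal convolution: zeros, constants, sifting", {
  k <- make_exp_lowpass(3, length = 6)
  expect_identical(convolve_temporal_causal(rep(0, 10), k), 0)
  expect_equal(convolve_temporal_causal(rep(4.2, 10), k), 4.2,
               tolerance = 1e-12)
  for (j in 0:3) {
    h <- rep(0, 8); h[8 - j] <- 1  # impulse at lag j
    expect_equal(convolve_temporal_causal(h, k), k$taps[j + 1],
                 tolerance = 1e-15)
  }
  # array form agrees with per-pixel form at the last frame
  st <- array(rnorm(4 * 5 * 7), c(4, 5, 7))
  out <- convolve_temporal_causal(st, k)
  expect_equal(out[2, 3], convolve_temporal_causal(st[2, 3, ], k),
               tolerance = 1e-15)
})

test_that("filter_temporal equals frame-by-frame causal convolution", {
  k <- make_gamma(3, 2, length = 5)
  st <- array(rnorm(3 * 4 * 9), c(3, 4, 9))
  filt <- filter_temporal(st, k)
  for (t in c(1, 4, 9)) {
    expect_all_near(filt[, , t],
                    convolve_temporal_causal(st[, , seq_len(t), drop = FALSE], k),
                    1e-12)
  }
})
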