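# Lamina stage: temporal band-pass (large monopolar cells), spatio-temporal
# lateral inhibition, and decomposition into rectified ON/OFF channels.

#' Temporal band-pass filtering of the retina output
#'
#' Causal convolution of the photoreceptor signal `P` with the zero-sum
#' band-pass kernel: static scenes decay to zero after the start-up
#' transient; luminance increases give an early positive response,
#' decreases a negative one.
#'
#' @param P `H x W x T` array from [retina_blur()].
#' @param kernel Band-pass kernel; default [make_bandpass()] defaults.
#' @return `H x W x T` array `LMC`.
#' @export
temporal_bandpass <- function(P, kernel = make_bandpass()) {
  filter_temporal(P, kernel)
}

#' Spatio-temporal lateral inhibition
#'
#' Surround suppression of the band-passed signal. The inhibition kernel is
#' separable into a fast excitatory pair (rectified-positive DoG centre
#' `W_SP` with a fast exponential `W_TP`) and a slow inhibitory pair
#' (rectified-negative DoG surround `W_SN` with a slow exponential `W_TN`):
#'
#' `LMCI(t) = conv2(filter(LMC, W_TP), W_SP) + conv2(filter(LMC, W_TN), W_SN)`
#'
#' A spatially uniform, temporally constant input is annihilated exactly
#' (both temporal kernels are unit-sum and the DoG halves cancel), and the
#' operation is linear in its input.
#'
#' @param LMC `H x W x T` array from [temporal_bandpass()].
#' @param sigma2,sigma3 Centre/surround DoG standard deviations (1.5, 2.0).
#' @param lambda1,lambda2 Fast/slow exponential time constants (3, 9),
#'   `lambda2 > lambda1`, in the same time-units as the band-pass.
#' @param dt Time-units per lag; default the calibrated [bandpass_step()]
#'   shared with the band-pass filter.
#' @return `H x W x T` array `LMCI`.
#' @export
lateral_inhibition <- function(LMC, sigma2 = 1.5, sigma3 = 2.0,
                               lambda1 = 3, lambda2 = 9, dt = NULL) {
  if (is.null(dt)) dt <- bandpass_step()
  dogs <- make_dog(sigma2, sigma3)
  wtp <- make_exp_lowpass(lambda1, dt = dt)
  wtn <- make_exp_lowpass(lambda2, dt = dt)
  fast <- filter_temporal(LMC, wtp)
  slow <- filter_temporal(LMC, wtn)
  d <- dim(LMC)
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) {
    out[, , t] <- convolve_spatial(fast[, , t], dogs$w_sp) +
      convolve_spatial(slow[, , t], dogs$w_sn)
  }
  out
}

#' ON/OFF decomposition
#'
#' Half-wave rectifies the inhibited signal into the parallel channels
#' carrying luminance increases (`S_ON = max(LMCI, 0)`) and decreases
#' (`S_OFF = max(-LMCI, 0)`). `S_ON - S_OFF` reconstructs the input and the
#' two channels have disjoint support.
#'
#' @param LMCI Array (any shape).
#' @return List with non-negative arrays `s_on` and `s_off`.
#' @export
split_on_off <- function(LMCI) {
  list(s_on = pmax(LMCI, 0), s_off = pmax(-LMCI, 0))
}

# Full lamina stage; internal pipeline wiring.
lamina_stage <- function(P, params) {
  dt <- resolve_bp_step(params)
  len <- if (is.null(params$bp_length)) max(8L, ceiling(31 / dt)) else params$bp_length
  LMC <- temporal_bandpass(P, make_bandpass(params$n1, params$n2,
                                            length = len, dt = dt))
  LMCI <- lateral_inhibition(LMC, params$sigma2, params$sigma3,
                             params$lambda1, params$lambda2, dt = dt)
  c(list(lmc = LMC, lmci = LMCI), split_on_off(LMCI))
}
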