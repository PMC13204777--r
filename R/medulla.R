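# Medulla stage: second-order lateral inhibition (Tm3/Tm2) giving size
# selectivity, and gamma-kernel delays producing the Mi1/Tm1 signals the
# correlator pairs against.

#' Second-order lateral inhibition
#'
#' Convolves an ON or OFF channel with the weighted inhibition kernel
#' `W1 = A * max(DOG, 0) + B * min(DOG, 0)` and rectifies the result. With
#' `B > A` the kernel has negative total mass, so extended uniform activity
#' is suppressed while isolated small blobs survive — the origin of the
#' model's small-size selectivity.
#'
#' @param S `H x W` matrix or `H x W x T` array (an ON or OFF channel).
#' @param A,B Centre/surround gains (defaults 1 and 3).
#' @param sigma2,sigma3 DoG standard deviations (defaults 1.5, 2.0).
#' @return Non-negative map/stack of the same shape.
#' @export
second_order_inhibition <- function(S, A = 1, B = 3, sigma2 = 1.5, sigma3 = 2.0) {
  dogs <- make_dog(sigma2, sigma3)
  w1 <- A * dogs$w_sp$weights + B * dogs$w_sn$weights
  if (is.matrix(S)) return(pmax(conv2_replicate_cpp(S, w1), 0))
  d <- dim(S)
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) out[, , t] <- pmax(conv2_replicate_cpp(S[, , t], w1), 0)
  out
}

#' Gamma-kernel temporal delay
#'
#' Causal convolution with a unit-sum gamma kernel: a constant input passes
#' through unchanged, a transient is delayed by about `tau` (the kernel's
#' mode). The delayed Tm3 models Mi1 and the delayed Tm2 models Tm1.
#'
#' @param S `H x W x T` array.
#' @param n Gamma order (default 5).
#' @param tau Gamma time constant in frames (default 0.75, i.e. 25 ms at
#'   30 FPS).
#' @param length Kernel taps; default `ceiling(3 * tau / dt) + 2` capped at
#'   the sequence length.
#' @param dt Temporal sampling step per lag (frames).
#' @return Delayed stack of the same shape.
#' @export
gamma_delay <- function(S, n = 5, tau = 0.75, length = NULL, dt = 1) {
  if (is.null(length)) length <- ceiling(3 * tau / dt) + 2L
  filter_temporal(S, make_gamma(n, tau, length = length, dt = dt))
}

# Full medulla stage; internal pipeline wiring. The delay time constant is
# converted from the configured unit (ms by default) into frames.
medulla_stage <- function(s_on, s_off, params) {
  tau_f <- resolve_tau_frames(params, params$tau3)
  tm3 <- second_order_inhibition(s_on, params$A, params$B,
                                 params$sigma2, params$sigma3)
  tm2 <- second_order_inhibition(s_off, params$A, params$B,
                                 params$sigma2, params$sigma3)
  list(tm3 = tm3, tm2 = tm2,
       mi1 = gamma_delay(tm3, params$n3, tau_f),
       tm1 = gamma_delay(tm2, params$n3, tau_f))
}
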