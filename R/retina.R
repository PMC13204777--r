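# Retina stage: grayscale conversion and Gaussian blur producing the
# photoreceptor signal P(x, y, t) that both downstream branches consume.

#' Convert an RGB frame to grayscale luminance
#'
#' Standard luma weighting `0.2989 R + 0.5870 G + 0.1140 B` per pixel.
#' Grayscale input (a matrix, or an array with one channel) passes through
#' unchanged; the result is kept as floating point to avoid re-quantization
#' before filtering.
#'
#' @param frame `H x W x 3` array (channels R, G, B in \[0, 255\]),
#'   `H x W x 1` array, or an `H x W` matrix.
#' @return `H x W` numeric matrix.
#' @export
rgb_to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 1L) {
    return(matrix(frame[, , 1L], d[1], d[2]))
  }
  if (length(d) != 3L || d[3] != 3L) {
    abort("`frame` must be a matrix or an H x W x {1,3} array.")
  }
  matrix(0.2989 * frame[, , 1L] + 0.5870 * frame[, , 2L] +
           0.1140 * frame[, , 3L], d[1], d[2])
}

#' Retina blur
#'
#' Convolves every frame independently with a unit-sum Gaussian of standard
#' deviation `sigma1` (no temporal mixing), emulating the optical blur of
#' the compound eye. This output feeds both the motion branch (band-pass,
#' ON/OFF, correlator) and the contrast branch (centre/surround pooling).
#'
#' @param frames An `msod_frames` object or `H x W x T` array.
#' @param sigma1 Blur standard deviation in pixels (default 1).
#' @return `H x W x T` array of blurred luminance `P`.
#' @export
retina_blur <- function(frames, sigma1 = 1) {
  stack <- if (inherits(frames, "msod_frames")) frames$frames else frames
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) {
    abort("`frames` must contain at least one frame.")
  }
  g <- make_gaussian2d(sigma1)
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) out[, , t] <- convolve_spatial(stack[, , t], g)
  out
}
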