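# Pipeline orchestration: parameters, the full detector, and inspection
# helpers.

#' Model parameters
#'
#' All tunable constants of the detector with their reference defaults.
#' Two time bases are in play. The band-pass filter (and the lamina
#' exponentials, which share its base) is discretized at `bp_step` filter
#' time-units per frame; the default calibration [bandpass_step()] makes
#' its discrete step response a single-frame transient, realizing the
#' consecutive-frame-difference behaviour the filter models. The
#' physiological delay constants `tau3` and `tau4` are interpreted in the
#' unit selected by `time_unit`: `"ms"` (default) converts them to frames
#' via `fps` (25 ms is 0.75 frames at 30 FPS), `"frame"` takes them
#' literally.
#'
#' @param sigma1 Retina blur standard deviation, px.
#' @param n1,n2 Band-pass time constants (`n2 > n1`).
#' @param bp_length Band-pass taps; `NULL` = enough for full decay.
#' @param bp_step Filter time-units per frame for the band-pass and the
#'   lamina exponentials; `NULL` = the calibrated [bandpass_step()].
#' @param sigma2,sigma3 Lamina DoG centre/surround standard deviations, px.
#' @param lambda1,lambda2 Lamina temporal excitatory/inhibitory constants
#'   (band-pass time-units).
#' @param psi,pi_win Contrast centre and outer window sides, px (odd).
#' @param A,B Medulla inhibition centre/surround gains.
#' @param n3,tau3 Medulla delay gamma order and time constant.
#' @param n4,tau4 Lobula feedback gamma order and time constant.
#' @param k Lobula feedback gain.
#' @param th Detection threshold on the per-frame normalized response.
#' @param norm_top Per-frame normalizer: number of largest positive
#'   response values averaged into the normalization scale (default 100);
#'   `NULL` normalizes by the frame maximum.
#' @param th2 Contrast-SD confirmation threshold, gray levels.
#' @param link_radius Trajectory link radius, px per frame.
#' @param nms Non-maximum-suppression window side, px.
#' @param gap_max Allowed missed frames in a trajectory (default 1).
#' @param min_length Minimum trajectory length before confirmation.
#' @param latency Intrinsic correlator latency in frames (default 1): the
#'   cover-then-reveal event that drives the response completes one frame
#'   after the object leaves a pixel, so detections at frame `t` are
#'   assigned to event frame `t - latency`.
#' @param warmup Frames excluded from evaluation (filter start-up).
#' @param time_unit Unit of `tau3`/`tau4`: `"ms"` or `"frame"`.
#' @param fps Frame rate used for the ms-to-frame conversion.
#' @param use_abs Threshold `|LC11|` rather than its positive part.
#' @return An `msod_params` list.
#' @export
msod_params <- function(sigma1 = 1, n1 = 1, n2 = 6, bp_length = NULL,
                        bp_step = NULL,
                        sigma2 = 1.5, sigma3 = 2.0, lambda1 = 3, lambda2 = 9,
                        psi = 11L, pi_win = 31L, A = 1, B = 3,
                        n3 = 5, tau3 = 25, n4 = 10, tau4 = 25, k = 0.01,
                        th = 0.2, norm_top = 100L, th2 = 4.0,
                        link_radius = 10, nms = 5L,
                        gap_max = 1L, min_length = 3L, latency = 1L,
                        warmup = 8L, time_unit = c("ms", "frame"), fps = 30,
                        use_abs = FALSE) {
  time_unit <- match.arg(time_unit)
  if (n2 <= n1) abort("`n2` must exceed `n1`.")
  if (sigma3 <= sigma2) abort("`sigma3` must exceed `sigma2`.")
  if (lambda2 <= lambda1) abort("`lambda2` must exceed `lambda1`.")
  p <- list(sigma1 = sigma1, n1 = n1, n2 = n2,
            bp_length = if (is.null(bp_length)) NULL else as.integer(bp_length),
            bp_step = bp_step,
            sigma2 = sigma2, sigma3 = sigma3, lambda1 = lambda1,
            lambda2 = lambda2, psi = as.integer(psi),
            pi_win = as.integer(pi_win), A = A, B = B, n3 = n3, tau3 = tau3,
            n4 = n4, tau4 = tau4, k = k, th = th, norm_top = norm_top,
            th2 = th2,
            link_radius = link_radius, nms = as.integer(nms),
            gap_max = as.integer(gap_max), min_length = as.integer(min_length),
            latency = as.integer(latency),
            warmup = as.integer(warmup), time_unit = time_unit, fps = fps,
            use_abs = isTRUE(use_abs))
  structure(p, class = "msod_params")
}

# filter time-units per frame for the band-pass / lamina exponentials
resolve_bp_step <- function(params) {
  if (!is.null(params$bp_step)) return(params$bp_step)
  if (params$time_unit == "frame") 1 else bandpass_step(params$n1, params$n2)
}

# delay/feedback time constants in frames
resolve_tau_frames <- function(params, tau) {
  if (params$time_unit == "ms") tau * params$fps / 1000 else tau
}

#' @export
print.msod_params <- function(x, ...) {
  cat("<msod parameters>\n")
  cat(sprintf("  retina: sigma1 = %g | band-pass: n1 = %g, n2 = %g (step %.3f units/frame)\n",
              x$sigma1, x$n1, x$n2, resolve_bp_step(x)))
  cat(sprintf("  inhibition: sigma2 = %g, sigma3 = %g, lambda1 = %g, lambda2 = %g, A = %g, B = %g\n",
              x$sigma2, x$sigma3, x$lambda1, x$lambda2, x$A, x$B))
  cat(sprintf("  contrast windows: %d / %d px | delays: gamma(%g, %g %s); feedback gamma(%g, %g %s), k = %g\n",
              x$psi, x$pi_win, x$n3, x$tau3, x$time_unit, x$n4, x$tau4,
              x$time_unit, x$k))
  cat(sprintf("  thresholds: th = %g, th2 = %g | link r = %g px, nms = %d, min length = %d, latency = %d, warm-up = %d\n",
              x$th, x$th2, x$link_radius, x$nms, x$min_length, x$latency,
              x$warmup))
  invisible(x)
}

#' Run the full small-object detector
#'
#' Executes the four stages in order — retina blur, lamina band-pass +
#' lateral inhibition + ON/OFF split (with the parallel contrast branch),
#' medulla second-order inhibition + delays, lobula feedback correlator —
#' then thresholds the LC11 response, links trajectories, samples contrast
#' along them and confirms trajectories whose contrast standard deviation
#' exceeds the threshold. The run is deterministic: identical input and
#' parameters give bit-identical output.
#'
#' @param frames An `msod_frames` object (see [render_sequence()]), or an
#'   `H x W x T` gray array, or `H x W x T x 3` RGB array.
#' @param params An [msod_params()] list.
#' @param keep_stages Retain every intermediate response stack (for
#'   [profile_row()] and stage dumps); roughly 13 stacks of the input size.
#' @return An `msod_result` with elements `detections` (tibble: `frame`,
#'   `x`, `y`, `score`, `norm_score`, `trajectory`, `ct`, `n_points`,
#'   `sd_ct`, `confirmed`), `lc11`, `t1`, `dims`, `fps`, `params`, and
#'   `stages` (list or `NULL`).
#' @export
msod_detect <- function(frames, params = msod_params(), keep_stages = FALSE) {
  if (inherits(frames, "msod_frames")) {
    stack <- frames$frames; fps <- frames$fps
  } else {
    stack <- frames; fps <- params$fps
  }
  d <- dim(stack)
  if (length(d) == 4L) {  # RGB sequence
    gray <- array(0, dim = d[1:3])
    for (t in seq_len(d[3])) gray[, , t] <- rgb_to_gray(stack[, , t, ])
    stack <- gray; d <- dim(stack)
  }
  if (length(d) != 3L) abort("`frames` must be H x W x T (or H x W x T x 3).")
  params$fps <- fps

  P <- retina_blur(stack, params$sigma1)
  lam <- lamina_stage(P, params)
  t1 <- local_contrast(P, params$psi, params$pi_win)
  med <- medulla_stage(lam$s_on, lam$s_off, params)
  lob <- run_lc11(med, k = params$k, n4 = params$n4,
                  tau4 = resolve_tau_frames(params, params$tau4))

  det <- threshold_detections(lob$lc11, th = params$th, nms = params$nms,
                              use_abs = params$use_abs,
                              norm_top = params$norm_top)
  # assign detections to their event frame (intrinsic correlator latency)
  if (params$latency > 0L && nrow(det) > 0L) {
    det$frame <- det$frame - params$latency
    det <- det[det$frame >= 0L, , drop = FALSE]
  }
  det <- det |>
    link_trajectories(link_radius = params$link_radius,
                      gap_max = params$gap_max) |>
    attach_contrast(t1) |>
    contrast_sd() |>
    confirm_objects(th2 = params$th2, min_length = params$min_length)

  stages <- NULL
  if (keep_stages) {
    stages <- list(P = P, LMC = lam$lmc, LMCI = lam$lmci, S_ON = lam$s_on,
                   S_OFF = lam$s_off, T1 = t1, Tm3 = med$tm3, Tm2 = med$tm2,
                   Mi1 = med$mi1, Tm1 = med$tm1, LC11_1 = lob$lc11_1,
                   LC11_2 = lob$lc11_2, LC11 = lob$lc11)
  }
  structure(list(detections = det, lc11 = lob$lc11, t1 = t1, dims = d,
                 fps = fps, params = params, stages = stages),
            class = "msod_result")
}

#' @export
print.msod_result <- function(x, ...) {
  det <- x$detections
  cat(sprintf("<msod result: %d x %d px, %d frames>\n",
              x$dims[2], x$dims[1], x$dims[3]))
  cat(sprintf("  %d detections in %d trajectories; %d confirmed points in %d trajectories\n",
              nrow(det), length(unique(det$trajectory)),
              sum(det$confirmed), length(unique(det$trajectory[det$confirmed]))))
  invisible(x)
}

#' Cross-section profiles of the retained stages
#'
#' Extracts the row `y0` of every retained response stack at frame `t0`,
#' the standard way of visualizing how each stage transforms the signal
#' along the motion axis.
#'
#' @param result An `msod_result` run with `keep_stages = TRUE`.
#' @param y0 Row (0-based).
#' @param t0 Frame (0-based).
#' @return Tibble with columns `stage`, `x`, `value`.
#' @export
profile_row <- function(result, y0, t0) {
  stopifnot(inherits(result, "msod_result"))
  if (is.null(result$stages)) {
    abort("stage stacks were not retained; rerun msod_detect() with keep_stages = TRUE.")
  }
  d <- result$dims
  if (y0 < 0 || y0 >= d[1] || t0 < 0 || t0 >= d[3]) {
    abort("`y0` or `t0` out of range.")
  }
  purrr::imap_dfr(result$stages, function(stack, name) {
    tibble::tibble(stage = name, x = seq_len(d[2]) - 1L,
                   value = stack[y0 + 1L, , t0 + 1L])
  })
}

#' @export
tidy.msod_result <- function(x, ...) x$detections

#' @export
glance.msod_result <- function(x, ...) {
  det <- x$detections
  tibble::tibble(n_frames = x$dims[3], height = x$dims[1], width = x$dims[2],
                 n_detections = nrow(det),
                 n_trajectories = length(unique(det$trajectory)),
                 n_confirmed = sum(det$confirmed),
                 n_confirmed_trajectories =
                   length(unique(det$trajectory[det$confirmed])),
                 th = x$params$th, th2 = x$params$th2)
}

#' @export
glance.msod_eval <- function(x, ...) x

#' @export
tidy.msod_eval <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
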