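# Evaluation of detector output against ground truth: frame-level
# detection rate (5-px rule), pixel-level precision/recall/F1 on stamped
# object boxes, and the response-quality summaries SNR and VN.

stamp_boxes <- function(dims, tbl, dilate = 0L) {
  mask <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(tbl))) {
    t <- tbl$frame[i] + 1L
    w <- tbl$width[i] + 2L * dilate; h <- tbl$height[i] + 2L * dilate
    x0 <- round(tbl$x[i]) - floor((w - 1) / 2); x1 <- x0 + w - 1L
    y0 <- round(tbl$y[i]) - floor((h - 1) / 2); y1 <- y0 + h - 1L
    xs <- max(0L, x0):min(dims[2] - 1L, x1)
    ys <- max(0L, y0):min(dims[1] - 1L, y1)
    if (length(xs) > 0L && length(ys) > 0L && t >= 1L && t <= dims[3]) {
      mask[ys + 1L, xs + 1L, t] <- TRUE
    }
  }
  mask
}

#' Frame-level detection rate
#'
#' Fraction of evaluated frames (after the warm-up) in which at least one
#' confirmed detection lies within `tol` pixels (Euclidean) of the true
#' target centre. Only non-pseudo ground-truth objects count as targets.
#'
#' @param detections Tibble with `frame`, `x`, `y` and (optionally)
#'   `confirmed`; when present, only confirmed rows are used.
#' @param truth Ground-truth tibble from [render_sequence()].
#' @param tol Match radius in pixels (default 5).
#' @param warmup Number of initial frames excluded (default 8).
#' @param last_frame Last evaluated frame (default all); the pipeline uses
#'   `T - 1 - latency` since later events cannot be observed.
#' @return Detection rate in \[0, 1\].
#' @export
detection_rate <- function(detections, truth, tol = 5, warmup = 8L,
                           last_frame = Inf) {
  targets <- truth[!truth$is_pseudo & truth$frame >= warmup &
                     truth$frame <= last_frame, , drop = FALSE]
  if (nrow(targets) == 0L) abort("ground truth contains no evaluable target frames.")
  if ("confirmed" %in% names(detections)) {
    detections <- detections[detections$confirmed, , drop = FALSE]
  }
  frames <- unique(targets$frame)
  hit <- vapply(frames, function(f) {
    tr <- targets[targets$frame == f, ]
    de <- detections[detections$frame == f, ]
    if (nrow(de) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(tr)), function(i) {
      any(sqrt((de$x - tr$x[i])^2 + (de$y - tr$y[i])^2) <= tol)
    }, logical(1)))
  }, logical(1))
  mean(hit)
}

#' Pixel-level precision, recall and F1
#'
#' Stamps object-sized boxes at the detections and at the true target
#' positions, then counts pixels: `Pr = TP / (TP + FP)`,
#' `Rc = TP / (TP + FN)`, `F1 = 2 Pr Rc / (Pr + Rc)`. Empty predictions
#' give `Pr = 0` by convention; pseudo-objects belong to the background in
#' the truth masks. Warm-up frames are excluded from the counts.
#'
#' @inheritParams detection_rate
#' @param dims `c(H, W, T)` of the evaluated sequence.
#' @param box `c(width, height)` of the stamped prediction boxes; default
#'   the true target size.
#' @return One-row tibble with `pr`, `rc`, `f1`, `tp`, `fp`, `fn`, `tn`.
#' @export
pixel_prf <- function(detections, truth, dims, box = NULL, warmup = 8L,
                      last_frame = Inf) {
  targets <- truth[!truth$is_pseudo, , drop = FALSE]
  if ("confirmed" %in% names(detections)) {
    detections <- detections[detections$confirmed, , drop = FALSE]
  }
  if (is.null(box)) {
    box <- if (nrow(targets) > 0L) c(targets$width[1], targets$height[1]) else c(5L, 5L)
  }
  pred_tbl <- tibble::tibble(frame = detections$frame, x = detections$x,
                             y = detections$y, width = box[1], height = box[2])
  pred <- stamp_boxes(dims, pred_tbl)
  tr <- stamp_boxes(dims, targets)
  f0 <- seq_len(dims[3]) - 1L
  keep <- f0 >= warmup & f0 <= last_frame
  pred <- pred[, , keep, drop = FALSE]
  tr <- tr[, , keep, drop = FALSE]
  tp <- sum(pred & tr); fp <- sum(pred & !tr)
  fn <- sum(!pred & tr); tn <- sum(!pred & !tr)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  tibble::tibble(pr = pr, rc = rc, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Response signal-to-noise ratio and visual noise
#'
#' Output-quality summaries of a non-negative response stack against the
#' ground truth. `SNR` is the mean over evaluated frames of the peak
#' response inside the `tol`-dilated true target region divided by the RMS
#' response outside it; `VN` is the percentage of total response energy
#' (sum of absolute responses) lying outside the target regions. These
#' definitions are house conventions (the quantities have no canonical
#' formula); use them to compare stages of one pipeline, not across
#' publications. An all-zero response returns `SNR = 0`, `VN = 0`.
#'
#' @param response `H x W x T` array; its positive part is used.
#' @inheritParams detection_rate
#' @return One-row tibble with `snr` (linear ratio) and `vn` (percent).
#' @export
snr_vn <- function(response, truth, tol = 5, warmup = 8L, last_frame = Inf) {
  d <- dim(response)
  resp <- pmax(response, 0)
  targets <- truth[!truth$is_pseudo, , drop = FALSE]
  inside <- stamp_boxes(d, targets, dilate = as.integer(tol))
  f0 <- seq_len(d[3]) - 1L
  keep <- which(f0 >= warmup & f0 <= last_frame)
  tot_in <- 0; tot_out <- 0; ratios <- numeric(0)
  for (t in keep) {
    r <- resp[, , t]; m <- inside[, , t]
    tot_in <- tot_in + sum(r[m]); tot_out <- tot_out + sum(r[!m])
    if (any(m)) {
      peak <- max(r[m])
      rms <- sqrt(mean(r[!m]^2))
      if (rms > 0) ratios <- c(ratios, peak / rms)
    }
  }
  total <- tot_in + tot_out
  tibble::tibble(snr = if (length(ratios) > 0) mean(ratios) else 0,
                 vn = if (total > 0) 100 * tot_out / total else 0)
}

#' Score a pipeline result against ground truth
#'
#' Computes the full evaluation report for one sequence: detection rate,
#' pixel precision/recall/F1 on the confirmed output, and SNR/VN of both
#' the raw LC11 response and the confirmed output (confirmed detections
#' stamped as unit-height boxes).
#'
#' @param result An `msod_result` from [msod_detect()].
#' @param truth Ground-truth tibble from [render_sequence()].
#' @param tol Match radius / dilation in pixels (default 5).
#' @param warmup Frames excluded from all metrics; default the result's
#'   parameter value.
#' @return A one-row `msod_eval` tibble with columns `dr`, `pr`, `rc`,
#'   `f1`, `tp`, `fp`, `fn`, `tn`, `snr_raw`, `vn_raw`, `snr`, `vn`,
#'   `n_frames_eval`, `n_confirmed`, `n_pseudo_confirmed`.
#' @export
evaluate_detections <- function(result, truth, tol = 5, warmup = NULL) {
  stopifnot(inherits(result, "msod_result"))
  if (is.null(warmup)) warmup <- result$params$warmup
  d <- result$dims
  lf <- d[3] - 1L - result$params$latency
  det <- result$detections
  conf <- det[det$confirmed, , drop = FALSE]

  dr <- detection_rate(det, truth, tol = tol, warmup = warmup,
                       last_frame = lf)
  prf <- pixel_prf(det, truth, d, warmup = warmup, last_frame = lf)
  # the raw response at frame t reports the event at frame t - latency, so
  # the truth regions are advanced by the latency before scoring it
  truth_raw <- truth
  truth_raw$frame <- truth_raw$frame + result$params$latency
  raw <- snr_vn(result$lc11, truth_raw, tol = tol, warmup = warmup,
                last_frame = lf + result$params$latency)
  out_stack <- array(0, dim = d)
  if (nrow(conf) > 0L) {
    tt <- truth[!truth$is_pseudo, , drop = FALSE]
    bw <- if (nrow(tt) > 0L) tt$width[1] else 5L
    bh <- if (nrow(tt) > 0L) tt$height[1] else 5L
    stamp <- stamp_boxes(d, tibble::tibble(frame = conf$frame, x = conf$x,
                                           y = conf$y, width = bw, height = bh))
    out_stack[stamp] <- 1
  }
  fin <- snr_vn(out_stack, truth, tol = tol, warmup = warmup,
                last_frame = lf)

  # pseudo-object trajectories confirmed: confirmed detections within tol of
  # a pseudo ground-truth position
  pseudo <- truth[truth$is_pseudo, , drop = FALSE]
  n_pseudo_conf <- 0L
  if (nrow(conf) > 0L && nrow(pseudo) > 0L) {
    bad_traj <- unique(unlist(lapply(seq_len(nrow(conf)), function(i) {
      p <- pseudo[pseudo$frame == conf$frame[i], ]
      if (nrow(p) > 0L &&
          any(sqrt((p$x - conf$x[i])^2 + (p$y - conf$y[i])^2) <= tol)) {
        conf$trajectory[i]
      } else NULL
    })))
    n_pseudo_conf <- length(bad_traj)
  }

  out <- tibble::tibble(dr = dr, pr = prf$pr, rc = prf$rc, f1 = prf$f1,
                        tp = prf$tp, fp = prf$fp, fn = prf$fn, tn = prf$tn,
                        snr_raw = raw$snr, vn_raw = raw$vn,
                        snr = fin$snr, vn = fin$vn,
                        n_frames_eval = lf - warmup + 1L,
                        n_confirmed = nrow(conf),
                        n_pseudo_confirmed = n_pseudo_conf)
  class(out) <- c("msod_eval", class(out))
  out
}
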