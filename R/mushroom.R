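# Mushroom-body stage: threshold the LC11 response into detections, link
# them into trajectories, sample local contrast along each trajectory, and
# confirm only trajectories whose contrast varies over time. A feature that
# rides with the background sees the same neighbourhood forever, so its
# contrast series is flat and it is rejected; an independent mover crosses
# changing background and its contrast standard deviation grows.

#' Threshold the LC11 response into per-frame detections
#'
#' Each frame's positive response is normalized by a per-frame scale — by
#' default the mean of the `norm_top` largest positive values, which tracks
#' the strength of the few strongest candidate objects without being
#' dominated by the single strongest one — so the threshold is scale-free.
#' Pixels above `th` are reduced
#' to local maxima by greedy non-maximum suppression over a `nms x nms`
#' window (ties broken toward smaller y, then x).
#'
#' @param lc11 `H x W x T` signed response array.
#' @param th Normalized response threshold (default 0.2, >= 0).
#' @param nms Side of the suppression window in pixels (default 5).
#' @param use_abs Threshold `|LC11|` instead of its positive part.
#' @param norm_top Number of largest positive values averaged into the
#'   per-frame normalizer (default 100, about four 5 x 5 object
#'   footprints); `NULL` normalizes by the frame maximum.
#' @return Tibble with columns `frame`, `x`, `y` (0-based), `score` (raw
#'   response) and `norm_score`.
#' @export
threshold_detections <- function(lc11, th = 0.2, nms = 5L, use_abs = FALSE,
                                 norm_top = 100L) {
  if (th < 0) abort("`th` must be non-negative.")
  d <- dim(lc11)
  sup <- (as.integer(nms) - 1L) %/% 2L
  out <- vector("list", d[3])
  for (t in seq_len(d[3])) {
    v <- if (use_abs) abs(lc11[, , t]) else pmax(lc11[, , t], 0)
    m <- if (is.null(norm_top)) max(v) else {
      mean(sort.int(v, decreasing = TRUE,
                    method = "quick")[seq_len(min(norm_top, length(v)))])
    }
    if (m <= 0) next
    nv <- v / m
    idx <- which(nv > th, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    cand <- tibble::tibble(y = unname(idx[, 1L]) - 1L,
                           x = unname(idx[, 2L]) - 1L,
                           score = lc11[, , t][idx], norm_score = nv[idx])
    cand <- cand[order(-cand$norm_score, cand$y, cand$x), ]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      prev <- which(keep)
      if (length(prev) == 0L ||
          all(pmax(abs(cand$x[prev] - cand$x[i]),
                   abs(cand$y[prev] - cand$y[i])) > sup)) {
        keep[i] <- TRUE
      }
    }
    kept <- cand[keep, ]
    out[[t]] <- tibble::tibble(frame = t - 1L, x = kept$x, y = kept$y,
                               score = kept$score, norm_score = kept$norm_score)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(frame = integer(), x = integer(), y = integer(),
                          score = numeric(), norm_score = numeric())
  }
  dplyr::arrange(res, .data$frame, .data$y, .data$x)
}

#' Link detections into motion trajectories
#'
#' Greedy frame-to-frame nearest-neighbour association: a detection joins
#' the open trajectory whose last position is nearest and within the
#' distance budget `link_radius * (frame gap)` (ties go to the trajectory
#' created first); otherwise it starts a new trajectory. Trajectories
#' unmatched for more than `gap_max` frames are closed. Each detection
#' belongs to exactly one trajectory.
#'
#' @param detections Tibble from [threshold_detections()].
#' @param link_radius Maximum Euclidean step per frame between consecutive
#'   points (default 10 px).
#' @param gap_max Allowed missed frames before a trajectory closes
#'   (default 0: strictly consecutive; the full pipeline default is 1).
#' @return The detections tibble with a `trajectory` integer column.
#' @export
link_trajectories <- function(detections, link_radius = 10, gap_max = 0L) {
  if (link_radius <= 0) abort("`link_radius` must be positive.")
  n <- nrow(detections)
  traj_id <- integer(n)
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  next_id <- 1L
  frames <- if (n > 0L) sort(unique(detections$frame)) else integer(0)
  for (f in frames) {
    rows <- which(detections$frame == f)
    taken <- rep(FALSE, length(last_x))
    for (r in rows) {
      ok <- which(!taken & last_f >= f - 1L - gap_max & last_f < f)
      if (length(ok) > 0L) {
        dist <- sqrt((last_x[ok] - detections$x[r])^2 +
                     (last_y[ok] - detections$y[r])^2)
        budget <- link_radius * (f - last_f[ok])
        close <- ok[dist <= budget]
        if (length(close) > 0L) {
          dclose <- dist[match(close, ok)]
          best <- close[dclose == min(dclose)]
          id <- min(best)  # tie-break: earliest-created trajectory
          traj_id[r] <- id
          last_x[id] <- detections$x[r]; last_y[id] <- detections$y[r]
          last_f[id] <- f
          taken[id] <- TRUE
          next
        }
      }
      traj_id[r] <- next_id
      last_x[next_id] <- detections$x[r]; last_y[next_id] <- detections$y[r]
      last_f[next_id] <- f
      taken[next_id] <- TRUE
      next_id <- next_id + 1L
    }
  }
  dplyr::mutate(detections, trajectory = traj_id)
}

#' Sample local contrast along each trajectory
#'
#' Attaches `ct = T1(x_t, y_t, t)` to every trajectory point: the contrast
#' trajectory that the confirmation test operates on.
#'
#' @param detections Tibble with `frame`, `x`, `y` (0-based).
#' @param t1 `H x W x T` local-contrast array.
#' @return The tibble with a `ct` column.
#' @export
attach_contrast <- function(detections, t1) {
  d <- dim(t1)
  if (nrow(detections) > 0L &&
      (any(detections$y < 0 | detections$y >= d[1]) ||
       any(detections$x < 0 | detections$x >= d[2]) ||
       any(detections$frame < 0 | detections$frame >= d[3]))) {
    abort("detection positions fall outside the contrast stack.")
  }
  ct <- if (nrow(detections) == 0L) numeric(0) else {
    t1[cbind(detections$y + 1L, detections$x + 1L, detections$frame + 1L)]
  }
  dplyr::mutate(detections, ct = ct)
}

cumulative_sd <- function(x) {
  vapply(seq_along(x),
         function(i) if (i < 2L) 0 else stats::sd(x[seq_len(i)]),
         numeric(1))
}

#' Running standard deviation of the contrast trajectory
#'
#' For each trajectory, `sd_ct[i]` is the sample standard deviation
#' (divisor n - 1) of the contrast values from the trajectory start up to
#' point `i`; trajectories shorter than two points have `sd_ct = 0`.
#'
#' @param detections Tibble with `trajectory` and `ct` columns.
#' @return The tibble, ordered by trajectory and frame, with `sd_ct` and a
#'   per-trajectory point counter `n_points`.
#' @export
contrast_sd <- function(detections) {
  detections |>
    dplyr::arrange(.data$trajectory, .data$frame) |>
    dplyr::group_by(.data$trajectory) |>
    dplyr::mutate(n_points = dplyr::row_number(),
                  sd_ct = cumulative_sd(.data$ct)) |>
    dplyr::ungroup()
}

#' Confirm small-object trajectories
#'
#' A trajectory point at frame `t` is confirmed iff its trajectory has at
#' least `min_length` points by then and the running contrast standard
#' deviation exceeds `th2`. Raising `th2` never adds confirmations
#' (monotone rejection).
#'
#' @param detections Tibble from [contrast_sd()].
#' @param th2 Contrast-SD threshold (default 4.0, > 0 gray levels).
#' @param min_length Minimum trajectory length before any confirmation
#'   (default 3 points).
#' @return The tibble with a logical `confirmed` column.
#' @export
confirm_objects <- function(detections, th2 = 4.0, min_length = 3L) {
  dplyr::mutate(detections,
                confirmed = .data$n_points >= min_length & .data$sd_ct > th2)
}
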