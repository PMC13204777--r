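# Seeded synthetic stimulus generator: a textured panorama drifting
# horizontally behind a fixed viewport, background-locked small dark
# distractors ("pseudo-objects") painted into the panorama itself, and
# independently moving small objects painted per frame, with exact
# per-frame ground truth.
#
# Coordinate convention shared by all modules: 0-based, x = column (width
# axis), y = row (height axis), origin at the top-left of the viewport.

#' Describe an object in a synthetic scene
#'
#' @param id Character label.
#' @param width,height Object size in pixels.
#' @param luminance Gray level in \[0, 255\] painted over the background.
#' @param velocity Horizontal velocity in px/s (signed); for
#'   background-locked objects this must equal the background velocity.
#' @param x,y Centre position at frame 0, viewport coordinates (0-based).
#' @param locked `TRUE` for a background-locked pseudo-object (painted into
#'   the panorama, so it translates rigidly with the background).
#' @return One-row tibble.
#' @export
object_spec <- function(id, width = 5L, height = 5L, luminance = 0,
                        velocity = 0, x, y, locked = FALSE) {
  if (luminance < 0 || luminance > 255) abort("`luminance` must lie in [0, 255].")
  tibble::tibble(id = as.character(id), width = as.integer(width),
                 height = as.integer(height), luminance = as.numeric(luminance),
                 velocity = as.numeric(velocity), x = as.numeric(x),
                 y = as.numeric(y), locked = isTRUE(locked))
}

#' Configure a synthetic scene
#'
#' @param width,height Viewport size in pixels (default 500 x 250).
#' @param fps Frame rate (default 30).
#' @param duration Sequence length in milliseconds (default 700, i.e. 21
#'   frames at 30 FPS).
#' @param bg_velocity Background velocity in px/s, signed; positive moves
#'   the background rightward on screen.
#' @param texture Background texture generator: `"bandlimited_noise"`
#'   (default), `"perlin"` (multi-octave value noise) or
#'   `"tiled_photo_like"` (piecewise-constant patches plus fine noise).
#' @param texture_scale Correlation length of the texture in pixels
#'   (default 12, photograph-like smoothness at this viewport size).
#' @param contrast_sd Luminance standard deviation of the texture in gray
#'   levels (default 40 around a mean of 127.5, the RMS contrast of a
#'   typical outdoor photograph; values are clipped to \[0, 255\]).
#' @param panorama_width Panorama width; default just covers the sweep.
#' @param noise_sd Optional additive Gaussian sensor noise (gray levels).
#' @param seed Integer seed; the whole rendering is a pure function of the
#'   configuration (identical seed, identical frames).
#' @param objects Tibble of [object_spec()] rows.
#' @return A `msod_scene` configuration object.
#' @export
scene_config <- function(width = 500L, height = 250L, fps = 30, duration = 700,
                         bg_velocity = 250,
                         texture = c("bandlimited_noise", "perlin", "tiled_photo_like"),
                         texture_scale = 12, contrast_sd = 40,
                         panorama_width = NULL, noise_sd = 0,
                         seed = 1L, objects = NULL) {
  texture <- match.arg(texture)
  if (fps <= 0 || duration <= 0) abort("`fps` and `duration` must be positive.")
  n_frames <- floor(duration * fps / 1000)
  if (n_frames < 1) abort("`duration` too short for one frame.")
  sweep <- abs(round(bg_velocity * (n_frames - 1) / fps))
  need <- as.integer(width + sweep)
  if (is.null(panorama_width)) panorama_width <- need
  if (panorama_width < need) {
    abort(sprintf("`panorama_width` must be at least %d to cover the sweep.", need))
  }
  if (is.null(objects)) {
    objects <- tibble::tibble(id = character(), width = integer(),
                              height = integer(), luminance = numeric(),
                              velocity = numeric(), x = numeric(), y = numeric(),
                              locked = logical())
  }
  locked_bad <- objects$locked & objects$velocity != bg_velocity
  if (any(locked_bad)) {
    abort("background-locked objects must have `velocity` equal to `bg_velocity`.")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration = duration, n_frames = as.integer(n_frames),
                 bg_velocity = bg_velocity, texture = texture,
                 texture_scale = texture_scale, contrast_sd = contrast_sd,
                 panorama_width = as.integer(panorama_width),
                 noise_sd = noise_sd, seed = as.integer(seed), objects = objects),
            class = "msod_scene")
}

#' @export
print.msod_scene <- function(x, ...) {
  cat(sprintf("<msod scene: %dx%d px, %g FPS, %d frames, bg %+g px/s, %s, seed %d>\n",
              x$width, x$height, x$fps, x$n_frames, x$bg_velocity, x$texture, x$seed))
  print(x$objects)
  invisible(x)
}

# Smooth a matrix with a unit-sum Gaussian; helper for the textures. The
# kernel radius is capped so small panoramas can still be generated.
smooth_mat <- function(m, sigma) {
  r <- min(ceiling(3 * sigma), (min(dim(m)) - 1L) %/% 2L)
  off <- -r:r
  g1 <- exp(-off^2 / (2 * sigma^2))
  w <- outer(g1, g1)
  conv2_replicate_cpp(m, w / sum(w))
}

# photograph-like luminance statistics: mean 127.5, SD contrast_sd, clipped
photo_normalize <- function(m, contrast_sd) {
  s <- stats::sd(as.vector(m))
  out <- if (s == 0) {
    matrix(127.5, nrow(m), ncol(m))
  } else {
    127.5 + contrast_sd * (m - mean(m)) / s
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Generate the textured background panorama
#'
#' Seeded, reproducible broadband texture of size
#' `height x panorama_width`, normalized to photograph-like luminance
#' statistics (mean 127.5, standard deviation `contrast_sd`, clipped to
#' \[0, 255\]). Identical configuration gives a bit-identical panorama.
#'
#' @param config A [scene_config()].
#' @return Numeric matrix (`height` rows, `panorama_width` columns).
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "msod_scene"))
  h <- config$height; w <- config$panorama_width
  withr::with_seed(config$seed, {
    pano <- switch(config$texture,
      bandlimited_noise = {
        photo_normalize(smooth_mat(matrix(rnorm(h * w), h, w),
                                   config$texture_scale),
                        config$contrast_sd)
      },
      perlin = {
        acc <- matrix(0, h, w)
        amp <- 1
        for (cell in pmax(2, round(config$texture_scale * c(2, 1, 0.5)))) {
          gh <- ceiling(h / cell) + 1L; gw <- ceiling(w / cell) + 1L
          g <- matrix(rnorm(gh * gw), gh, gw)
          yi <- (seq_len(h) - 1) / cell; xi <- (seq_len(w) - 1) / cell
          y0 <- floor(yi); x0 <- floor(xi)
          fy <- yi - y0; fx <- xi - x0
          a <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
          b <- g[cbind(rep(y0 + 1, w), rep(x0 + 2, each = h))]
          c_ <- g[cbind(rep(y0 + 2, w), rep(x0 + 1, each = h))]
          d <- g[cbind(rep(y0 + 2, w), rep(x0 + 2, each = h))]
          wx <- rep(fx, each = h); wy <- rep(fy, w)
          acc <- acc + amp * matrix((a * (1 - wx) + b * wx) * (1 - wy) +
                                    (c_ * (1 - wx) + d * wx) * wy, h, w)
          amp <- amp / 2
        }
        photo_normalize(acc, config$contrast_sd)
      },
      tiled_photo_like = {
        cell <- max(4, round(config$texture_scale * 2))
        gh <- ceiling(h / cell); gw <- ceiling(w / cell)
        blocks <- matrix(rnorm(gh * gw), gh, gw)
        coarse <- blocks[rep(seq_len(gh), each = cell)[seq_len(h)],
                         rep(seq_len(gw), each = cell)[seq_len(w)]]
        fine <- matrix(rnorm(h * w, sd = 0.3), h, w)
        photo_normalize(smooth_mat(coarse + fine, 1), config$contrast_sd)
      })
    pano
  })
}

paint_rect <- function(frame, cx, cy, w, h, value) {
  nr <- nrow(frame); nc <- ncol(frame)
  x0 <- round(cx) - floor((w - 1) / 2); x1 <- x0 + w - 1L
  y0 <- round(cy) - floor((h - 1) / 2); y1 <- y0 + h - 1L
  xs <- max(0L, x0):min(nc - 1L, x1)
  ys <- max(0L, y0):min(nr - 1L, y1)
  if (length(xs) > 0 && length(ys) > 0 && x1 >= 0 && x0 <= nc - 1L &&
      y1 >= 0 && y0 <= nr - 1L) {
    frame[ys + 1L, xs + 1L] <- value
  }
  frame
}

#' Render a synthetic frame sequence with ground truth
#'
#' Frame `t` (0-based) shows the panorama window at offset
#' `off0 - round(bg_velocity * t / fps)` so the background translates at
#' `bg_velocity` px/s on screen. Background-locked objects are painted into
#' the panorama (fixed panorama coordinates); independent movers are
#' painted per frame at `x0 + velocity * t / fps` (rounded to the nearest
#' pixel, hard edges, no anti-aliasing). Ground truth records the exact
#' (sub-pixel) centre of every object whose centre is inside the viewport.
#'
#' @param config A [scene_config()].
#' @return A list with `frames` (an `msod_frames` object: `height x width x
#'   n_frames` array plus `fps`) and `truth` (tibble with columns `frame`,
#'   `object_id`, `x`, `y`, `width`, `height`, `is_pseudo`).
#' @export
render_sequence <- function(config) {
  stopifnot(inherits(config, "msod_scene"))
  H <- config$height; W <- config$width; TT <- config$n_frames
  fps <- config$fps; v_bg <- config$bg_velocity
  off0 <- max(0, round(v_bg * (TT - 1) / fps))
  pano <- generate_background(config)

  obj <- config$objects
  bad <- obj$x < 0 | obj$x > W - 1 | obj$y < 0 | obj$y > H - 1
  if (any(bad)) abort("object start centres must lie inside the viewport.")

  # paint locked objects into the panorama once: rigid with the background
  locked <- obj[obj$locked, , drop = FALSE]
  for (i in seq_len(nrow(locked))) {
    pano <- paint_rect(pano, locked$x[i] + off0, locked$y[i],
                       locked$width[i], locked$height[i], locked$luminance[i])
  }
  movers <- obj[!obj$locked, , drop = FALSE]

  frames <- array(0, dim = c(H, W, TT))
  truth <- vector("list", TT)
  for (t in seq_len(TT) - 1L) {
    off <- off0 - round(v_bg * t / fps)
    fr <- pano[, (off + 1L):(off + W), drop = FALSE]
    rec <- list()
    for (i in seq_len(nrow(locked))) {
      x_t <- locked$x[i] + round(v_bg * t / fps)
      if (x_t >= 0 && x_t <= W - 1) {
        rec[[length(rec) + 1L]] <- tibble::tibble(
          frame = t, object_id = locked$id[i], x = x_t, y = locked$y[i],
          width = locked$width[i], height = locked$height[i], is_pseudo = TRUE)
      }
    }
    for (i in seq_len(nrow(movers))) {
      x_t <- movers$x[i] + movers$velocity[i] * t / fps
      if (x_t >= 0 && x_t <= W - 1) {
        fr <- paint_rect(fr, x_t, movers$y[i], movers$width[i],
                         movers$height[i], movers$luminance[i])
        rec[[length(rec) + 1L]] <- tibble::tibble(
          frame = t, object_id = movers$id[i], x = x_t, y = movers$y[i],
          width = movers$width[i], height = movers$height[i], is_pseudo = FALSE)
      }
    }
    if (config$noise_sd > 0) {
      fr <- withr::with_seed(config$seed + 7919L * (t + 1L), {
        fr + matrix(rnorm(H * W, sd = config$noise_sd), H, W)
      })
      fr[fr < 0] <- 0
      fr[fr > 255] <- 255
    }
    frames[, , t + 1L] <- fr
    truth[[t + 1L]] <- dplyr::bind_rows(rec)
  }
  list(frames = new_frames(frames, fps),
       truth = dplyr::bind_rows(truth))
}

#' Frame-sequence container
#'
#' @param frames `H x W x T` numeric array of gray levels in \[0, 255\].
#' @param fps Frame rate.
#' @return An `msod_frames` object.
#' @export
new_frames <- function(frames, fps) {
  d <- dim(frames)
  if (length(d) != 3L) abort("`frames` must be an H x W x T array.")
  if (!all(is.finite(frames))) abort("frame values must be finite.")
  structure(list(frames = frames, fps = fps), class = "msod_frames")
}

#' @export
print.msod_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<msod frames: %d x %d px, %d frames @ %g FPS, range [%.4g, %.4g]>\n",
              d[2], d[1], d[3], x$fps, min(x$frames), max(x$frames)))
  invisible(x)
}

#' Baseline study scene
#'
#' The reference stimulus: 500 x 250 px viewport at 30 FPS for 700 ms
#' (21 frames), background drifting rightward at 250 px/s, three
#' background-locked 5 x 5 luminance-0 pseudo-objects, and one independent
#' 5 x 5 luminance-0 object moving leftward at 250 px/s. Positions are
#' chosen so no two trajectories approach within the default link radius.
#'
#' @param seed Integer seed controlling the background texture.
#' @return A [scene_config()].
#' @export
baseline_scene <- function(seed = 1L) {
  objects <- dplyr::bind_rows(
    object_spec("A", x = 50,  y = 60,  luminance = 0, velocity = 250, locked = TRUE),
    object_spec("B", x = 65,  y = 125, luminance = 0, velocity = 250, locked = TRUE),
    object_spec("C", x = 80,  y = 190, luminance = 0, velocity = 250, locked = TRUE),
    object_spec("D", x = 430, y = 125, luminance = 0, velocity = -250, locked = FALSE))
  scene_config(seed = seed, objects = objects)
}

#' Parameter-sweep scenes
#'
#' Enumerates the benchmark grid over one attribute of the independent
#' mover, all other parameters at baseline: `width` 2:1:12 (height 5),
#' `height` 2:1:12 (width 5), `size` (2:1:12) squared, `luminance` 0:25:250,
#' `velocity` 250:50:500 px/s.
#'
#' @param parameter One of `"width"`, `"height"`, `"size"`, `"luminance"`,
#'   `"velocity"`.
#' @param seed Integer seed shared by all configurations in the sweep.
#' @return Named list of [scene_config()] objects, one per grid value.
#' @export
sweep_scenes <- function(parameter = c("width", "height", "size", "luminance",
                                       "velocity"), seed = 1L) {
  parameter <- match.arg(parameter)
  values <- switch(parameter,
                   width = 2:12, height = 2:12, size = 2:12,
                   luminance = seq(0, 250, by = 25),
                   velocity = seq(250, 500, by = 50))
  cfgs <- lapply(values, function(v) {
    cfg <- baseline_scene(seed)
    i <- which(!cfg$objects$locked)
    cfg$objects[i, ] <- switch(parameter,
      width     = dplyr::mutate(cfg$objects[i, ], width = as.integer(v)),
      height    = dplyr::mutate(cfg$objects[i, ], height = as.integer(v)),
      size      = dplyr::mutate(cfg$objects[i, ], width = as.integer(v),
                                height = as.integer(v)),
      luminance = dplyr::mutate(cfg$objects[i, ], luminance = as.numeric(v)),
      velocity  = dplyr::mutate(cfg$objects[i, ], velocity = -as.numeric(v)))
    cfg
  })
  names(cfgs) <- as.character(values)
  cfgs
}
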