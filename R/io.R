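# Plain-text / image I/O: PNG frame directories, CSV detections and
# ground truth, TIFF stage dumps.

#' Write a frame sequence as numbered PNG files
#'
#' 8-bit gray PNGs named `frame_0000.png`, `frame_0001.png`, ... (frame
#' numbers 0-based). Requires the `png` package.
#'
#' @param frames An `msod_frames` object or `H x W x T` array in \[0, 255\].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_frames_png <- function(frames, dir) {
  rlang::check_installed("png")
  stack <- if (inherits(frames, "msod_frames")) frames$frames else frames
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(dim(stack)[3])
  for (t in seq_len(dim(stack)[3])) {
    paths[t] <- file.path(dir, sprintf("frame_%04d.png", t - 1L))
    png::writePNG(stack[, , t] / 255, paths[t])
  }
  invisible(paths)
}

#' Read a directory of PNG frames
#'
#' Reads `*.png` in lexicographic order into a frame stack; RGB images are
#' converted to luminance.
#'
#' @param dir Directory of PNG files.
#' @param fps Frame rate to attach.
#' @return An `msod_frames` object with values in \[0, 255\].
#' @export
read_frames_png <- function(dir, fps = 30) {
  rlang::check_installed("png")
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) abort(sprintf("no PNG frames found in '%s'.", dir))
  imgs <- lapply(files, function(f) {
    im <- png::readPNG(f) * 255
    if (length(dim(im)) == 3L) rgb_to_gray(im[, , 1:3, drop = FALSE]) else im
  })
  d <- dim(imgs[[1]])
  stack <- array(0, dim = c(d[1], d[2], length(imgs)))
  for (t in seq_along(imgs)) {
    if (!identical(dim(imgs[[t]]), d)) {
      abort(sprintf("frame %d has inconsistent dimensions.", t - 1L))
    }
    stack[, , t] <- imgs[[t]]
  }
  new_frames(stack, fps)
}

#' Write detections to CSV
#'
#' Columns `frame`, `x`, `y`, `score`, `trajectory`, `confirmed` (0/1).
#'
#' @param result An `msod_result` (or its detections tibble).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_detections_csv <- function(result, path) {
  det <- if (inherits(result, "msod_result")) result$detections else result
  out <- dplyr::transmute(det, frame = .data$frame, x = .data$x, y = .data$y,
                          score = .data$score, trajectory = .data$trajectory,
                          confirmed = as.integer(.data$confirmed))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write ground truth to CSV
#'
#' Columns `frame`, `object_id`, `x`, `y`, `width`, `height`, `is_pseudo`
#' (0/1).
#'
#' @param truth Ground-truth tibble from [render_sequence()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_truth_csv <- function(truth, path) {
  out <- dplyr::mutate(truth, is_pseudo = as.integer(.data$is_pseudo))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a detections or ground-truth CSV
#'
#' @param path CSV written by [write_detections_csv()] or
#'   [write_truth_csv()].
#' @return A tibble; 0/1 flag columns are restored to logical.
#' @export
read_msod_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(c("confirmed", "is_pseudo"), names(x))) {
    x[[col]] <- as.logical(x[[col]])
  }
  x
}

#' Dump a response stack as TIFF images
#'
#' One 32-bit float TIFF per frame, for inspection in external viewers.
#' Requires the `tiff` package.
#'
#' @param stack `H x W x T` numeric array.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_stack_tiff <- function(stack, dir, prefix = "stage") {
  rlang::check_installed("tiff")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(dim(stack)[3])
  for (t in seq_len(dim(stack)[3])) {
    paths[t] <- file.path(dir, sprintf("%s_%04d.tif", prefix, t - 1L))
    tiff::writeTIFF(stack[, , t], paths[t], bits.per.sample = 32L,
                    reduce = FALSE)
  }
  invisible(paths)
}
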