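# ggplot2 visualisations of results.

#' Plot detected trajectories
#'
#' Image-plane view of every detection, coloured by confirmation status and
#' grouped by trajectory; confirmed trajectories are what the model reports
#' as genuine small moving objects.
#'
#' @param object An `msod_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msod_result <- function(object, ...) {
  det <- object$detections
  ggplot2::ggplot(det, ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$trajectory,
                                    colour = .data$confirmed)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, object$dims[2] - 1),
                         ylim = c(object$dims[1] - 1, 0), expand = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "confirmed",
                  title = "Detections and trajectories")
}

#' Plot per-stage row profiles
#'
#' Line profiles of each retained stage along one image row at one frame,
#' faceted by stage (see [profile_row()]).
#'
#' @param result An `msod_result` run with `keep_stages = TRUE`.
#' @param y0 Row (0-based).
#' @param t0 Frame (0-based).
#' @return A ggplot.
#' @export
plot_profiles <- function(result, y0, t0) {
  prof <- profile_row(result, y0, t0)
  prof$stage <- factor(prof$stage, levels = unique(prof$stage))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stage, scales = "free_y", ncol = 3) +
    ggplot2::labs(x = "x (px)", y = "response",
                  title = sprintf("Stage profiles at y = %d, frame %d", y0, t0))
}

#' Plot contrast-SD growth per trajectory
#'
#' The running standard deviation of the contrast trajectory against frame
#' time, one line per trajectory, with the confirmation threshold drawn as
#' a horizontal reference. Background-locked features stay flat; true
#' movers climb across the threshold.
#'
#' @param object An `msod_result`.
#' @return A ggplot.
#' @export
plot_contrast_sd <- function(object) {
  det <- object$detections
  ggplot2::ggplot(det, ggplot2::aes(x = .data$frame, y = .data$sd_ct,
                                    group = .data$trajectory,
                                    colour = .data$confirmed)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$th2, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "frame", y = "running SD of local contrast",
                  colour = "confirmed")
}
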