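# Figures: group-average trajectories in the standardized space.

#' Plot group-average standardized trajectories
#'
#' Draws the frame-wise mean mouse path of each group in the standardized
#' coordinate space (start at the origin, chosen response at the upper
#' left). Liars and depressed responders typically arc further toward the
#' non-chosen alternative than truth-tellers.
#'
#' @param avg Either a `mouse_cohort` (averaged on the fly) or the output
#'   of [average_trajectory()].
#' @return A ggplot object.
#' @export
plot_average_trajectories <- function(avg) {
  if (inherits(avg, "mouse_cohort")) avg <- average_trajectory(avg)
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$group)) +
    ggplot2::geom_path(linewidth = 0.9) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 15) +
    ggplot2::annotate("text", x = 0, y = -0.06, label = "START",
                      size = 3) +
    ggplot2::coord_fixed(xlim = c(-1.15, 1.15), ylim = c(-0.12, 1.75)) +
    ggplot2::labs(
      x = "x (standardized)", y = "y (standardized)",
      colour = NULL,
      title = "Average mouse trajectories by group"
    ) +
    ggplot2::theme_minimal()
}
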