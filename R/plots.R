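# Plotting helpers (ggplot2).

#' Spaghetti plot of cohort index trajectories by group
#'
#' @param cohort Cohort tibble from [simulate_longitudinal_cohort()] (or any
#'   long table with `subject_id`, `group`, `age` and the value column).
#' @param value_col Index column to plot.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cohort, value_col = "dki_alps") {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$age, y = .data[[value_col]],
                               group = .data$subject_id,
                               colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "age (years)", y = value_col,
                  title = sprintf("Longitudinal %s trajectories", value_col))
}

#' Plot the four ROI means behind an ALPS result
#'
#' @param object An `alps_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alps_result <- function(object, ...) {
  rois <- object$dti_rois
  df <- tibble::tibble(
    hemisphere = rep(c("left", "right"), each = 4L),
    component = rep(names(rois$left), 2L),
    value = c(rois$left, rois$right)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$value,
                                   fill = .data$hemisphere)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "axis diffusivity (1e-3 mm²/s)",
                  title = sprintf("ALPS ROI means (bilateral index %.3f)",
                                  object$dti_alps_mean))
}
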