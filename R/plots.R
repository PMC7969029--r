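utils::globalVariables(c("position", "mean_val", "lo", "hi", "parameter",
                         "value", "col", "row", "r"))

#' Plot average profiles with shaded SEM envelopes
#'
#' One panel per parameter, mean line with a `mean +/- sem` ribbon —
#' the standard way to eyeball where the boundary signal sits.
#'
#' @param avg long average-profile data.frame from [average_profiles()].
#' @param parameters subset of parameters to show (default all).
#' @return a ggplot object.
#' @export
plot_average_profiles <- function(avg, parameters = NULL) {
  if (!is.null(parameters)) avg <- avg[avg$parameter %in% parameters, ]
  avg$mean_val <- avg$mean
  avg$lo <- avg$mean - avg$sem
  avg$hi <- avg$mean + avg$sem
  ggplot2::ggplot(avg, ggplot2::aes(position, mean_val)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.3,
                         fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue4", linewidth = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "position (nt, junction at 0)", y = "parameter value") +
    ggplot2::theme_minimal()
}

#' Joint plot of all parameters on the normalised scale
#'
#' Min-max normalises each parameter's pooled average profile to `[0, 1]`
#' and overlays them, which is how the characteristic joint deviation
#' around the junction (and the flatness of controls) is usually shown.
#'
#' @param avg long average-profile data.frame.
#' @return a ggplot object.
#' @export
plot_joint_profiles <- function(avg) {
  parts <- lapply(split(avg, avg$parameter), function(d) {
    d <- d[order(d$position), ]
    d$value <- minmax_normalize(d$mean)
    d
  })
  long <- do.call(rbind, parts)
  ggplot2::ggplot(long, ggplot2::aes(position, value, group = parameter,
                                     colour = parameter)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = "position (nt, junction at 0)",
                  y = "normalised value") +
    ggplot2::theme_minimal()
}
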