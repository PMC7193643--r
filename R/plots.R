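#' Box plots of MAD by threshold offset
#'
#' MAD (mm) of the surface models against the reference model, per
#' threshold offset and acquisition mode, before and after best-fit
#' superimposition.
#'
#' @param records Sweep-record tibble from [run_threshold_sweep()].
#' @return A ggplot object.
#' @export
plot_mad <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = factor(.data$threshold_offset),
                               y = .data$mad_mm,
                               fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "threshold offset (intensity units)",
                  y = "MAD (mm)", fill = "superimposition") +
    ggplot2::theme_minimal()
}

#' Box plots of the movement components
#'
#' Rigid movement (translations in mm, rotations in degrees) required to
#' superimpose each threshold model on the reference model.
#'
#' @inheritParams plot_mad
#' @return A ggplot object.
#' @export
plot_movement <- function(records) {
  long <- tidyr::pivot_longer(
    dplyr::filter(records, .data$status == "after"),
    cols = c("tx", "ty", "tz", "rx", "ry", "rz"),
    names_to = "component", values_to = "value")
  long$component <- factor(long$component,
                           levels = c("tx", "ty", "tz", "rx", "ry", "rz"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$threshold_offset),
                               y = .data$value, fill = .data$mode)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "threshold offset (intensity units)",
                  y = "movement (mm / degrees)", fill = "mode") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.threshsurf_sweep <- function(object, type = c("mad", "movement"),
                                      ...) {
  type <- match.arg(type)
  if (type == "mad") plot_mad(object) else plot_movement(object)
}
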