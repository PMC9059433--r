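# ggplot2 views of waveforms and sweep tables.

#' Plot ventilation waveforms
#'
#' Faceted time series of tube/lung pressure (cmH2O), inspiratory and exhaust
#' flow (L/min) and lung volume (mL), shaded by breath phase.
#'
#' @param object A `vcv_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vcv_sim <- function(object, ...) {
  wf <- object$waveform
  long <- wf |>
    tidyr::pivot_longer(
      cols = c(
        "p_tube_cmH2O", "p_lung_cmH2O",
        "flow_insp_L_min", "flow_exh_L_min", "v_lung_mL"
      ),
      names_to = "signal", values_to = "value"
    ) |>
    dplyr::mutate(panel = dplyr::case_when(
      grepl("^p_", .data$signal) ~ "pressure [cmH2O]",
      grepl("^flow", .data$signal) ~ "flow [L/min]",
      TRUE ~ "lung volume [mL]"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_s, y = .data$value,
    colour = .data$signal
  )) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vcv_sim
#' @param sim A `vcv_sim`.
#' @export
plot_waveform <- function(sim, ...) autoplot.vcv_sim(sim, ...)

#' Plot a sweep result table
#'
#' @param sweep A tibble from [run_sweep()].
#' @param y Column to plot against the swept value (default peak pressure).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, y = "peak_cmH2O") {
  ok <- sweep[isTRUE(sweep$ok) | sweep$ok, , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$value, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(ok$param), y = y) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
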