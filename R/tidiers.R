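# broom-style verbs for simulation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into its waveform tibble
#'
#' @param x A `vcv_sim`.
#' @param ... Unused.
#' @return The waveform tibble (one row per sample).
#' @exportS3Method generics::tidy
#' @export
tidy.vcv_sim <- function(x, ...) {
  x$waveform
}

#' One-row summary of a simulation run
#'
#' @param x A `vcv_sim`.
#' @param ... Unused.
#' @return A one-row tibble: cycles simulated, samples, steady-state peak /
#'   plateau / PEEP / delivered volume, mass-conservation residual and the
#'   flow-limitation flag.
#' @exportS3Method generics::glance
#' @export
glance.vcv_sim <- function(x, ...) {
  met <- steady_state_metrics(x)
  tibble::tibble(
    n_cycles = x$scenario$engine$n_cycles,
    n_samples = nrow(x$waveform),
    peak_cmH2O = met$peak_cmH2O,
    plateau_cmH2O = met$plateau_cmH2O,
    peep_cmH2O = met$peep_cmH2O,
    delivered_mL = met$delivered_mL,
    peak_exp_flow_L_min = met$peak_exp_flow_L_min,
    mass_residual_pct = x$mass$residual_pct,
    flow_limited = x$flow_limited
  )
}
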