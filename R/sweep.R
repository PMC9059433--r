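# Parametric sweep runner: one simulation + metrics per parameter value,
# emitted as a tidy table with per-row failure capture.

#' Run a one-parameter sweep over a base scenario
#'
#' For each value, rebuilds the scenario with the parameter replaced, runs
#' [simulate_vcv()] and reads steady-state [breath_metrics()]. A failed run
#' is recorded in its row (`ok = FALSE`, `error` message) and the sweep
#' continues. Rows are ordered by input value order.
#'
#' @param scenario Base [vent_scenario()].
#' @param param Parameter name as in [vent_scenario()] (dotted config aliases
#'   such as `"vcv.tidal_volume"` are accepted). Values are in the clinical
#'   units of that argument (mL, s, kPa, L/cmH2O, mm^2, ...).
#' @param values Numeric vector of parameter values (nonempty).
#' @param eps,tau Plateau detector settings forwarded to metrics.
#' @return A tibble, one row per value: `param`, `value`, the steady-state
#'   breath metrics, `mass_residual_pct`, `flow_limited`, `ok`, `error`.
#' @examples
#' \donttest{
#' run_sweep(vent_scenario(n_cycles = 2, washout = 1),
#'   "tidal_volume", c(300, 500))
#' }
#' @export
run_sweep <- function(scenario, param, values, eps = 0.5, tau = 0.2) {
  stopifnot(inherits(scenario, "vent_scenario"))
  if (length(values) == 0) stop("empty sweep value list", call. = FALSE)
  canon <- resolve_param_name(param)
  purrr::map_dfr(values, function(v) {
    base <- tibble::tibble(param = canon, value = v)
    res <- tryCatch(
      {
        args <- stats::setNames(list(v), canon)
        sc <- do.call(update_scenario, c(list(scenario), args))
        sim <- simulate_vcv(sc)
        met <- steady_state_metrics(sim, eps = eps, tau = tau)
        dplyr::bind_cols(
          base, met,
          tibble::tibble(
            mass_residual_pct = sim$mass$residual_pct,
            flow_limited = sim$flow_limited,
            ok = TRUE, error = NA_character_
          )
        )
      },
      error = function(e) {
        dplyr::bind_cols(base, tibble::tibble(ok = FALSE, error = conditionMessage(e)))
      }
    )
    res
  })
}
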