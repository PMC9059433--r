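# Small, fast scenarios for the unit tests: coarser output grid and fewer
# cycles than the package defaults, physics unchanged.

fast_scenario <- function(...) {
  args <- utils::modifyList(
    list(dt_out = 0.01, n_cycles = 2, washout = 1),
    list(...)
  )
  do.call(vent_scenario, args)
}

# Scenario used for static-compliance manoeuvres: a long pause so the
# plateau is well developed and a long exhaust so end-expiratory pressure
# returns to (near) atmospheric.
recovery_scenario <- function(compliance, tidal_volume) {
  vent_scenario(
    compliance = compliance, tidal_volume = tidal_volume,
    inspiratory_time = 1.4, plateau_time = 0.5,
    exhaust_time = 6, cycle_period = 8,
    dt_out = 0.01, n_cycles = 2, washout = 1
  )
}
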