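# Built-in self test: the fast physical invariants, runnable from the CLI.

#' Run the built-in invariant checks
#'
#' Quick physical sanity suite: orifice-flow regime continuity and
#' monotonicity, unit round-trips, valve truth tables, the rigid-chamber
#' closed form, and mass conservation of a short default breath. Intended for
#' the command line (`ventsim selftest`); the full test suite lives in the
#' package tests.
#'
#' @param quiet Suppress per-check messages.
#' @return `TRUE` if all checks pass, else `FALSE` (invisibly), with failures
#'   reported.
#' @export
vent_selftest <- function(quiet = FALSE) {
  gas <- gas_properties()
  checks <- list(
    "critical ratio 0.528 (air)" = function() {
      abs(critical_pressure_ratio(gas) - 0.528) < 5e-4
    },
    "choked/subsonic continuity at the critical ratio" = function() {
      b <- critical_pressure_ratio(gas)
      p_up <- 3e5
      f_sub <- orifice_mass_flow(1e-6, p_up, p_up * (b + 1e-12), gas)
      f_chk <- orifice_mass_flow(1e-6, p_up, p_up * b, gas)
      abs(f_sub - f_chk) / f_chk < 1e-6
    },
    "choked flow invariant to downstream pressure" = function() {
      a <- orifice_mass_flow(1e-6, 3e5, 3e5 * 0.3, gas)
      b2 <- orifice_mass_flow(1e-6, 3e5, 3e5 * 0.5, gas)
      abs(a - b2) / a < 1e-12
    },
    "flow linear in area" = function() {
      abs(orifice_mass_flow(2e-6, 2e5, 1.5e5, gas) -
        2 * orifice_mass_flow(1e-6, 2e5, 1.5e5, gas)) < 1e-15
    },
    "pressure unit round trip" = function() {
      x <- convert_pressure(convert_pressure(12.3, "cmH2O", "MPa"), "MPa", "cmH2O")
      abs(x - 12.3) < 1e-10
    },
    "5/2 bistable retains position with both coils energized" = function() {
      spec <- valve_spec("5/2")
      st <- valve_state(spec, "HOME")
      st2 <- valve_state_update(spec, st, TRUE, TRUE)
      st2$position == "HOME"
    },
    "rigid-chamber fill matches the linear closed form" = function() {
      sc <- vent_scenario(
        tidal_volume = 240, inspiratory_time = 0.6, plateau_time = 0,
        exhaust_time = 0.2, cycle_period = 0.8, insp_area = 0,
        source_pressure = 400, n_cycles = 1, washout = 0
      )
      sim <- simulate_vcv(sc)
      wf <- sim$waveform[sim$waveform$phase == "INSPIRATION", ]
      q <- target_flow(sc$vcv)
      rho <- reference_density(sc$gas)
      slope <- sc$gas$R * sc$gas$theta * rho * q / sc$tube$volume # Pa/s
      expect <- convert_pressure(slope * wf$time_s, "Pa", "cmH2O")
      max(abs(wf$p_tube_cmH2O - expect) / max(expect)) < 1e-3
    },
    "mass conservation of a default breath" = function() {
      sim <- simulate_vcv(vent_scenario(n_cycles = 1, washout = 0))
      sim$mass$residual_pct < 0.5
    }
  )
  ok <- TRUE
  for (nm in names(checks)) {
    pass <- tryCatch(isTRUE(checks[[nm]]()), error = function(e) FALSE)
    if (!quiet) message(sprintf("[%s] %s", if (pass) "ok" else "FAIL", nm))
    ok <- ok && pass
  }
  invisible(ok)
}
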