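# The volume-controlled ventilation law and the breath-cycle phase machine:
# inspiration -> plateau -> expiration -> rest, driven either by fixed
# durations or by the electro-pneumatic relay/timer circuits.

BREATH_PHASES <- c("INSPIRATION", "PLATEAU", "EXPIRATION", "REST")

#' Volume-controlled ventilation settings
#'
#' @param tidal_volume Tidal volume V_T (m^3).
#' @param inspiratory_time Inspiratory time T_i (s), pause included.
#' @param plateau_time End-inspiratory pause T_p (s), `0 <= T_p < T_i`.
#' @param exhaust_time Exhaust (expiratory valve open) time T_e (s).
#' @param cycle_period Breath period (s, `>= T_i + T_e`); slack is rest at
#'   end-expiration with all valves closed.
#' @param source_pressure Regulated supply absolute pressure (Pa).
#' @return An object of class `vcv_settings`.
#' @export
vcv_settings <- function(tidal_volume, inspiratory_time, plateau_time = 0,
                         exhaust_time, cycle_period = inspiratory_time + exhaust_time,
                         source_pressure = 200e3) {
  stopifnot(
    tidal_volume > 0,
    inspiratory_time > plateau_time, plateau_time >= 0,
    exhaust_time > 0,
    cycle_period >= inspiratory_time + exhaust_time,
    source_pressure > 0
  )
  structure(
    list(
      tidal_volume = tidal_volume,
      inspiratory_time = inspiratory_time,
      plateau_time = plateau_time,
      exhaust_time = exhaust_time,
      cycle_period = cycle_period,
      source_pressure = source_pressure
    ),
    class = "vcv_settings"
  )
}

#' Set inspiratory flow of the volume controller
#'
#' The constant flow a VCV delivers while inspiration is active:
#' Q_T = V_T / (T_i - T_p).
#'
#' @param settings A [vcv_settings()] object.
#' @return Volumetric flow (m^3 s^-1, at atmospheric conditions).
#' @examples
#' s <- vcv_settings(500e-6, 1.2, 0.2, 1.6)
#' target_flow(s) # 5e-4 m^3/s = 30 L/min
#' @export
target_flow <- function(settings) {
  tvo <- settings$inspiratory_time - settings$plateau_time
  if (tvo <= 0) stop("inspiratory time must exceed plateau time", call. = FALSE)
  settings$tidal_volume / tvo
}

#' Commanded ventilator output flow (piecewise volume cutoff)
#'
#' The controller outputs Q_T while the phase is inspiratory and the volume
#' delivered this breath is below V_T, and zero otherwise (volume-triggered
#' cutoff).
#'
#' @param settings A [vcv_settings()] object.
#' @param delivered Volume delivered so far this breath (m^3, >= 0).
#' @param phase One of `"INSPIRATION"`, `"PLATEAU"`, `"EXPIRATION"`, `"REST"`.
#' @return Volumetric flow (m^3 s^-1).
#' @export
commanded_flow <- function(settings, delivered, phase) {
  stopifnot(delivered >= 0)
  phase <- match.arg(phase, BREATH_PHASES)
  if (phase == "INSPIRATION" && delivered < settings$tidal_volume) {
    target_flow(settings)
  } else {
    0
  }
}

#' Breath phase at a time within the cycle
#'
#' Half-open partition of the cycle: `[0, T_i - T_p)` inspiration,
#' `[T_i - T_p, T_i)` plateau, `[T_i, T_i + T_e)` expiration, the remainder
#' rest.
#'
#' @param t_in_cycle Time since cycle start (s), in `[0, cycle_period)`.
#'   Vectorised.
#' @param settings A [vcv_settings()] object.
#' @return Character vector of phases.
#' @export
phase_at <- function(t_in_cycle, settings) {
  if (any(t_in_cycle < 0 | t_in_cycle >= settings$cycle_period)) {
    stop("time outside [0, cycle_period)", call. = FALSE)
  }
  ti <- settings$inspiratory_time
  tvo <- ti - settings$plateau_time
  te <- settings$exhaust_time
  ifelse(t_in_cycle < tvo, "INSPIRATION",
    ifelse(t_in_cycle < ti, "PLATEAU",
      ifelse(t_in_cycle < ti + te, "EXPIRATION", "REST")
    )
  )
}

# ---- electro-pneumatic circuit emulation -----------------------------------

#' Emulate the relay-ladder control circuit of a rig preset
#'
#' Steps the electro-pneumatic control circuit of the 5/2 (PA), 5/3 (PB) and
#' 3/2 (PC) experiment presets: a latched pushbutton energizes relay K1, K1
#' feeds an on-delay timer whose output re-arms itself so the solenoid command
#' toggles every `timer_delay` seconds (actuation alternates with period
#' `2 * timer_delay`), and the valve position follows the archetype's coil
#' semantics via [valve_state_update()]. The breath phase is derived from the
#' resulting supply/exhaust connectivity.
#'
#' @param archetype Valve archetype (`"5/2"`, `"5/3"`, `"3/2"` or aliases
#'   `PA`/`PB`/`PC`).
#' @param timer_delay On-delay timer setting d (s); the valve toggles at
#'   t = d, 2d, 3d, ...
#' @param times Non-decreasing evaluation times (s, from 0).
#' @param spec Optional [valve_spec()]; defaults to the archetype with 6 mm^2
#'   paths and no switching delay.
#' @return A tibble with columns `time`, `phase`, `position`, `supply_open`,
#'   `exhaust_open`, `coil_a`, `coil_b`.
#' @export
circuit_driven_phase <- function(archetype, timer_delay, times, spec = NULL) {
  archetype <- normalize_archetype(archetype)
  stopifnot(timer_delay > 0, length(times) > 0, all(diff(times) >= 0), times[1] >= 0)
  if (is.null(spec)) {
    spec <- valve_spec(archetype, supply_area = 6e-6, exhaust_area = 6e-6)
  }
  timer <- on_delay_timer(timer_delay)
  # Circuit starts insufflating: the start pushbutton latches K1 and (for the
  # bistable 5/2) pulses the set coil; spring-return archetypes hold their
  # insufflation coil where their home position is the exhaust side.
  toggles <- 0L
  want_supply <- TRUE
  state <- valve_state(spec, position = if (archetype == "5/3") "HOME" else "HOME")
  rows <- vector("list", length(times))
  for (i in seq_along(times)) {
    now <- times[i]
    timer <- on_delay_timer_update(timer, input = TRUE, now = now)
    if (timer$output) { # timer fires: toggle command, re-arm
      toggles <- toggles + 1L
      want_supply <- !want_supply
      timer$rise_time <- now
      timer$output <- FALSE
    }
    sig <- .coil_signals(archetype, want_supply)
    state <- valve_state_update(spec, state, sig$a, sig$b, now = now)
    conn <- state$connectivity
    phase <- if (conn["supply"] > 0) {
      "INSPIRATION"
    } else if (conn["exhaust"] > 0) {
      "EXPIRATION"
    } else {
      "REST"
    }
    rows[[i]] <- tibble::tibble(
      time = now, phase = phase, position = state$position,
      supply_open = unname(conn["supply"]), exhaust_open = unname(conn["exhaust"]),
      coil_a = sig$a, coil_b = sig$b
    )
  }
  dplyr::bind_rows(rows)
}

# Coil signals that request the supply or exhaust path for each archetype.
# 5/2: coil A drives ACTUATED (supply), coil B drives HOME (exhaust).
# 5/3: energized -> ACTUATED (exhaust), de-energized -> HOME (supply).
# 3/2: energized -> ACTUATED (supply), de-energized -> HOME (exhaust).
.coil_signals <- function(archetype, want_supply) {
  switch(archetype,
    "5/2" = list(a = want_supply, b = !want_supply),
    "5/3" = list(a = !want_supply, b = FALSE),
    "3/2" = list(a = want_supply, b = FALSE)
  )
}
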