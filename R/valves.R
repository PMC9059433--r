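# Compressible orifice flow through gating valves (choked/subsonic regimes)
# and the discrete switching machinery: 5/2 bistable double-coil, 5/3
# spring-return and 3/2 spring-return solenoid valves, plus on-delay timers.

VALVE_ARCHETYPES <- c("5/2", "5/3", "3/2")
.archetype_aliases <- c(
  "5/2" = "5/2", "5/3" = "5/3", "3/2" = "3/2",
  PA = "5/2", PB = "5/3", PC = "3/2"
)

normalize_archetype <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("\\\\", "/", x)
  if (!x %in% names(.archetype_aliases)) {
    stop(sprintf(
      "unknown valve archetype '%s' (known: %s)",
      x, paste(names(.archetype_aliases), collapse = ", ")
    ), call. = FALSE)
  }
  unname(.archetype_aliases[x])
}

#' Critical pressure ratio for choked orifice flow
#'
#' The downstream/upstream pressure ratio below which a converging orifice
#' chokes: b = (2/(k+1))^(k/(k-1)). For air (k = 1.4) this is 0.528 to three
#' decimals.
#'
#' @param gas A [gas_properties()] object (only `k` is used).
#' @return The dimensionless critical ratio.
#' @examples
#' critical_pressure_ratio(gas_properties()) # ~0.528
#' @export
critical_pressure_ratio <- function(gas = gas_properties()) {
  k <- gas$k
  if (!is.numeric(k) || k <= 1) stop("heat-capacity ratio k must exceed 1", call. = FALSE)
  (2 / (k + 1))^(k / (k - 1))
}

#' Compressible mass flow through an effective orifice
#'
#' Converging-nozzle model of a pneumatic valve: below the critical pressure
#' ratio the flow is choked and depends only on upstream conditions,
#'
#'   mdot = A p_up sqrt(k/(R theta)) (2/(k+1))^((k+1)/(2(k-1)))
#'
#' above it the subsonic branch applies,
#'
#'   mdot = A p_up sqrt(2k/((k-1) R theta)) sqrt(r^(2/k) - r^((k+1)/k)),
#'
#' with r = p_down/p_up. The result is a non-negative magnitude directed from
#' high to low pressure; the circuit graph assigns sign. Vectorised over
#' pressures and area.
#'
#' @param area Effective orifice area (m^2, >= 0).
#' @param p_up,p_down Upstream and downstream absolute pressures (Pa, > 0);
#'   `p_up >= p_down` is expected (callers orient the pair).
#' @param gas A [gas_properties()] object.
#' @return Mass flow magnitude (kg s^-1).
#' @examples
#' gas <- gas_properties()
#' orifice_mass_flow(6e-6, 200e3, 101.325e3, gas) # choked (ratio ~0.507)
#' @export
orifice_mass_flow <- function(area, p_up, p_down, gas = gas_properties()) {
  stopifnot(all(area >= 0))
  if (any(p_up <= 0) || any(p_down <= 0)) {
    stop("absolute pressures must be positive", call. = FALSE)
  }
  k <- gas$k
  R <- gas$R
  theta <- gas$theta
  b <- critical_pressure_ratio(gas)
  r <- pmin(p_down / p_up, 1)
  choked <- area * p_up * sqrt(k / (R * theta)) * (2 / (k + 1))^((k + 1) / (2 * (k - 1)))
  # guard: r^(2/k) - r^((k+1)/k) can go epsilon-negative at r = 1
  sub_arg <- pmax(r^(2 / k) - r^((k + 1) / k), 0)
  subsonic <- area * p_up * sqrt(2 * k / ((k - 1) * R * theta)) * sqrt(sub_arg)
  ifelse(r <= b, choked, subsonic)
}

# Port connectivity per (archetype, position): open fraction of the
# supply->patient and patient->exhaust paths. Home positions follow the
# circuit narratives: the 5/3 rests with the supply path pressurised
# (spring-return, rear chamber filled when de-energized), the 5/2 and 3/2
# rest with the exhaust path open.
.connectivity_table <- list(
  "5/2" = list(
    HOME     = c(supply = 0, exhaust = 1),
    ACTUATED = c(supply = 1, exhaust = 0)
  ),
  "5/3" = list(
    HOME     = c(supply = 1, exhaust = 0),
    ACTUATED = c(supply = 0, exhaust = 1),
    MID      = c(supply = 0, exhaust = 0)
  ),
  "3/2" = list(
    HOME     = c(supply = 0, exhaust = 1),
    ACTUATED = c(supply = 1, exhaust = 0)
  )
)

#' Specification of a solenoid gating valve
#'
#' @param archetype `"5/2"` (bistable, two coils), `"5/3"` (spring-return,
#'   closed mid position) or `"3/2"` (spring-return). Aliases `"PA"`, `"PB"`,
#'   `"PC"` are accepted.
#' @param supply_area Effective area of the supply (inspiratory) path (m^2).
#' @param exhaust_area Effective area of the exhaust path (m^2).
#' @param switching_delay Delay between a coil command and the position
#'   change (s, >= 0).
#' @return An object of class `valve_spec`.
#' @export
valve_spec <- function(archetype = "5/2", supply_area = 6e-6,
                       exhaust_area = 6e-6, switching_delay = 0) {
  archetype <- normalize_archetype(archetype)
  stopifnot(
    supply_area >= 0, exhaust_area >= 0,
    supply_area + exhaust_area > 0,
    switching_delay >= 0
  )
  structure(
    list(
      archetype = archetype,
      supply_area = supply_area,
      exhaust_area = exhaust_area,
      switching_delay = switching_delay
    ),
    class = "valve_spec"
  )
}

#' Instantaneous state of a solenoid valve
#'
#' @param spec A [valve_spec()].
#' @param position `"HOME"`, `"ACTUATED"`, or (5/3 only) `"MID"`.
#' @return An object of class `valve_state` with the position, coil signals
#'   and the port connectivity implied by the position.
#' @export
valve_state <- function(spec, position = "HOME") {
  position <- match.arg(position, c("HOME", "ACTUATED", "MID"))
  if (position == "MID" && spec$archetype != "5/3") {
    stop("MID position only exists for the 5/3 archetype", call. = FALSE)
  }
  structure(
    list(
      archetype = spec$archetype,
      position = position,
      coil_a = FALSE,
      coil_b = FALSE,
      pending = NULL, # list(position=, at=) while a switch is in flight
      connectivity = valve_connectivity(spec$archetype, position)
    ),
    class = "valve_state"
  )
}

#' Port connectivity of a valve archetype in a given position
#'
#' @param archetype Valve archetype tag.
#' @param position Position tag.
#' @return Named numeric vector with open fractions for the `supply`
#'   (supply to patient) and `exhaust` (patient to exhaust) paths.
#' @export
valve_connectivity <- function(archetype, position) {
  archetype <- normalize_archetype(archetype)
  tab <- .connectivity_table[[archetype]]
  if (!position %in% names(tab)) {
    stop(sprintf("position '%s' not valid for archetype %s", position, archetype),
      call. = FALSE
    )
  }
  tab[[position]]
}

# Target position implied by the coil signals alone (before switching delay).
# 5/2: bistable memory -- a sole energized coil selects a side; both or
# neither retain the current position (the coils "act on each other with the
# same force"). 5/3 and 3/2: spring return.
.commanded_position <- function(archetype, current, coil_a, coil_b) {
  switch(archetype,
    "5/2" = {
      if (coil_a && !coil_b) "ACTUATED" else if (coil_b && !coil_a) "HOME" else current
    },
    "5/3" = if (coil_a) "ACTUATED" else "HOME",
    "3/2" = if (coil_a) "ACTUATED" else "HOME"
  )
}

#' Advance a valve state machine given coil signals
#'
#' Applies the archetype semantics: the 5/2 is bistable (a sole energized
#' coil drives it after the switching delay; both or neither energized retain
#' the position), the 5/3 and 3/2 are spring-return (energized = ACTUATED,
#' de-energized = HOME). Connectivity is recomputed from the new position.
#'
#' @param spec A [valve_spec()].
#' @param state The current [valve_state()].
#' @param coil_a,coil_b Coil signals; `coil_b` is meaningful only for the 5/2.
#' @param now Current time (s).
#' @return The updated `valve_state`.
#' @export
valve_state_update <- function(spec, state, coil_a, coil_b = FALSE, now = 0) {
  target <- .commanded_position(spec$archetype, state$position, isTRUE(coil_a), isTRUE(coil_b))
  state$coil_a <- isTRUE(coil_a)
  state$coil_b <- isTRUE(coil_b)
  if (target == state$position) {
    state$pending <- NULL
  } else if (spec$switching_delay == 0) {
    state$position <- target
    state$pending <- NULL
  } else if (is.null(state$pending) || state$pending$position != target) {
    state$pending <- list(position = target, at = now + spec$switching_delay)
  } else if (now >= state$pending$at) {
    state$position <- target
    state$pending <- NULL
  }
  state$connectivity <- valve_connectivity(spec$archetype, state$position)
  state
}

#' On-delay timer relay
#'
#' A relay whose output asserts once its input has been continuously true for
#' `delay` seconds, and resets immediately on a falling input.
#'
#' @param delay Delay (s, > 0).
#' @return An object of class `on_delay_timer`.
#' @export
on_delay_timer <- function(delay) {
  stopifnot(is.numeric(delay), delay > 0)
  structure(
    list(delay = delay, rise_time = NA_real_, output = FALSE, last_now = -Inf),
    class = "on_delay_timer"
  )
}

#' @rdname on_delay_timer
#' @param timer An `on_delay_timer`.
#' @param input Logical input signal at time `now`.
#' @param now Current time (s); must be non-decreasing across calls.
#' @return The updated timer (field `output` carries the relay output).
#' @export
on_delay_timer_update <- function(timer, input, now) {
  if (now < timer$last_now) {
    stop("on-delay timer driven backwards in time", call. = FALSE)
  }
  timer$last_now <- now
  if (isTRUE(input)) {
    if (is.na(timer$rise_time)) timer$rise_time <- now
    timer$output <- (now - timer$rise_time) >= timer$delay
  } else {
    timer$rise_time <- NA_real_
    timer$output <- FALSE
  }
  timer
}
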