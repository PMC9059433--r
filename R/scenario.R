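# Scenario configuration: clinical/engineering units at the boundary,
# absolute SI inside. A scenario bundles gas properties, lung and tube
# mechanics, valve geometry, VCV settings and integrator options, and can be
# round-tripped through a YAML file with explicit units on every quantity.

#' Build a simulation scenario
#'
#' Arguments are in the units a clinician or pneumatics engineer would use;
#' they are converted to absolute SI once, here. The defaults are the
#' reference desk-scale breath scenario: a 500 mL breath delivered over a 1.2 s
#' inspiration with a 0.3 s end-inspiratory pause (set flow 33.3 L/min), 1.6 s exhaust, adult-typical lung
#' mechanics, and a 6 mm^2 exhalation valve.
#'
#' @param tidal_volume Tidal volume (mL).
#' @param inspiratory_time Inspiratory time incl. pause (s).
#' @param plateau_time End-inspiratory pause (s).
#' @param exhaust_time Expiratory-valve open time (s).
#' @param cycle_period Breath period (s); defaults to a 15 breaths/min cycle
#'   of 4 s for the breath family, `2 * timer_delay` for the rig family.
#' @param source_pressure Regulated supply pressure (kPa, absolute).
#' @param compliance Lung compliance (L/cmH2O).
#' @param unstressed_volume Lung volume at zero gauge pressure (L).
#' @param tube_volume Rigid patient-tube volume (L).
#' @param archetype Gating-valve archetype: `"5/2"`, `"5/3"`, `"3/2"` (or
#'   `PA`/`PB`/`PC`).
#' @param supply_area Effective area of the supply orifice feeding the tube
#'   (mm^2).
#' @param insp_area Effective area of the tube-to-lung (inspiratory) path
#'   (mm^2).
#' @param exhaust_area Effective area of the exhalation valve (mm^2).
#' @param switching_delay Valve switching delay (s).
#' @param cushion Logical; first-order slow-start of the exhaust area (the
#'   5/3 actuator's magnetic cushion). Defaults to on for the 5/3 archetype.
#' @param cushion_tau Cushion time constant (s).
#' @param gas A [gas_properties()] object.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param dt_out Output sampling interval (s).
#' @param n_cycles Number of breath cycles to simulate.
#' @param washout Cycles discarded before steady-state metrics are read.
#' @param family `"breath"` (clinical timing grid) or `"rig"` (relay-timer
#'   circuit timing; requires `timer_delay`).
#' @param timer_delay On-delay timer setting for the rig family (s).
#' @return An object of class `vent_scenario`.
#' @examples
#' sc <- vent_scenario()
#' sc$vcv$tidal_volume # 5e-4 m^3
#' @export
vent_scenario <- function(tidal_volume = 500,
                          inspiratory_time = 1.2,
                          plateau_time = 0.3,
                          exhaust_time = 1.6,
                          cycle_period = NULL,
                          source_pressure = 200,
                          compliance = 0.05,
                          unstressed_volume = 2,
                          tube_volume = 0.5,
                          archetype = "5/2",
                          supply_area = 6,
                          insp_area = 12,
                          exhaust_area = 6,
                          switching_delay = 0,
                          cushion = NULL,
                          cushion_tau = 0.2,
                          gas = gas_properties(),
                          rtol = 1e-8,
                          atol = 1e-10,
                          dt_out = 0.005,
                          n_cycles = 3,
                          washout = 2,
                          family = c("breath", "rig"),
                          timer_delay = NULL) {
  family <- match.arg(family)
  archetype <- normalize_archetype(archetype)
  if (is.null(cushion)) cushion <- archetype == "5/3"
  if (family == "rig") {
    if (is.null(timer_delay) || timer_delay <= 0) {
      stop("rig-family scenarios need a positive timer_delay", call. = FALSE)
    }
    inspiratory_time <- timer_delay
    plateau_time <- 0
    exhaust_time <- timer_delay
    if (is.null(cycle_period)) cycle_period <- 2 * timer_delay
  }
  if (is.null(cycle_period)) cycle_period <- 4
  config <- list(
    tidal_volume = tidal_volume, inspiratory_time = inspiratory_time,
    plateau_time = plateau_time, exhaust_time = exhaust_time,
    cycle_period = cycle_period, source_pressure = source_pressure,
    compliance = compliance, unstressed_volume = unstressed_volume,
    tube_volume = tube_volume, archetype = archetype,
    supply_area = supply_area, insp_area = insp_area,
    exhaust_area = exhaust_area, switching_delay = switching_delay,
    cushion = cushion, cushion_tau = cushion_tau, gas = gas,
    rtol = rtol, atol = atol, dt_out = dt_out,
    n_cycles = n_cycles, washout = washout,
    family = family, timer_delay = timer_delay
  )
  stopifnot(n_cycles >= 1, washout >= 0, washout < n_cycles, dt_out > 0)
  structure(
    list(
      gas = gas,
      lung = lung_params(
        compliance = convert_volume(compliance, "L", "m3") / PA_PER_CMH2O,
        unstressed_volume = convert_volume(unstressed_volume, "L", "m3")
      ),
      tube = tube_params(convert_volume(tube_volume, "L", "m3")),
      valve = list(
        spec = valve_spec(
          archetype,
          supply_area = convert_area(supply_area, "mm2", "m2"),
          exhaust_area = convert_area(exhaust_area, "mm2", "m2"),
          switching_delay = switching_delay
        ),
        insp_area = convert_area(insp_area, "mm2", "m2"),
        cushion = isTRUE(cushion),
        cushion_tau = cushion_tau
      ),
      vcv = vcv_settings(
        tidal_volume = convert_volume(tidal_volume, "mL", "m3"),
        inspiratory_time = inspiratory_time,
        plateau_time = plateau_time,
        exhaust_time = exhaust_time,
        cycle_period = cycle_period,
        source_pressure = convert_pressure(source_pressure, "kPa", "Pa")
      ),
      engine = list(
        rtol = rtol, atol = atol, dt_out = dt_out,
        n_cycles = n_cycles, washout = washout
      ),
      family = family,
      timer_delay = timer_delay,
      config = config
    ),
    class = "vent_scenario"
  )
}

#' Modify a scenario
#'
#' Rebuilds a scenario from its stored clinical-unit configuration with the
#' named fields replaced; names are those of [vent_scenario()] (dotted config
#' paths such as `"vcv.tidal_volume"` are accepted as aliases).
#'
#' @param scenario A `vent_scenario`.
#' @param ... Named replacements, e.g. `tidal_volume = 300`.
#' @return A new `vent_scenario`.
#' @export
update_scenario <- function(scenario, ...) {
  stopifnot(inherits(scenario, "vent_scenario"))
  changes <- list(...)
  names(changes) <- vapply(names(changes), resolve_param_name, character(1))
  do.call(vent_scenario, utils::modifyList(scenario$config, changes))
}

.param_aliases <- c(
  "vcv.tidal_volume" = "tidal_volume",
  "vcv.inspiratory_time" = "inspiratory_time",
  "vcv.plateau_time" = "plateau_time",
  "vcv.exhaust_time" = "exhaust_time",
  "vcv.cycle_period" = "cycle_period",
  "vcv.source_pressure" = "source_pressure",
  "lung.compliance" = "compliance",
  "lung.unstressed_volume" = "unstressed_volume",
  "tube.volume" = "tube_volume",
  "valve.archetype" = "archetype",
  "valve.supply_area" = "supply_area",
  "valve.insp_area" = "insp_area",
  "valve.exhaust_area" = "exhaust_area",
  "circuit.preset" = "archetype",
  "circuit.timer_delay" = "timer_delay"
)

resolve_param_name <- function(name) {
  if (name %in% .param_aliases) {
    return(name)
  } # already canonical
  if (name %in% names(.param_aliases)) {
    return(unname(.param_aliases[name]))
  }
  if (name %in% names(formals(vent_scenario))) {
    return(name)
  }
  stop(sprintf(
    "unknown scenario parameter '%s' (known: %s and dotted aliases)",
    name, paste(setdiff(names(formals(vent_scenario)), "..."), collapse = ", ")
  ), call. = FALSE)
}

#' @export
print.vent_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<vent_scenario: %s family, %s valve>\n", cfg$family, cfg$archetype
  ))
  cat(sprintf(
    "  VCV: V_T %g mL, T_i %g s (pause %g s), T_e %g s, cycle %g s\n",
    cfg$tidal_volume, cfg$inspiratory_time, cfg$plateau_time,
    cfg$exhaust_time, cfg$cycle_period
  ))
  cat(sprintf(
    "  lung: C %g L/cmH2O, V_l0 %g L; tube %g L; A_sup/A_insp/A_ev %g/%g/%g mm2\n",
    cfg$compliance, cfg$unstressed_volume, cfg$tube_volume,
    cfg$supply_area, cfg$insp_area, cfg$exhaust_area
  ))
  invisible(x)
}

# ---- YAML round-trip -------------------------------------------------------

.qty <- function(value, unit) list(value = value, unit = unit)

.qty_in <- function(q, kind, convert, target) {
  if (is.numeric(q) && is.null(names(q))) {
    stop(sprintf("%s must carry an explicit unit ({value:, unit:})", kind),
      call. = FALSE
    )
  }
  if (!is.list(q) || is.null(q$value) || is.null(q$unit)) {
    stop(sprintf("%s must be a {value:, unit:} mapping", kind), call. = FALSE)
  }
  convert(q$value, q$unit, target)
}

#' Read / write a scenario as YAML
#'
#' The on-disk form carries explicit units on every physical quantity so that
#' the cmH2O/MPa ambiguity cannot enter a run silently. `read_scenario()` of a
#' `write_scenario()` output reproduces a scenario with identical simulation
#' behaviour.
#'
#' @param path File path.
#' @param scenario A `vent_scenario`.
#' @return `read_scenario()` a `vent_scenario`; `write_scenario()` the path,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  gas <- do.call(gas_properties, c(
    list(),
    raw$gas[intersect(
      names(raw$gas),
      names(formals(gas_properties))
    )]
  ))
  args <- list(gas = gas)
  grab <- function(section, key, kind, convert, target) {
    q <- raw[[section]][[key]]
    if (is.null(q)) {
      return(NULL)
    }
    .qty_in(q, paste(section, key, sep = "."), convert, target)
  }
  # unit-bearing quantities
  num_or_null <- function(section, key) raw[[section]][[key]]
  set <- function(name, val) if (!is.null(val)) args[[name]] <<- val
  set("compliance", {
    q <- raw$lung$compliance
    if (!is.null(q)) {
      parts <- strsplit(q$unit, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("compliance unit must be <volume>/<pressure>", call. = FALSE)
      convert_volume(q$value, parts[1], "L") /
        convert_pressure(1, parts[2], "cmH2O")
    }
  })
  set("unstressed_volume", grab("lung", "unstressed_volume", "volume", convert_volume, "L"))
  set("tube_volume", grab("tube", "volume", "volume", convert_volume, "L"))
  set("supply_area", grab("valve", "supply_area", "area", convert_area, "mm2"))
  set("insp_area", grab("valve", "inspiratory_area", "area", convert_area, "mm2"))
  set("exhaust_area", grab("valve", "exhaust_area", "area", convert_area, "mm2"))
  set("archetype", num_or_null("valve", "archetype"))
  set("switching_delay", num_or_null("valve", "switching_delay"))
  set("cushion", num_or_null("valve", "cushion"))
  set("cushion_tau", num_or_null("valve", "cushion_tau"))
  set("tidal_volume", grab("vcv", "tidal_volume", "volume", convert_volume, "mL"))
  set("inspiratory_time", num_or_null("vcv", "inspiratory_time"))
  set("plateau_time", num_or_null("vcv", "plateau_time"))
  set("exhaust_time", num_or_null("vcv", "exhaust_time"))
  set("cycle_period", num_or_null("vcv", "cycle_period"))
  set("source_pressure", grab("vcv", "source_pressure", "pressure", convert_pressure, "kPa"))
  for (k in c("rtol", "atol", "dt_out", "n_cycles", "washout")) {
    set(k, num_or_null("engine", k))
  }
  set("family", raw$family)
  set("timer_delay", raw$timer_delay)
  do.call(vent_scenario, args)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "vent_scenario"))
  cfg <- scenario$config
  out <- list(
    family = cfg$family,
    gas = list(
      specific_gas_constant = cfg$gas$R,
      heat_capacity_ratio = cfg$gas$k,
      temperature = cfg$gas$theta,
      atmospheric_pressure = cfg$gas$p_atm
    ),
    lung = list(
      compliance = .qty(cfg$compliance, "L/cmH2O"),
      unstressed_volume = .qty(cfg$unstressed_volume, "L")
    ),
    tube = list(volume = .qty(cfg$tube_volume, "L")),
    valve = list(
      archetype = cfg$archetype,
      supply_area = .qty(cfg$supply_area, "mm2"),
      inspiratory_area = .qty(cfg$insp_area, "mm2"),
      exhaust_area = .qty(cfg$exhaust_area, "mm2"),
      switching_delay = cfg$switching_delay,
      cushion = cfg$cushion,
      cushion_tau = cfg$cushion_tau
    ),
    vcv = list(
      tidal_volume = .qty(cfg$tidal_volume, "mL"),
      inspiratory_time = cfg$inspiratory_time,
      plateau_time = cfg$plateau_time,
      exhaust_time = cfg$exhaust_time,
      cycle_period = cfg$cycle_period,
      source_pressure = .qty(cfg$source_pressure, "kPa")
    ),
    engine = scenario$engine
  )
  if (!is.null(cfg$timer_delay)) out$timer_delay <- cfg$timer_delay
  yaml::write_yaml(out, path)
  invisible(path)
}
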