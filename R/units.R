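# Unit handling. All physics inside the package runs in absolute SI
# (Pa, kg/s, m^3); clinical/engineering units (cmH2O, MPa, L/min, mL) exist
# only at the configuration and output boundaries.

#' Conventional conversion factor: pascals per centimetre of water
#' @keywords internal
PA_PER_CMH2O <- 98.0665

.pressure_units <- c(Pa = 1, kPa = 1e3, MPa = 1e6, cmH2O = PA_PER_CMH2O)
.volume_units <- c(`m3` = 1, L = 1e-3, mL = 1e-6)
.area_units <- c(`m2` = 1, mm2 = 1e-6)
.flow_units <- c(`m3/s` = 1, `L/s` = 1e-3, `L/min` = 1e-3 / 60)

#' Gas properties of the working gas
#'
#' Bundles the constants of the ideal-gas working fluid: the specific gas
#' constant, the heat-capacity ratio, the (isothermal) working temperature and
#' the ambient atmospheric pressure. Defaults are standard dry air at room
#' temperature.
#'
#' @param specific_gas_constant Specific gas constant R (J kg^-1 K^-1).
#' @param heat_capacity_ratio Heat-capacity ratio k (dimensionless, > 1).
#' @param temperature Working temperature (K); the model is isothermal.
#' @param atmospheric_pressure Ambient absolute pressure (Pa).
#' @return An object of class `gas_properties`.
#' @examples
#' gas_properties()
#' @export
gas_properties <- function(specific_gas_constant = 287.05,
                           heat_capacity_ratio = 1.4,
                           temperature = 293.15,
                           atmospheric_pressure = 101325) {
  stopifnot(
    is.numeric(specific_gas_constant), specific_gas_constant > 0,
    is.numeric(heat_capacity_ratio), heat_capacity_ratio > 1,
    is.numeric(temperature), temperature >= 250, temperature <= 330,
    is.numeric(atmospheric_pressure), atmospheric_pressure > 0
  )
  structure(
    list(
      R = as.numeric(specific_gas_constant),
      k = as.numeric(heat_capacity_ratio),
      theta = as.numeric(temperature),
      p_atm = as.numeric(atmospheric_pressure)
    ),
    class = "gas_properties"
  )
}

#' @export
print.gas_properties <- function(x, ...) {
  cat("<gas_properties>",
    sprintf(" R     = %.4g J/kg/K", x$R),
    sprintf(" k     = %.4g", x$k),
    sprintf(" theta = %.4g K", x$theta),
    sprintf(" p_atm = %.6g Pa", x$p_atm),
    sep = "\n"
  )
  invisible(x)
}

.convert_with <- function(value, from_unit, to_unit, table, kind) {
  if (!from_unit %in% names(table)) {
    stop(sprintf(
      "unknown %s unit '%s' (known: %s)",
      kind, from_unit, paste(names(table), collapse = ", ")
    ), call. = FALSE)
  }
  if (!to_unit %in% names(table)) {
    stop(sprintf(
      "unknown %s unit '%s' (known: %s)",
      kind, to_unit, paste(names(table), collapse = ", ")
    ), call. = FALSE)
  }
  stopifnot(is.numeric(value), all(is.finite(value)))
  # ratio first: same-unit conversions stay exact
  value * (unname(table[from_unit]) / unname(table[to_unit]))
}

#' Convert pressure magnitudes between units
#'
#' Exact multiplicative conversion between `Pa`, `kPa`, `MPa` and `cmH2O`
#' (1 cmH2O = 98.0665 Pa). Vectorised over `value`.
#'
#' @param value Numeric pressure magnitude(s).
#' @param from_unit,to_unit Unit tags, one of `"Pa"`, `"kPa"`, `"MPa"`,
#'   `"cmH2O"`.
#' @return Converted magnitude(s).
#' @examples
#' convert_pressure(1, "cmH2O", "Pa") # 98.0665
#' convert_pressure(0.1, "MPa", "cmH2O")
#' @export
convert_pressure <- function(value, from_unit, to_unit) {
  .convert_with(value, from_unit, to_unit, .pressure_units, "pressure")
}

#' @rdname convert_pressure
#' @export
convert_volume <- function(value, from_unit, to_unit) {
  .convert_with(value, from_unit, to_unit, .volume_units, "volume")
}

#' @rdname convert_pressure
#' @export
convert_area <- function(value, from_unit, to_unit) {
  .convert_with(value, from_unit, to_unit, .area_units, "area")
}

#' @rdname convert_pressure
#' @export
convert_flow <- function(value, from_unit, to_unit) {
  .convert_with(value, from_unit, to_unit, .flow_units, "volumetric flow")
}

#' Gauge/absolute pressure conversion
#'
#' The physics core works in absolute pascals; clinical pressures (cmH2O) are
#' gauge. `gauge_to_absolute()` adds atmospheric pressure,
#' `absolute_to_gauge()` is its exact inverse.
#'
#' @param p_gauge Gauge pressure (Pa, relative to atmosphere).
#' @param p_abs Absolute pressure (Pa).
#' @param gas A [gas_properties()] object supplying atmospheric pressure.
#' @return Pressure in Pa (absolute or gauge respectively).
#' @export
gauge_to_absolute <- function(p_gauge, gas = gas_properties()) {
  stopifnot(is.numeric(p_gauge), all(is.finite(p_gauge)))
  p <- p_gauge + gas$p_atm
  if (any(p <= 0)) {
    stop("nonphysical absolute pressure <= 0 Pa", call. = FALSE)
  }
  p
}

#' @rdname gauge_to_absolute
#' @export
absolute_to_gauge <- function(p_abs, gas = gas_properties()) {
  stopifnot(is.numeric(p_abs), all(is.finite(p_abs)))
  if (any(p_abs <= 0)) {
    stop("nonphysical absolute pressure <= 0 Pa", call. = FALSE)
  }
  p_abs - gas$p_atm
}

#' Gas density at reference (atmospheric) conditions
#'
#' rho = p_atm / (R * theta); used to convert between volumetric flow reported
#' at atmospheric conditions and the mass flow the chamber equations need.
#'
#' @inheritParams gauge_to_absolute
#' @return Density (kg m^-3).
#' @export
reference_density <- function(gas = gas_properties()) {
  gas$p_atm / (gas$R * gas$theta)
}

#' Volumetric/mass flow conversion at reference density
#'
#' Volumetric flows are reported at atmospheric conditions (ATPD); the
#' conversion is multiplication by the reference density and is exactly
#' invertible.
#'
#' @param q_vol Volumetric flow (m^3 s^-1 at atmospheric conditions).
#' @param mdot Mass flow (kg s^-1).
#' @inheritParams gauge_to_absolute
#' @return Mass flow (kg/s) or volumetric flow (m^3/s).
#' @export
volumetric_to_mass_flow <- function(q_vol, gas = gas_properties()) {
  stopifnot(is.numeric(q_vol), all(is.finite(q_vol)))
  q_vol * reference_density(gas)
}

#' @rdname volumetric_to_mass_flow
#' @export
mass_to_volumetric_flow <- function(mdot, gas = gas_properties()) {
  stopifnot(is.numeric(mdot), all(is.finite(mdot)))
  mdot / reference_density(gas)
}
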