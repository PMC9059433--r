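# Continuum state of the breathable-air circuit: a rigid flexible-tube
# chamber and a single-compartment compliant lung, both isothermal ideal-gas
# chambers. Pressures are absolute Pa throughout.

#' Lung mechanical parameters
#'
#' Linear single-compartment lung: volume responds to gauge pressure with a
#' constant compliance, V_l(p) = V_l0 + C_l (p - p_atm).
#'
#' @param compliance Compliance C_l in m^3/Pa (use [convert_volume()] /
#'   [convert_pressure()] or the config layer for clinical L/cmH2O input).
#' @param unstressed_volume Lung volume at zero gauge pressure (m^3).
#' @return An object of class `lung_params`.
#' @examples
#' # 0.05 L/cmH2O, 2 L unstressed volume
#' lung_params(compliance = 0.05e-3 / 98.0665, unstressed_volume = 2e-3)
#' @export
lung_params <- function(compliance, unstressed_volume) {
  stopifnot(compliance > 0, unstressed_volume > 0)
  structure(
    list(compliance = compliance, unstressed_volume = unstressed_volume),
    class = "lung_params"
  )
}

#' Tube (patient circuit) parameters
#'
#' @param volume Rigid internal volume of the flexible tube (m^3).
#' @return An object of class `tube_params`.
#' @export
tube_params <- function(volume) {
  stopifnot(volume > 0)
  structure(list(volume = volume), class = "tube_params")
}

#' Lung volume at a given alveolar pressure
#'
#' V_l = V_l0 + C_l (p_l - p_atm); the derivative with respect to p_l is the
#' compliance exactly (the defining linear compliance law).
#'
#' @param p_l Absolute lung pressure (Pa). Vectorised.
#' @param lung A [lung_params()] object.
#' @param gas A [gas_properties()] object.
#' @return Lung volume (m^3).
#' @export
lung_volume <- function(p_l, lung, gas = gas_properties()) {
  v <- lung$unstressed_volume + lung$compliance * (p_l - gas$p_atm)
  if (any(v <= 0)) {
    stop("nonpositive lung volume: over-deflation, check parameters", call. = FALSE)
  }
  v
}

#' Pressure derivatives of the tube-lung chamber system
#'
#' Isothermal ideal-gas chamber dynamics. The rigid tube obeys
#' dp_t/dt = (R theta / V_t) (mdot_in - mdot_tl - mdot_ex); the compliant
#' lung follows from d(p_l V_l)/dt = R theta mdot_tl with dV_l/dt = C_l
#' dp_l/dt, giving dp_l/dt = R theta mdot_tl / (V_l(p_l) + C_l p_l). With
#' C_l = 0 the lung form reduces to the rigid-chamber law.
#'
#' @param p_t,p_l Absolute tube and lung pressures (Pa).
#' @param mdot_in Mass flow into the tube from the ventilator (kg/s, signed).
#' @param mdot_tl Mass flow from tube to lung (kg/s, signed; negative during
#'   expiration).
#' @param mdot_ex Mass flow from tube to the exhaust port (kg/s, signed).
#' @param tube A [tube_params()] object.
#' @param lung A [lung_params()] object.
#' @param gas A [gas_properties()] object.
#' @return Named numeric vector `c(dp_t, dp_l)` in Pa/s.
#' @export
pressure_derivatives <- function(p_t, p_l, mdot_in, mdot_tl, mdot_ex,
                                 tube, lung, gas = gas_properties()) {
  stopifnot(
    p_t > 0, p_l > 0,
    is.finite(mdot_in), is.finite(mdot_tl), is.finite(mdot_ex)
  )
  rt <- gas$R * gas$theta
  dp_t <- rt * (mdot_in - mdot_tl - mdot_ex) / tube$volume
  dp_l <- rt * mdot_tl / (lung_volume(p_l, lung, gas) + lung$compliance * p_l)
  c(dp_t = dp_t, dp_l = dp_l)
}

#' Stored gas mass in the two chambers (ideal-gas closure)
#'
#' m = p V / (R theta) for the tube (fixed volume) and the lung (volume from
#' the compliance law).
#'
#' @inheritParams pressure_derivatives
#' @return Named vector `c(m_tube, m_lung)` in kg.
#' @export
stored_mass <- function(p_t, p_l, tube, lung, gas = gas_properties()) {
  rt <- gas$R * gas$theta
  c(
    m_tube = p_t * tube$volume / rt,
    m_lung = p_l * lung_volume(p_l, lung, gas) / rt
  )
}
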