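# Psychrometric and thermal closures: saturation curve, vapor concentrations,
# enthalpy stream terms (H-dot) and lumped heat-transfer terms (Q-dot).
# All units SI internally; temperatures in degC at the interface (only
# temperature differences and the ideal-gas conversion use absolute scale).

.M_W <- 0.018015       # molar mass of water [kg/mol]
.R_GAS <- 8.314462618  # universal gas constant [J/(mol K)]

#' Material property table
#'
#' Specific heat capacities, latent heat and transport properties used by the
#' enthalpy and evaporation closures.  Values are editable defaults for
#' typical pharmaceutical granulation materials; override any field via
#' \code{...}.
#'
#' @param ... named overrides of the default fields.
#' @return An object of class \code{fbg_props}: a named list with fields
#'   \code{cp_s}, \code{cp_wl}, \code{cp_wg}, \code{cp_b}, \code{cp_a},
#'   \code{cp_steel} (specific heats, J/(kg K), for dry solids, liquid water,
#'   water vapor, binder solids, dry air, wall steel), \code{lambda0} (latent
#'   heat of vaporization at the reference temperature, J/kg), \code{T0}
#'   (enthalpy reference temperature, degC), \code{rho_particle} (true
#'   particle density, kg/m^3), \code{D_w} (water-vapor diffusivity in air,
#'   m^2/s), \code{mu_air} (dynamic viscosity of air, Pa s) and
#'   \code{rho_air} (air density, kg/m^3).
#' @export
#' @examples
#' material_properties()
#' material_properties(rho_particle = 1400)
material_properties <- function(...) {
  props <- list(
    cp_s = 1100, cp_wl = 4186, cp_wg = 1900, cp_b = 1300,
    cp_a = 1006, cp_steel = 490,
    lambda0 = 2.45e6, T0 = 25,
    rho_particle = 1500, D_w = 2.6e-5,
    mu_air = 1.85e-5, rho_air = 1.10
  )
  props <- modifyList(props, list(...))
  stopifnot(all(vapply(props, function(v) is.numeric(v) && v > 0, TRUE)))
  structure(props, class = "fbg_props")
}

#' Equipment property table
#'
#' Lumped equipment constants of the two-compartment model: chamber air
#' holdup, free volume, wall mass, and constant-UA heat-transfer conductances
#' between bed, air, wall and environment.
#'
#' @param scale \code{"pilot"} (about 60 kg charge) or \code{"commercial"}
#'   (about 220 kg charge); selects a default set, which \code{...} can then
#'   override field-wise.
#' @param ... named overrides.
#' @return An object of class \code{fbg_equip}: named list with fields
#'   \code{m_air} (dry-air holdup, kg), \code{V_chamber} (free volume, m^3),
#'   \code{m_wall} (wall mass, kg), \code{UA_bed_wall}, \code{UA_air_wall},
#'   \code{UA_wall_env}, \code{UA_bed_air} (conductances, W/K), \code{A_bed}
#'   (bed cross-section for the superficial velocity, m^2), \code{T_env}
#'   (environment temperature, degC) and \code{P_atm} (pressure, Pa).
#' @export
equipment_properties <- function(scale = c("pilot", "commercial"), ...) {
  scale <- match.arg(scale)
  equip <- switch(scale,
    pilot = list(
      m_air = 1.7, V_chamber = 1.5, m_wall = 400,
      UA_bed_wall = 15, UA_air_wall = 25, UA_wall_env = 10,
      UA_bed_air = 500, A_bed = 0.5, T_env = 22, P_atm = 101325
    ),
    commercial = list(
      m_air = 6.5, V_chamber = 5.6, m_wall = 1300,
      UA_bed_wall = 45, UA_air_wall = 75, UA_wall_env = 30,
      UA_bed_air = 1800, A_bed = 1.7, T_env = 22, P_atm = 101325
    )
  )
  equip <- modifyList(equip, list(...))
  stopifnot(all(vapply(equip, function(v) is.numeric(v) && is.finite(v), TRUE)),
            all(unlist(equip[setdiff(names(equip), "T_env")]) > 0))
  structure(equip, class = "fbg_equip")
}

#' Saturation vapor pressure of water
#'
#' Magnus-form (Arden Buck) fit of the saturation pressure over liquid water,
#' valid between -20 and 150 degC.  Strictly increasing in temperature;
#' reproduces 611 Pa at 0 degC, 2339 Pa at 20 degC and one atmosphere at the
#' normal boiling point to well under a percent.
#'
#' @param T_c temperature [degC]; vectorized.
#' @return saturation pressure [Pa].
#' @export
#' @examples
#' saturation_vapor_pressure(c(0, 20, 100))
saturation_vapor_pressure <- function(T_c) {
  if (any(!is.finite(T_c)) || any(T_c < -20) || any(T_c > 150)) {
    stop("saturation_vapor_pressure: temperature outside validity range ",
         "[-20, 150] degC", call. = FALSE)
  }
  611.21 * exp((18.678 - T_c / 234.5) * T_c / (257.14 + T_c))
}

#' Water-vapor concentration in the chamber
#'
#' @param m_air_w mass of water vapor held in the chamber air [kg].
#' @param V chamber free volume [m^3].
#' @return concentration c_w [kg/m^3].
#' @export
vapor_concentration <- function(m_air_w, V) {
  stopifnot(all(m_air_w >= 0), all(V > 0))
  m_air_w / V
}

#' Saturation concentration of water vapor at a surface
#'
#' Ideal-gas conversion of the saturation pressure at the (particle surface)
#' temperature: c_sat = p_sat(T) M_w / (R T_K).
#'
#' @param T_c surface temperature [degC]; vectorized.
#' @param P total pressure [Pa]; unused by the ideal-gas form, accepted for
#'   interface completeness.
#' @return saturation concentration [kg/m^3].
#' @export
#' @examples
#' saturation_concentration(20) # about 0.0173 kg/m^3
saturation_concentration <- function(T_c, P = 101325) {
  saturation_vapor_pressure(T_c) * .M_W / (.R_GAS * (T_c + 273.15))
}

#' Water inflow carried by the inlet air
#'
#' @param x_in inlet-air mixing ratio [kg water / kg dry air].
#' @param F_air dry-air mass flow [kg/s].
#' @return water mass inflow [kg/s].
#' @export
mixing_ratio_to_flow <- function(x_in, F_air) {
  stopifnot(all(x_in >= 0), all(F_air >= 0))
  x_in * F_air
}

#' Enthalpy stream terms of the energy balances
#'
#' The H-dot terms of the bed and air energy balances, relative to the
#' reference temperature \code{props$T0}: spray liquid feed, inlet and outlet
#' moist air (outlet at the well-mixed chamber humidity \code{x}), and the
#' evaporation stream carrying the full latent plus vapor-sensible enthalpy
#' from the bed into the air.
#'
#' @param state list with \code{T_bed}, \code{T_air} [degC] and \code{x}
#'   (chamber mixing ratio, kg/kg).
#' @param inputs list with \code{F_spray}, \code{F_air} [kg/s], \code{w_s}
#'   (binder solids weight fraction), \code{T_spray}, \code{T_in} [degC],
#'   \code{x_in} [kg/kg] and \code{m_evap} [kg/s].
#' @param props \code{\link{material_properties}}.
#' @return named list \code{H_spray}, \code{H_air_in}, \code{H_air_out},
#'   \code{H_evap}, all in W.
#' @export
enthalpy_rates <- function(state, inputs, props) {
  T0 <- props$T0
  H_spray <- inputs$F_spray *
    ((1 - inputs$w_s) * props$cp_wl + inputs$w_s * props$cp_b) *
    (inputs$T_spray - T0)
  H_air_in <- inputs$F_air * (props$cp_a + inputs$x_in * props$cp_wg) *
    (inputs$T_in - T0)
  H_air_out <- inputs$F_air * (props$cp_a + state$x * props$cp_wg) *
    (state$T_air - T0)
  H_evap <- inputs$m_evap * (props$lambda0 + props$cp_wg * (state$T_bed - T0))
  list(H_spray = H_spray, H_air_in = H_air_in,
       H_air_out = H_air_out, H_evap = H_evap)
}

#' Lumped heat-transfer terms
#'
#' Constant-UA convective closures between bed, air, wall and environment.
#' Sign convention: \code{Q_x_y = UA_xy (T_x - T_y)}, positive when heat
#' flows from x to y.
#'
#' @param T_bed,T_air,T_wall temperatures [degC].
#' @param equip \code{\link{equipment_properties}}.
#' @return named list \code{Q_bed_wall}, \code{Q_bed_air}, \code{Q_air_wall},
#'   \code{Q_wall_env}, all in W.
#' @export
heat_transfer_rates <- function(T_bed, T_air, T_wall, equip) {
  list(
    Q_bed_wall = equip$UA_bed_wall * (T_bed - T_wall),
    Q_bed_air  = equip$UA_bed_air * (T_bed - T_air),
    Q_air_wall = equip$UA_air_wall * (T_air - T_wall),
    Q_wall_env = equip$UA_wall_env * (T_wall - equip$T_env)
  )
}
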