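# The core digital twin: evaporation closures, flow correction factors, and
# phase-by-phase stiff integration of the six-state heat- and mass-balance
# ODE system over a recipe.  A readable R right-hand side (fbg_rhs) serves as
# the reference; simulate_recipe() uses the identical compiled C version for
# speed (tested to agree to machine precision).

#' Model parameters of the evaporation closure
#'
#' @param theta_p effective particle (exchange) size [m], > 0.  Enters both
#'   the available surface area and the Reynolds-number part of the transfer
#'   coefficient.
#' @param theta_e evaporation-efficiency scale [LOD \%], > 0.
#' @param alpha_spray,alpha_air linear flow correction factors (dimensionless,
#'   default 1): actual flow = alpha x setpoint.  Fixed per product.
#' @param covariance covariance matrix of the estimates: 2x2 over
#'   (theta_p, theta_e), or 4x4 when the alphas were fitted too.  Defaults to
#'   the zero matrix (parameters treated as known).
#' @return object of class \code{fbg_params}.
#' @export
model_parameters <- function(theta_p, theta_e, alpha_spray = 1, alpha_air = 1,
                             covariance = matrix(0, 2, 2)) {
  stopifnot(theta_p > 0, theta_e > 0, alpha_spray > 0, alpha_air > 0,
            is.matrix(covariance), nrow(covariance) %in% c(2, 4),
            nrow(covariance) == ncol(covariance))
  if (max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance))))
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("covariance must be positive semidefinite", call. = FALSE)
  nm <- c("theta_p", "theta_e", "alpha_spray", "alpha_air")[
    seq_len(nrow(covariance))]
  dimnames(covariance) <- list(nm, nm)
  structure(list(theta_p = theta_p, theta_e = theta_e,
                 alpha_spray = alpha_spray, alpha_air = alpha_air,
                 covariance = covariance),
            class = "fbg_params")
}

#' @export
print.fbg_params <- function(x, ...) {
  cat(sprintf("<fbg_params> theta_p = %.4g m, theta_e = %.4g LOD%%, ",
              x$theta_p, x$theta_e),
      sprintf("alpha_spray = %.4g, alpha_air = %.4g\n",
              x$alpha_spray, x$alpha_air))
  if (any(x$covariance != 0)) {
    cat("covariance:\n"); print(x$covariance)
  }
  invisible(x)
}

#' Loss-on-drying of a bed state
#'
#' LOD = 100 m_bed_w / (m_bed_w + m_bed_s + m_bed_b): percent water by total
#' wet bed mass.
#'
#' @param m_bed_w liquid water in the bed [kg].
#' @param m_bed_s dry solids charge [kg].
#' @param m_bed_b binder solids in the bed [kg].
#' @return LOD [\%], in [0, 100).  Vectorized.
#' @export
loss_on_drying <- function(m_bed_w, m_bed_s, m_bed_b = 0) {
  tot <- m_bed_w + m_bed_s + m_bed_b
  if (any(tot <= 0)) stop("empty bed: total bed mass must be > 0",
                          call. = FALSE)
  100 * pmax(m_bed_w, 0) / tot
}

#' Evaporation efficiency
#'
#' eta = min(exp(LOD / theta_e) - 1, 1): mass transfer becomes effectively
#' less efficient at lower moisture contents; saturates at 1 above
#' LOD = theta_e ln 2.
#'
#' @param lod loss-on-drying [\%], >= 0.  Vectorized.
#' @param theta_e efficiency scale [LOD \%], > 0.
#' @return eta in [0, 1], nondecreasing in \code{lod}.
#' @export
evaporation_efficiency <- function(lod, theta_e) {
  stopifnot(all(lod >= 0), theta_e > 0)
  pmin(expm1(lod / theta_e), 1)
}

#' Available particle surface area
#'
#' Monodisperse spheres of time-invariant effective size theta_p at the true
#' particle density: N_p = 6 m_solid / (rho pi theta_p^3), giving
#' A_p = N_p pi theta_p^2 = 6 m_solid / (rho theta_p).
#'
#' @param theta_p effective particle size [m].
#' @param m_solid total solid mass (charge + binder) [kg].
#' @param rho_particle true particle density [kg/m^3].
#' @return A_p [m^2].
#' @export
#' @examples
#' particle_surface_area(200e-6, 60, 1500) # 1200 m^2
particle_surface_area <- function(theta_p, m_solid, rho_particle) {
  stopifnot(all(theta_p > 0), all(m_solid > 0), all(rho_particle > 0))
  6 * m_solid / (rho_particle * theta_p)
}

#' Mass transfer coefficient
#'
#' k = k0(theta_p) eta, with k0 from the Ranz-Marshall correlation
#' Sh = 2 + 0.6 Re^(1/2) Sc^(1/3) and k0 = Sh D_w / theta_p.  The Reynolds
#' number uses the superficial velocity u = F_air / (rho_air A_bed).
#'
#' @param theta_p effective particle size [m].
#' @param eta evaporation efficiency in [0, 1].
#' @param F_air dry-air mass flow [kg/s].
#' @param props \code{\link{material_properties}} (supplies \code{D_w},
#'   \code{mu_air}, \code{rho_air}).
#' @param equip \code{\link{equipment_properties}} (supplies \code{A_bed}).
#' @return k [m/s]; 0 when \code{eta = 0}.
#' @export
mass_transfer_coefficient <- function(theta_p, eta, F_air, props, equip) {
  stopifnot(all(eta >= 0), all(eta <= 1), all(theta_p > 0))
  if (props$D_w <= 0) stop("nonpositive diffusivity D_w", call. = FALSE)
  u <- F_air / (props$rho_air * equip$A_bed)
  Re <- props$rho_air * u * theta_p / props$mu_air
  Sc <- props$mu_air / (props$rho_air * props$D_w)
  Sh <- 2 + 0.6 * sqrt(Re) * Sc^(1 / 3)
  (Sh * props$D_w / theta_p) * eta
}

#' Evaporation rate
#'
#' m_evap = k A_p (c_sat(T_bed) - c_w), floored at zero (no condensation)
#' and zero once the bed water is exhausted.
#'
#' @param state list with \code{m_bed_w}, \code{m_bed_b}, \code{m_air_w}
#'   [kg] and \code{T_bed} [degC]; \code{m_bed_s} taken from \code{m_bed_s}.
#' @param m_bed_s dry solids charge [kg].
#' @param F_air dry-air flow [kg/s] (for the Reynolds number).
#' @param params \code{\link{model_parameters}}.
#' @param props \code{\link{material_properties}}.
#' @param equip \code{\link{equipment_properties}}.
#' @return m_evap [kg/s], >= 0.
#' @export
evaporation_rate <- function(state, m_bed_s, F_air, params, props, equip) {
  if (state$m_bed_w <= 0) return(0)
  lod <- loss_on_drying(state$m_bed_w, m_bed_s, state$m_bed_b)
  eta <- evaporation_efficiency(lod, params$theta_e)
  Ap <- particle_surface_area(params$theta_p, m_bed_s + state$m_bed_b,
                              props$rho_particle)
  k <- mass_transfer_coefficient(params$theta_p, eta, F_air, props, equip)
  drive <- saturation_concentration(state$T_bed) -
    vapor_concentration(state$m_air_w, equip$V_chamber)
  k * Ap * max(drive, 0)
}

#' Corrected flows
#'
#' F_i = alpha_i F_i_set: linear correction factors absorbing calibration
#' offsets of the flow sensors; fixed per product across a campaign.
#'
#' @param F_spray_set,F_air_set setpoints [kg/s].
#' @param params \code{\link{model_parameters}}.
#' @return named list \code{F_spray}, \code{F_air} [kg/s].
#' @export
corrected_flows <- function(F_spray_set, F_air_set, params) {
  stopifnot(all(F_spray_set >= 0), all(F_air_set >= 0))
  list(F_spray = params$alpha_spray * F_spray_set,
       F_air = params$alpha_air * F_air_set)
}

# parameter vector handed to the compiled rhs; order mirrored in src/fbg_rhs.c
.fbg_parms_vector <- function(inputs, params, props, equip, m_bed_s) {
  c(inputs$w_s, inputs$F_spray, inputs$F_air, inputs$T_in, inputs$x_in,
    inputs$T_spray,
    params$theta_p, params$theta_e,
    props$cp_s, props$cp_wl, props$cp_wg, props$cp_b, props$cp_a,
    props$cp_steel, props$lambda0, props$T0, props$rho_particle, props$D_w,
    props$mu_air, props$rho_air,
    equip$m_air, equip$V_chamber, equip$m_wall, equip$UA_bed_wall,
    equip$UA_air_wall, equip$UA_wall_env, equip$UA_bed_air, equip$A_bed,
    equip$T_env, equip$P_atm,
    m_bed_s)
}

#' Right-hand side of the two-compartment model (reference implementation)
#'
#' Time derivatives of the eight-element state vector
#' \code{(m_bed_w, m_bed_b, m_air_w, T_bed, T_air, T_wall, cum_w_out,
#' cum_H_out)}; the last two are running integrals of the water leaving with
#' the exhaust air and of the outgoing enthalpy streams, used by the
#' conservation diagnostics.  \code{simulate_recipe} integrates the identical
#' compiled version of this function.
#'
#' @param t time [s] (the system is autonomous within a phase).
#' @param state numeric state vector of length 6 or 8 (accumulators assumed 0
#'   if missing).
#' @param inputs list of phase inputs: \code{F_spray}, \code{F_air} (already
#'   alpha-corrected, kg/s), \code{T_in}, \code{T_spray} [degC], \code{x_in}
#'   [kg/kg], \code{w_s}.
#' @param params,props,equip model parameter and property tables.
#' @param m_bed_s dry solids charge [kg].
#' @return list whose first element is the derivative vector (deSolve
#'   convention), followed by diagnostic scalars \code{m_evap}, \code{lod},
#'   \code{x}.
#' @export
fbg_rhs <- function(t, state, inputs, params, props, equip, m_bed_s) {
  if (length(state) == 6) state <- c(state, 0, 0)
  m_bed_w <- max(state[1], 0); m_bed_b <- max(state[2], 0)
  m_air_w <- max(state[3], 0)
  T_bed <- state[4]; T_air <- state[5]; T_wall <- state[6]
  if (any(!is.finite(state)))
    stop("non-finite state: ", paste(signif(state, 6), collapse = ", "),
         call. = FALSE)

  st <- list(m_bed_w = m_bed_w, m_bed_b = m_bed_b, m_air_w = m_air_w,
             T_bed = T_bed)
  m_evap <- evaporation_rate(st, m_bed_s, inputs$F_air, params, props, equip)
  if (state[1] <= 0) m_evap <- 0
  x <- m_air_w / equip$m_air

  d_m_bed_w <- (1 - inputs$w_s) * inputs$F_spray - m_evap
  d_m_bed_b <- inputs$w_s * inputs$F_spray
  d_m_air_w <- inputs$F_air * (inputs$x_in - x) + m_evap

  H <- enthalpy_rates(list(T_bed = T_bed, T_air = T_air, x = x),
                      c(inputs, list(m_evap = m_evap)), props)
  Q <- heat_transfer_rates(T_bed, T_air, T_wall, equip)

  C_bed <- m_bed_s * props$cp_s + m_bed_w * props$cp_wl + m_bed_b * props$cp_b
  d_T_bed <- (H$H_spray - H$H_evap - Q$Q_bed_wall - Q$Q_bed_air -
                (T_bed - props$T0) *
                (d_m_bed_w * props$cp_wl + d_m_bed_b * props$cp_b)) / C_bed
  C_air <- equip$m_air * props$cp_a + m_air_w * props$cp_wg
  d_T_air <- (H$H_air_in - H$H_air_out + H$H_evap + Q$Q_bed_air -
                Q$Q_air_wall -
                (T_air - props$T0) * d_m_air_w * props$cp_wg) / C_air
  d_T_wall <- (Q$Q_bed_wall + Q$Q_air_wall - Q$Q_wall_env) /
    (equip$m_wall * props$cp_steel)

  deriv <- c(d_m_bed_w, d_m_bed_b, d_m_air_w, d_T_bed, d_T_air, d_T_wall,
             inputs$F_air * x, H$H_air_out + Q$Q_wall_env)
  if (any(!is.finite(deriv)))
    stop("non-finite derivative at t = ", t, "; state = ",
         paste(signif(state, 6), collapse = ", "), call. = FALSE)
  list(deriv, m_evap = m_evap,
       lod = loss_on_drying(m_bed_w, m_bed_s, m_bed_b), x = x)
}

# initial 8-state vector from a recipe
.initial_state <- function(recipe, equip) {
  m_bed_w0 <- recipe$m_solids_0 * recipe$lod_0 / (100 - recipe$lod_0)
  x0 <- recipe$phases[[1]]$x_in
  c(m_bed_w = m_bed_w0, m_bed_b = 0, m_air_w = x0 * equip$m_air,
    T_bed = recipe$T_bed_0, T_air = recipe$T_air_0, T_wall = recipe$T_wall_0,
    cum_w_out = 0, cum_H_out = 0)
}

#' Simulate a recipe
#'
#' Integrates the model phase by phase with a stiff multistep solver
#' (\code{deSolve::ode}, lsoda), state continuous across phase boundaries and
#' setpoints piecewise constant per phase.  Deterministic for fixed inputs.
#'
#' @param recipe an \code{fbg_recipe}.
#' @param params \code{\link{model_parameters}}.
#' @param props \code{\link{material_properties}}.
#' @param equip \code{\link{equipment_properties}}.
#' @param output_dt output grid spacing [s]; phase boundaries are always grid
#'   points.
#' @param rtol,atol_mass,atol_temp solver tolerances (relative; absolute on
#'   masses [kg] and temperatures [degC]).
#' @param compiled use the compiled C right-hand side (default) or the R
#'   reference.
#' @return An object of class \code{fbg_trajectory}: a data.frame with
#'   columns \code{t}, \code{m_bed_w}, \code{m_bed_b}, \code{m_air_w},
#'   \code{T_bed}, \code{T_air}, \code{T_wall}, \code{lod}, \code{x_out},
#'   \code{m_evap}, \code{phase}, and attributes \code{lod_max},
#'   \code{t_at_lod_max}, \code{recipe}, \code{conservation} (see
#'   \code{\link{conservation_residuals}}).
#' @export
simulate_recipe <- function(recipe, params, props = material_properties(),
                            equip = equipment_properties(),
                            output_dt = 10, rtol = 1e-8, atol_mass = 1e-10,
                            atol_temp = 1e-8, compiled = TRUE) {
  validate_recipe(recipe)
  y <- .initial_state(recipe, equip)
  atol <- c(rep(atol_mass, 3), rep(atol_temp, 3), atol_mass, 1e-2)
  tab <- phase_table(recipe)
  rows <- vector("list", nrow(tab))
  t_off <- 0
  for (i in seq_len(nrow(tab))) {
    ph <- recipe$phases[[i]]
    fl <- corrected_flows(ph$F_spray_set, ph$F_air_set, params)
    inputs <- list(w_s = recipe$w_s, F_spray = fl$F_spray, F_air = fl$F_air,
                   T_in = ph$T_in_set, x_in = ph$x_in,
                   T_spray = recipe$T_spray)
    times <- unique(c(seq(0, ph$duration, by = output_dt), ph$duration))
    sol <- if (compiled) {
      pv <- .fbg_parms_vector(inputs, params, props, equip, recipe$m_solids_0)
      deSolve::ode(y = y, times = times, func = "fbg_derivs",
                   parms = pv, dllname = "fbgtwin", initfunc = "fbg_init",
                   method = "lsoda", rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y = y, times = times,
                   func = function(t, y, p)
                     fbg_rhs(t, y, inputs, params, props, equip,
                             recipe$m_solids_0)[1],
                   parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
    }
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed in phase '", ph$name, "'", call. = FALSE)
    y <- sol[nrow(sol), -1]
    y[1:3] <- pmax(y[1:3], 0)
    block <- as.data.frame(unclass(sol))
    names(block) <- c("t", names(.initial_state(recipe, equip)))
    block$t <- block$t + t_off
    block$phase <- ph$name
    # drop the phase-start row except for the very first phase
    rows[[i]] <- if (i == 1) block else block[-1, , drop = FALSE]
    t_off <- t_off + ph$duration
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # clamp tiny solver undershoots in the reported mass columns
  out$m_bed_w <- pmax(out$m_bed_w, 0)
  out$m_bed_b <- pmax(out$m_bed_b, 0)
  out$m_air_w <- pmax(out$m_air_w, 0)
  out$lod <- loss_on_drying(out$m_bed_w, recipe$m_solids_0, out$m_bed_b)
  out$x_out <- out$m_air_w / equip$m_air
  out$m_evap <- .trajectory_m_evap(out, recipe, params, props, equip)
  imax <- which.max(out$lod)
  structure(out, class = c("fbg_trajectory", "data.frame"),
            lod_max = out$lod[imax], t_at_lod_max = out$t[imax],
            recipe = recipe, params = params, props = props, equip = equip)
}

# vectorized re-evaluation of m_evap along a stored trajectory
.trajectory_m_evap <- function(out, recipe, params, props, equip) {
  eta <- evaporation_efficiency(out$lod, params$theta_e)
  Ap <- particle_surface_area(params$theta_p,
                              recipe$m_solids_0 + out$m_bed_b,
                              props$rho_particle)
  tab <- phase_table(recipe)
  F_air_set <- tab$F_air_set[match(out$phase, tab$name)]
  F_air <- params$alpha_air * F_air_set
  k <- mass_transfer_coefficient(params$theta_p, eta, F_air, props, equip)
  drive <- pmax(saturation_concentration(out$T_bed) -
                  vapor_concentration(out$m_air_w, equip$V_chamber), 0)
  ifelse(out$m_bed_w <= 0, 0, k * Ap * drive)
}

#' Maximum LOD of a trajectory
#' @param traj an \code{fbg_trajectory}.
#' @return named list \code{lod_max} [\%] and \code{t_at_lod_max} [s].
#' @export
lod_max <- function(traj) {
  list(lod_max = attr(traj, "lod_max"),
       t_at_lod_max = attr(traj, "t_at_lod_max"))
}

#' @export
print.fbg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fbg_trajectory> %d points over %.1f min; lod_max = %.3f%% at %.1f min\n",
    nrow(x), max(x$t) / 60, attr(x, "lod_max"), attr(x, "t_at_lod_max") / 60))
  invisible(x)
}

#' @export
plot.fbg_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$t / 60, x$lod, type = "l", xlab = "time [min]", ylab = "LOD [%]",
       ...)
  graphics::abline(v = cumsum(vapply(attr(x, "recipe")$phases, `[[`, 0,
                                     "duration")) / 60,
                   lty = 3, col = "grey")
  graphics::matplot(x$t / 60, cbind(x$T_bed, x$T_air, x$T_wall), type = "l",
                    lty = 1, xlab = "time [min]", ylab = "T [degC]")
  graphics::legend("bottomright", c("bed", "air", "wall"), col = 1:3,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns \code{t_s,lod_pct,T_bed_C,T_air_C,T_wall_C,x_out_gkg,m_evap_kgs}.
#'
#' @param traj an \code{fbg_trajectory}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(data.frame(t_s = traj$t, lod_pct = traj$lod,
                       T_bed_C = traj$T_bed, T_air_C = traj$T_air,
                       T_wall_C = traj$T_wall, x_out_gkg = traj$x_out * 1000,
                       m_evap_kgs = traj$m_evap),
            path, row.names = FALSE)
  invisible(path)
}

#' Conservation residuals of a simulated trajectory
#'
#' Water closure: change of (bed + air) water minus the net piecewise-analytic
#' inflow plus the integrated exhaust outflow, relative to the total water
#' throughput.  Solids closure: final binder mass against w_s x integral of
#' the spray rate.  Energy closure: change of the sensible enthalpy inventory
#' of bed + air + wall against the integrated boundary streams
#' (spray + inlet air - outlet air - wall loss), relative to the largest
#' cumulative stream.  The exhaust-water and outgoing-enthalpy integrals are
#' carried as auxiliary ODE states, so the residuals measure model and solver
#' consistency, not quadrature error.
#'
#' @param traj an \code{fbg_trajectory}.
#' @return named list \code{water_rel}, \code{solids_rel}, \code{energy_rel}
#'   (relative residuals).
#' @export
conservation_residuals <- function(traj) {
  recipe <- attr(traj, "recipe"); params <- attr(traj, "params")
  props <- attr(traj, "props"); equip <- attr(traj, "equip")
  tab <- phase_table(recipe)
  F_spray <- params$alpha_spray * tab$F_spray_set
  F_air <- params$alpha_air * tab$F_air_set
  dur <- tab$duration
  n <- nrow(traj)

  water_in <- sum((1 - recipe$w_s) * F_spray * dur) +
    sum(F_air * tab$x_in * dur)
  water_out <- traj$cum_w_out[n]
  d_water <- (traj$m_bed_w[n] + traj$m_air_w[n]) -
    (traj$m_bed_w[1] + traj$m_air_w[1])
  throughput <- max(water_in, water_out, abs(d_water), 1e-12)
  water_rel <- abs(d_water - (water_in - water_out)) / throughput

  solids_rel <- abs(traj$m_bed_b[n] - recipe$w_s * sum(F_spray * dur)) /
    max(recipe$w_s * sum(F_spray * dur), 1e-12)

  T0 <- props$T0
  E <- function(i) {
    (recipe$m_solids_0 * props$cp_s + traj$m_bed_w[i] * props$cp_wl +
       traj$m_bed_b[i] * props$cp_b) * (traj$T_bed[i] - T0) +
      (equip$m_air * props$cp_a + traj$m_air_w[i] * props$cp_wg) *
        (traj$T_air[i] - T0) +
      equip$m_wall * props$cp_steel * (traj$T_wall[i] - T0)
  }
  H_spray <- sum(F_spray * ((1 - recipe$w_s) * props$cp_wl +
                              recipe$w_s * props$cp_b) *
                   (recipe$T_spray - T0) * dur)
  H_air_in <- sum(F_air * (props$cp_a + tab$x_in * props$cp_wg) *
                    (tab$T_in_set - T0) * dur)
  E_out <- traj$cum_H_out[n]
  scale <- max(abs(H_spray) + abs(H_air_in), E_out, abs(E(n) - E(1)), 1)
  energy_rel <- abs((E(n) - E(1)) - (H_spray + H_air_in - E_out)) / scale

  list(water_rel = water_rel, solids_rel = solids_rel,
       energy_rel = energy_rel)
}
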