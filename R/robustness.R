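# Input-variability ("risk fingerprint") analysis: enumeration of the four
# scenario sets, deviation scoring, design-space checking, and the
# maximum-tolerable-deviation search, all at several inlet-air humidity
# levels and for both wet and dry coordinated deviations.
#
# Scenario sets:
#   I   fixed 2-sigma deviations; all nonempty combinations of the three
#       deviatable parameters x all nonempty subsets of the spray subphases.
#   II  one parameter in one spray subphase; magnitude searched on an
#       integer sigma grid (default 1..30).
#   III six 5-minute pulses uniformly spaced over the spray phase; parameter
#       subsets of size 1..3; magnitude searched (default 1..20).
#   IV  one parameter offset over the whole spray phase (a calibration
#       error); magnitude searched (default 1..20).

#' Construct a scenario specification
#'
#' Usually produced by \code{\link{build_scenarios}}.
#'
#' @param set_id \code{"I"}, \code{"II"}, \code{"III"} or \code{"IV"}.
#' @param direction \code{"wet"} or \code{"dry"}.
#' @param humidity_gkg inlet-air mixing ratio level [g/kg].
#' @param params character subset of the deviatable parameters.
#' @param spray_subphases affected spray subphase indices.
#' @param magnitude deviation magnitude [sigma]; \code{NA} when searched.
#' @param pulses optional pulse windows (data.frame \code{start},
#'   \code{duration} [s]).
#' @param n_phases_affected phase count entering the deviation score;
#'   defaults to \code{length(spray_subphases)}.  Set III uses 1 (the pulsed
#'   30-minute disturbance counts as one event, so its scores are 1..3).
#' @return object of class \code{fbg_scenario}.
#' @export
scenario_spec <- function(set_id, direction, humidity_gkg, params,
                          spray_subphases, magnitude = NA_real_,
                          pulses = NULL,
                          n_phases_affected = length(spray_subphases)) {
  stopifnot(set_id %in% c("I", "II", "III", "IV"),
            direction %in% c("wet", "dry"),
            humidity_gkg >= 0, length(params) >= 1)
  structure(list(set_id = set_id, direction = direction,
                 humidity_gkg = humidity_gkg,
                 params = unique(as.character(params)),
                 spray_subphases = sort(unique(as.integer(spray_subphases))),
                 magnitude = magnitude, pulses = pulses,
                 n_phases_affected = as.integer(n_phases_affected)),
            class = "fbg_scenario")
}

#' Deviation score of a scenario
#'
#' Product of the number of process parameters varying and the number of
#' granulation (spray sub)phases affected; a surrogate for the scenario's
#' improbability.  A zero-magnitude scenario scores 0.
#'
#' @param spec an \code{fbg_scenario}.
#' @return integer score.
#' @export
#' @examples
#' # three parameters over all five subphases: the worst case, score 15
deviation_score <- function(spec) {
  if (!is.na(spec$magnitude) && spec$magnitude == 0) return(0L)
  length(spec$params) * spec$n_phases_affected
}

.nonempty_subsets <- function(x) {
  n <- length(x)
  unlist(lapply(seq_len(n), function(k)
    utils::combn(x, k, simplify = FALSE)), recursive = FALSE)
}

#' Enumerate the scenarios of one scenario set
#'
#' @param set_id \code{"I"}..\code{"IV"}.
#' @param recipe the nominal \code{fbg_recipe}; must contain spray subphases.
#' @param humidity_levels inlet-air humidity levels [g/kg].
#' @param directions deviation directions to include.
#' @param params deviatable parameters (default all three).
#' @param magnitude fixed magnitude for set I [sigma].
#' @param pulse_count,pulse_duration set III pulse schedule (default six
#'   5-minute pulses, uniformly spaced over the spray phase).
#' @return list of \code{\link{scenario_spec}} objects.
#' @export
build_scenarios <- function(set_id, recipe,
                            humidity_levels = c(1, 5, 10),
                            directions = c("wet", "dry"),
                            params = c("T_in", "F_air", "F_spray"),
                            magnitude = 2,
                            pulse_count = 6, pulse_duration = 300) {
  stopifnot(set_id %in% c("I", "II", "III", "IV"))
  spray_idx <- .spray_phase_indices(recipe)
  if (length(spray_idx) == 0)
    stop("recipe has no spray subphases", call. = FALSE)
  nsub <- length(spray_idx)
  subphases <- seq_len(nsub)

  specs <- list()
  for (h in humidity_levels) for (d in directions) {
    new <- switch(set_id,
      I = {
        combos <- expand.grid(p = seq_along(.nonempty_subsets(params)),
                              f = seq_along(.nonempty_subsets(subphases)))
        psub <- .nonempty_subsets(params)
        fsub <- .nonempty_subsets(subphases)
        lapply(seq_len(nrow(combos)), function(i)
          scenario_spec("I", d, h, psub[[combos$p[i]]],
                        fsub[[combos$f[i]]], magnitude = magnitude))
      },
      II = {
        combos <- expand.grid(p = params, f = subphases,
                              stringsAsFactors = FALSE)
        lapply(seq_len(nrow(combos)), function(i)
          scenario_spec("II", d, h, combos$p[i], combos$f[i]))
      },
      III = {
        tab <- phase_table(recipe)
        t0 <- tab$t_start[spray_idx[1]]
        t1 <- tab$t_end[spray_idx[nsub]]
        slot <- (t1 - t0) / pulse_count
        if (pulse_duration > slot)
          stop("set III pulses overlap: spray phase too short for ",
               pulse_count, " pulses of ", pulse_duration, " s",
               call. = FALSE)
        pulses <- data.frame(start = t0 + (seq_len(pulse_count) - 1) * slot,
                             duration = pulse_duration)
        lapply(.nonempty_subsets(params), function(ps)
          scenario_spec("III", d, h, ps, subphases, pulses = pulses,
                        n_phases_affected = 1L))
      },
      IV = lapply(params, function(p)
        scenario_spec("IV", d, h, p, subphases))
    )
    specs <- c(specs, new)
  }
  specs
}

# humidity-resolved recipe: either override x_in on the single recipe, or
# delegate to a user-supplied function(h_gkg) -> recipe
.recipe_at_humidity <- function(recipe, h_gkg) {
  if (is.function(recipe)) recipe(h_gkg)
  else set_humidity(recipe, h_gkg)
}

#' Run a single disturbance scenario
#'
#' Sets the scenario's humidity level on the recipe, applies the disturbance
#' profile, simulates, and checks the maximum LOD against the design space.
#'
#' @param recipe nominal \code{fbg_recipe} (or a \code{function(h_gkg)}
#'   returning the humidity-group recipe).
#' @param params calibrated \code{\link{model_parameters}}.
#' @param spec an \code{\link{scenario_spec}}; its magnitude must be set
#'   (possibly via \code{magnitude}).
#' @param sigmas \code{\link{parameter_std_devs}}.
#' @param ds \code{\link{design_space}}.
#' @param magnitude overrides \code{spec$magnitude} (used by the searches).
#' @param props,equip,output_dt simulation settings.
#' @return one-row data.frame: \code{set_id}, \code{direction},
#'   \code{humidity_gkg}, \code{magnitude}, \code{n_params},
#'   \code{n_phases}, \code{score}, \code{lod_max}, \code{in_range}.
#' @export
run_scenario <- function(recipe, params, spec, sigmas, ds,
                         magnitude = spec$magnitude,
                         props = material_properties(),
                         equip = equipment_properties(), output_dt = 30) {
  stopifnot(inherits(spec, "fbg_scenario"), !is.na(magnitude))
  rec <- .recipe_at_humidity(recipe, spec$humidity_gkg)
  if (magnitude > 0) {
    profile <- disturbance_profile(spec$params, spec$spray_subphases,
                                   magnitude, spec$direction,
                                   pulses = spec$pulses)
    rec <- withCallingHandlers(
      apply_disturbance(rec, profile, sigmas),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  traj <- tryCatch(
    simulate_recipe(rec, params, props, equip, output_dt = output_dt),
    error = function(e)
      stop("scenario (set ", spec$set_id, ", ", spec$direction, ", ",
           spec$humidity_gkg, " g/kg, ", paste(spec$params, collapse = "+"),
           "): ", conditionMessage(e), call. = FALSE))
  lm <- attr(traj, "lod_max")
  spec$magnitude <- magnitude
  data.frame(set_id = spec$set_id, direction = spec$direction,
             humidity_gkg = spec$humidity_gkg, magnitude = magnitude,
             n_params = length(spec$params),
             n_phases = spec$n_phases_affected,
             score = deviation_score(spec),
             lod_max = lm, in_range = in_design_space(lm, ds),
             stringsAsFactors = FALSE)
}

#' Fraction of out-of-range runs by deviation score
#'
#' Set I metric: per deviation score, the fraction of simulations whose
#' maximum LOD left the design space.  Non-monotone behaviour in the score is
#' reported as-is.
#'
#' @param results data.frame of \code{\link{run_scenario}} rows.
#' @return data.frame \code{score}, \code{n}, \code{n_out},
#'   \code{fraction_out} (empty for empty input).
#' @export
fraction_out_by_score <- function(results) {
  if (NROW(results) == 0)
    return(data.frame(score = integer(), n = integer(), n_out = integer(),
                      fraction_out = numeric()))
  agg <- aggregate(cbind(n = 1, n_out = !results$in_range),
                   by = list(score = results$score), FUN = sum)
  agg$fraction_out <- agg$n_out / agg$n
  agg[order(agg$score), ]
}

#' Maximum tolerable input deviation
#'
#' Evaluates the scenario at every integer magnitude of \code{search_range}
#' and returns the largest magnitude whose maximum LOD stays inside the
#' design space (the full grid is evaluated: the response need not be
#' monotone in the magnitude).  Returns the range top when the design space
#' is never left (capped), and a flagged result when already the nominal
#' (zero-deviation) run is out of range.
#'
#' @param recipe,params,spec,sigmas,ds,props,equip,output_dt as in
#'   \code{\link{run_scenario}}.
#' @param search_range integer sigma grid, e.g. \code{1:30}.
#' @return list: \code{sigma_star} (largest in-range magnitude; 0 if none;
#'   \code{NA} when the nominal run is out of range), \code{capped} (TRUE if
#'   the whole grid stayed in range), \code{nominal_in}, \code{grid}
#'   (data.frame \code{magnitude}, \code{lod_max}, \code{in_range}).
#' @export
max_tolerable_deviation <- function(recipe, params, spec, sigmas, ds,
                                    search_range = 1:30,
                                    props = material_properties(),
                                    equip = equipment_properties(),
                                    output_dt = 30) {
  stopifnot(all(search_range == round(search_range)),
            all(search_range > 0))
  nominal <- run_scenario(recipe, params, spec, sigmas, ds, magnitude = 0,
                          props = props, equip = equip,
                          output_dt = output_dt)
  rows <- lapply(sort(search_range), function(m)
    run_scenario(recipe, params, spec, sigmas, ds, magnitude = m,
                 props = props, equip = equip, output_dt = output_dt))
  grid <- do.call(rbind, rows)[, c("magnitude", "lod_max", "in_range")]
  if (!nominal$in_range)
    return(list(sigma_star = NA_real_, capped = FALSE, nominal_in = FALSE,
                grid = grid))
  in_r <- grid$magnitude[grid$in_range]
  list(sigma_star = if (length(in_r)) max(in_r) else 0,
       capped = all(grid$in_range), nominal_in = TRUE, grid = grid)
}

#' Risk fingerprint of a process
#'
#' Runs the requested scenario sets at every humidity level and both
#' deviation directions, and aggregates the two robustness metrics: set I,
#' the fraction of out-of-design-space runs by deviation score; sets II-IV,
#' the maximum tolerable deviation in sigma (per parameter and subphase for
#' set II, per parameter subset for set III, per parameter for set IV).
#' Deterministic: no hidden randomness.
#'
#' @param recipe nominal \code{fbg_recipe}, or a \code{function(h_gkg)}
#'   returning the humidity-group recipe to emulate feed-forward humidity
#'   compensation.
#' @param params calibrated \code{\link{model_parameters}}.
#' @param sigmas \code{\link{parameter_std_devs}}.
#' @param ds \code{\link{design_space}}.
#' @param humidity_levels [g/kg]; default 1 (dry extreme), 5 (target),
#'   10 (wet extreme).
#' @param sets subset of \code{c("I","II","III","IV")}.
#' @param directions subset of \code{c("wet","dry")}.
#' @param range_II,range_III,range_IV integer sigma search grids.
#' @param props,equip,output_dt simulation settings.
#' @return An object of class \code{fbg_fingerprint}: list with
#'   \code{nominal} (per-humidity nominal \code{lod_max} and range check),
#'   one data.frame per requested set (\code{set_I} ... \code{set_IV}), the
#'   \code{design_space}, and \code{meta}.
#' @export
risk_fingerprint <- function(recipe, params, sigmas, ds,
                             humidity_levels = c(1, 5, 10),
                             sets = c("I", "II", "III", "IV"),
                             directions = c("wet", "dry"),
                             range_II = 1:30, range_III = 1:20,
                             range_IV = 1:20,
                             props = material_properties(),
                             equip = equipment_properties(),
                             output_dt = 30) {
  out <- list(design_space = ds,
              meta = list(humidity_levels = humidity_levels, sets = sets,
                          directions = directions, sigmas = sigmas))
  base_recipe <- if (is.function(recipe)) recipe(humidity_levels[1])
                 else recipe

  nom <- do.call(rbind, lapply(humidity_levels, function(h) {
    traj <- simulate_recipe(.recipe_at_humidity(recipe, h), params, props,
                            equip, output_dt = output_dt)
    data.frame(humidity_gkg = h, lod_max = attr(traj, "lod_max"),
               in_range = in_design_space(attr(traj, "lod_max"), ds))
  }))
  out$nominal <- nom

  if ("I" %in% sets) {
    specs <- build_scenarios("I", base_recipe, humidity_levels, directions)
    res <- do.call(rbind, lapply(specs, function(sp)
      run_scenario(recipe, params, sp, sigmas, ds, props = props,
                   equip = equip, output_dt = output_dt)))
    frac <- do.call(rbind, lapply(split(res,
                                        list(res$direction,
                                             res$humidity_gkg)), function(g) {
      f <- fraction_out_by_score(g)
      if (nrow(f)) cbind(direction = g$direction[1],
                         humidity_gkg = g$humidity_gkg[1], f)
    }))
    rownames(frac) <- NULL
    out$set_I <- frac
    out$set_I_runs <- res
  }

  search_set <- function(id, range) {
    specs <- build_scenarios(id, base_recipe, humidity_levels, directions)
    do.call(rbind, lapply(specs, function(sp) {
      mt <- max_tolerable_deviation(recipe, params, sp, sigmas, ds,
                                    search_range = range, props = props,
                                    equip = equip, output_dt = output_dt)
      data.frame(direction = sp$direction, humidity_gkg = sp$humidity_gkg,
                 params = paste(sp$params, collapse = "+"),
                 subphase = if (id == "II") sp$spray_subphases else NA,
                 score = deviation_score(sp),
                 sigma_star = mt$sigma_star, capped = mt$capped,
                 nominal_in = mt$nominal_in, stringsAsFactors = FALSE)
    }))
  }
  if ("II" %in% sets) out$set_II <- search_set("II", range_II)
  if ("III" %in% sets) out$set_III <- search_set("III", range_III)
  if ("IV" %in% sets) out$set_IV <- search_set("IV", range_IV)

  structure(out, class = "fbg_fingerprint")
}

#' @export
print.fbg_fingerprint <- function(x, ...) {
  cat("<fbg_fingerprint> design space [", x$design_space$lod_max_lo, ", ",
      x$design_space$lod_max_hi, "] LOD%\n", sep = "")
  cat("nominal lod_max by humidity:\n")
  print(x$nominal, row.names = FALSE, digits = 4)
  if (!is.null(x[["set_I"]])) {
    cat("\nset I fraction out of range by score (max over groups):\n")
    agg <- aggregate(fraction_out ~ score, data = x[["set_I"]], FUN = max)
    print(agg, row.names = FALSE, digits = 3)
  }
  for (s in c("set_II", "set_III", "set_IV")) {
    if (!is.null(x[[s]])) {
      cat("\n", s, " minimum tolerable-deviation sigma*: ",
          suppressWarnings(min(x[[s]]$sigma_star, na.rm = TRUE)), "\n",
          sep = "")
    }
  }
  invisible(x)
}
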