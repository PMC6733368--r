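# Domain types for recipes and batch records, plus readers/writers.
# A recipe is an ordered list of phases (premix, spray subphases, dry
# subphases) with piecewise-constant setpoints; times are seconds internally,
# recipe files may declare minutes and are converted on read.

.PHASE_KINDS <- c("premix", "spray", "dry")

#' Construct a recipe phase
#'
#' @param name text label, e.g. \code{"spray-2"}.
#' @param kind one of \code{"premix"}, \code{"spray"}, \code{"dry"}.
#' @param duration phase duration [s], > 0.
#' @param T_in_set inlet air temperature setpoint [degC].
#' @param F_air_set inlet dry-air mass-flow setpoint [kg/s].
#' @param F_spray_set binder solution spray-rate setpoint [kg/s]; must be 0
#'   for premix and dry phases.
#' @param x_in inlet-air mixing ratio [kg water / kg dry air].
#' @return A validated list of class \code{fbg_phase}.
#' @export
phase <- function(name, kind, duration, T_in_set, F_air_set,
                  F_spray_set = 0, x_in = 0) {
  ph <- structure(
    list(name = as.character(name), kind = match.arg(kind, .PHASE_KINDS),
         duration = as.numeric(duration), T_in_set = as.numeric(T_in_set),
         F_air_set = as.numeric(F_air_set),
         F_spray_set = as.numeric(F_spray_set), x_in = as.numeric(x_in)),
    class = "fbg_phase")
  validate_phase(ph)
  ph
}

validate_phase <- function(ph) {
  num <- c("duration", "T_in_set", "F_air_set", "F_spray_set", "x_in")
  for (f in num) {
    v <- ph[[f]]
    if (length(v) != 1 || !is.finite(v))
      stop("phase '", ph$name, "': field '", f, "' must be a finite scalar",
           call. = FALSE)
  }
  if (ph$duration <= 0)
    stop("phase '", ph$name, "': duration must be > 0", call. = FALSE)
  if (ph$F_air_set < 0 || ph$F_spray_set < 0 || ph$x_in < 0)
    stop("phase '", ph$name, "': setpoints and x_in must be >= 0",
         call. = FALSE)
  if (ph$kind != "spray" && ph$F_spray_set != 0)
    stop("phase '", ph$name, "': F_spray_set must be 0 in a '", ph$kind,
         "' phase", call. = FALSE)
  invisible(ph)
}

#' Construct a granulation recipe
#'
#' @param phases list of \code{\link{phase}} objects; spray subphases must be
#'   contiguous.
#' @param m_solids_0 initial dry solids charge [kg].
#' @param lod_0 initial loss-on-drying [\%], in [0, 100).
#' @param w_s binder solids weight fraction in the spray solution, in [0, 1).
#' @param T_spray spray liquid temperature [degC].
#' @param T_bed_0,T_air_0,T_wall_0 initial temperatures [degC].
#' @param name optional recipe label.
#' @return A validated object of class \code{fbg_recipe}.
#' @export
fbg_recipe <- function(phases, m_solids_0, lod_0 = 1, w_s = 0.08,
                       T_spray = 25, T_bed_0 = 25, T_air_0 = 25,
                       T_wall_0 = 25, name = "recipe") {
  rec <- structure(
    list(name = as.character(name), phases = phases,
         m_solids_0 = as.numeric(m_solids_0), lod_0 = as.numeric(lod_0),
         w_s = as.numeric(w_s), T_spray = as.numeric(T_spray),
         T_bed_0 = as.numeric(T_bed_0), T_air_0 = as.numeric(T_air_0),
         T_wall_0 = as.numeric(T_wall_0)),
    class = "fbg_recipe")
  validate_recipe(rec)
  rec
}

validate_recipe <- function(rec) {
  if (length(rec$phases) < 1)
    stop("recipe must contain at least one phase", call. = FALSE)
  for (ph in rec$phases) {
    if (!inherits(ph, "fbg_phase")) stop("phases must be fbg_phase objects",
                                         call. = FALSE)
    validate_phase(ph)
  }
  kinds <- vapply(rec$phases, `[[`, "", "kind")
  spray_idx <- which(kinds == "spray")
  if (length(spray_idx) > 1 && any(diff(spray_idx) != 1))
    stop("spray subphases must be contiguous", call. = FALSE)
  if (rec$m_solids_0 <= 0) stop("m_solids_0 must be > 0", call. = FALSE)
  if (rec$lod_0 < 0 || rec$lod_0 >= 100)
    stop("lod_0 must be in [0, 100)", call. = FALSE)
  if (rec$w_s < 0 || rec$w_s >= 1)
    stop("w_s must be in [0, 1)", call. = FALSE)
  invisible(rec)
}

#' @export
print.fbg_recipe <- function(x, ...) {
  cat("<fbg_recipe> ", x$name, ": ", length(x$phases), " phases, charge ",
      x$m_solids_0, " kg, w_s = ", x$w_s, "\n", sep = "")
  df <- phase_table(x)
  df$duration_min <- df$duration / 60
  print(df[, c("name", "kind", "duration_min", "T_in_set", "F_air_set",
               "F_spray_set", "x_in")], row.names = FALSE)
  invisible(x)
}

#' Tabulate the phases of a recipe
#'
#' @param recipe an \code{fbg_recipe}.
#' @return data.frame with one row per phase (durations in seconds) plus
#'   \code{t_start}/\code{t_end} columns on the batch clock.
#' @export
phase_table <- function(recipe) {
  df <- do.call(rbind, lapply(recipe$phases, function(ph)
    data.frame(name = ph$name, kind = ph$kind, duration = ph$duration,
               T_in_set = ph$T_in_set, F_air_set = ph$F_air_set,
               F_spray_set = ph$F_spray_set, x_in = ph$x_in,
               stringsAsFactors = FALSE)))
  df$t_end <- cumsum(df$duration)
  df$t_start <- df$t_end - df$duration
  df
}

#' Total recipe duration in seconds
#' @param recipe an \code{fbg_recipe}.
#' @return total duration [s].
#' @export
recipe_duration <- function(recipe) {
  sum(vapply(recipe$phases, `[[`, 0, "duration"))
}

#' Total sprayed solution and binder mass of a recipe
#'
#' @param recipe an \code{fbg_recipe}.
#' @return named list: \code{solution} = sum of F_spray x duration over spray
#'   subphases [kg]; \code{binder} = w_s x solution [kg]; \code{water} =
#'   (1 - w_s) x solution [kg].
#' @export
sprayed_mass <- function(recipe) {
  df <- phase_table(recipe)
  sol <- sum(df$F_spray_set * df$duration)
  list(solution = sol, binder = recipe$w_s * sol,
       water = (1 - recipe$w_s) * sol)
}

#' Read a recipe from a structured YAML file
#'
#' The file holds the scalar recipe fields, an optional \code{time_unit}
#' (\code{"s"} default, or \code{"min"}, converted on read) and a
#' \code{phases} list with one block per phase.  All invariants are enforced;
#' violations raise an error naming the offending field.
#'
#' @param path file path.
#' @return an \code{fbg_recipe}.
#' @seealso \code{\link{write_recipe}}
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  required <- c("phases", "m_solids_0")
  miss <- setdiff(required, names(doc))
  if (length(miss))
    stop("recipe file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unit <- if (is.null(doc$time_unit)) "s" else doc$time_unit
  if (!unit %in% c("s", "min"))
    stop("time_unit must be 's' or 'min'", call. = FALSE)
  fac <- if (unit == "min") 60 else 1
  phases <- lapply(doc$phases, function(b) {
    need <- c("name", "kind", "duration", "T_in_set", "F_air_set")
    miss <- setdiff(need, names(b))
    if (length(miss))
      stop("phase block missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    phase(b$name, b$kind, b$duration * fac, b$T_in_set, b$F_air_set,
          if (is.null(b$F_spray_set)) 0 else b$F_spray_set,
          if (is.null(b$x_in)) 0 else b$x_in)
  })
  fbg_recipe(phases,
             m_solids_0 = doc$m_solids_0,
             lod_0 = if (is.null(doc$lod_0)) 1 else doc$lod_0,
             w_s = if (is.null(doc$w_s)) 0.08 else doc$w_s,
             T_spray = if (is.null(doc$T_spray)) 25 else doc$T_spray,
             T_bed_0 = if (is.null(doc$T_bed_0)) 25 else doc$T_bed_0,
             T_air_0 = if (is.null(doc$T_air_0)) 25 else doc$T_air_0,
             T_wall_0 = if (is.null(doc$T_wall_0)) 25 else doc$T_wall_0,
             name = if (is.null(doc$name)) "recipe" else doc$name)
}

#' Write a recipe to a structured YAML file
#'
#' Writes seconds (\code{time_unit: s}) with enough precision that
#' \code{read_recipe(write_recipe(r)) } reproduces \code{r} field-wise.
#'
#' @param recipe an \code{fbg_recipe}.
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
write_recipe <- function(recipe, path) {
  validate_recipe(recipe)
  doc <- list(
    name = recipe$name, time_unit = "s",
    m_solids_0 = recipe$m_solids_0, lod_0 = recipe$lod_0, w_s = recipe$w_s,
    T_spray = recipe$T_spray, T_bed_0 = recipe$T_bed_0,
    T_air_0 = recipe$T_air_0, T_wall_0 = recipe$T_wall_0,
    phases = lapply(recipe$phases, function(ph) ph[names(ph)])
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Construct a batch record
#'
#' A batch record ties a recipe to timestamped LOD measurements taken during
#' its execution.
#'
#' @param recipe the \code{fbg_recipe} that was run.
#' @param samples data.frame with columns \code{t} (sampling time from batch
#'   start, s) and \code{lod} (measured loss-on-drying, \%).
#' @param label text label, e.g. \code{"A"}.
#' @param scale batch mass [kg]; defaults to the recipe charge.
#' @return object of class \code{fbg_batch}.
#' @export
batch_record <- function(recipe, samples, label = "A",
                         scale = recipe$m_solids_0) {
  stopifnot(is.data.frame(samples), all(c("t", "lod") %in% names(samples)))
  samples <- samples[order(samples$t), c("t", "lod")]
  if (any(samples$t < 0) || any(samples$t > recipe_duration(recipe)))
    stop("sample times must lie within the recipe duration", call. = FALSE)
  if (any(samples$lod < 0) || any(samples$lod >= 100))
    stop("lod samples must be in [0, 100)", call. = FALSE)
  structure(list(recipe = recipe, samples = samples,
                 label = as.character(label), scale = as.numeric(scale)),
            class = "fbg_batch")
}

#' Read batch LOD samples from CSV
#'
#' Expects the two-column header \code{t_min,lod_pct} (times in minutes from
#' batch start).
#'
#' @param path CSV file path.
#' @param recipe the recipe the batch was run with.
#' @param label batch label.
#' @return an \code{fbg_batch}.
#' @export
read_batch_csv <- function(path, recipe, label = "A") {
  df <- read.csv(path)
  if (!all(c("t_min", "lod_pct") %in% names(df)))
    stop("batch CSV must have header t_min,lod_pct", call. = FALSE)
  batch_record(recipe, data.frame(t = df$t_min * 60, lod = df$lod_pct),
               label = label)
}

#' Write batch LOD samples to CSV
#' @param batch an \code{fbg_batch}.
#' @param path destination path; header \code{t_min,lod_pct}.
#' @return \code{path}, invisibly.
#' @export
write_batch_csv <- function(batch, path) {
  write.csv(data.frame(t_min = batch$samples$t / 60,
                       lod_pct = batch$samples$lod),
            path, row.names = FALSE)
  invisible(path)
}

#' LOD design space
#'
#' The interval of maximum LOD within which downstream quality attributes
#' are acceptable.
#'
#' @param lod_max_lo,lod_max_hi lower and upper bound on the maximum LOD [\%].
#' @return object of class \code{fbg_design_space}.
#' @export
design_space <- function(lod_max_lo, lod_max_hi) {
  stopifnot(is.numeric(lod_max_lo), is.numeric(lod_max_hi))
  if (!(lod_max_lo < lod_max_hi))
    stop("design space requires lod_max_lo < lod_max_hi", call. = FALSE)
  structure(list(lod_max_lo = lod_max_lo, lod_max_hi = lod_max_hi),
            class = "fbg_design_space")
}

#' Is a maximum LOD inside the design space?
#' @param lod_max maximum LOD value(s) [\%].
#' @param ds a \code{\link{design_space}}.
#' @return logical vector.
#' @export
in_design_space <- function(lod_max, ds) {
  lod_max >= ds$lod_max_lo & lod_max <= ds$lod_max_hi
}

#' Rescale the spray rate of a recipe at constant total binder
#'
#' Multiplies every spray-subphase rate by \code{factor} and divides spray
#' subphase durations by the same factor, so the total sprayed solution (and
#' binder) mass is conserved.  Used to center the maximum LOD in its design
#' space.
#'
#' @param recipe an \code{fbg_recipe}.
#' @param factor spray-rate multiplier > 0.
#' @return a new \code{fbg_recipe}.
#' @export
rescale_spray <- function(recipe, factor) {
  stopifnot(factor > 0)
  recipe$phases <- lapply(recipe$phases, function(ph) {
    if (ph$kind == "spray") {
      ph$F_spray_set <- ph$F_spray_set * factor
      ph$duration <- ph$duration / factor
    }
    ph
  })
  validate_recipe(recipe)
  recipe
}

#' Set the inlet-air humidity of every phase
#'
#' @param recipe an \code{fbg_recipe}.
#' @param x_in_gkg mixing ratio in g water per kg dry air.
#' @return a new \code{fbg_recipe} with \code{x_in = x_in_gkg / 1000} in
#'   every phase.
#' @export
set_humidity <- function(recipe, x_in_gkg) {
  stopifnot(x_in_gkg >= 0)
  recipe$phases <- lapply(recipe$phases, function(ph) {
    ph$x_in <- x_in_gkg / 1000
    ph
  })
  recipe
}

#' Select the humidity-group recipe containing a given mixing ratio
#'
#' Feed-forward humidity compensation splits the ambient-humidity range into
#' groups, each with its own centered recipe; this picks the recipe of the
#' group containing the measured inlet humidity.
#'
#' @param recipes named list of \code{fbg_recipe}, one per group.
#' @param x_in measured mixing ratio [g/kg].
#' @param groups named list (same names) of \code{c(lo, hi)} bounds [g/kg],
#'   inclusive; defaults to the three groups (1-3), (4-6), (7-10) g/kg.
#' @return the matching \code{fbg_recipe}.
#' @export
select_recipe_by_humidity <- function(recipes, x_in,
                                      groups = list(low = c(1, 3),
                                                    mid = c(4, 6),
                                                    high = c(7, 10))) {
  stopifnot(is.list(recipes), length(recipes) == length(groups),
            setequal(names(recipes), names(groups)))
  for (g in names(groups)) {
    b <- groups[[g]]
    if (x_in >= b[1] && x_in <= b[2]) return(recipes[[g]])
  }
  stop("x_in = ", x_in, " g/kg lies outside all humidity groups",
       call. = FALSE)
}
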