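# Disturbance profiles: coordinated wet/dry offsets of the deviatable process
# parameters (inlet air temperature, air flow rate, spray rate) over spray
# subphases, in units of each parameter's typical standard deviation, with
# optional pulsed (windowed) application.

.DEV_PARAMS <- c("T_in", "F_air", "F_spray")

#' Typical standard deviations of the deviatable process parameters
#'
#' One value per parameter; disturbance magnitudes are expressed as multiples
#' of these.
#'
#' @param sigma_T_in inlet air temperature sd [degC].
#' @param sigma_F_air inlet air flow sd [kg/s].
#' @param sigma_F_spray spray rate sd [kg/s].
#' @return object of class \code{fbg_sigmas}.
#' @export
parameter_std_devs <- function(sigma_T_in = 1.0, sigma_F_air = 0.01,
                               sigma_F_spray = 2e-4) {
  stopifnot(sigma_T_in > 0, sigma_F_air > 0, sigma_F_spray > 0)
  structure(list(sigma_T_in = sigma_T_in, sigma_F_air = sigma_F_air,
                 sigma_F_spray = sigma_F_spray), class = "fbg_sigmas")
}

.sigma_of <- function(sigmas, param) {
  switch(param,
         T_in = sigmas$sigma_T_in,
         F_air = sigmas$sigma_F_air,
         F_spray = sigmas$sigma_F_spray,
         stop("unknown process parameter: ", param, call. = FALSE))
}

#' Direction sign pattern of coordinated deviations
#'
#' A "wet" deviation pushes the maximum LOD up: more spray, less drying
#' capacity (colder, slower air).  A "dry" deviation is the exact negation.
#'
#' @param direction \code{"wet"} or \code{"dry"}.
#' @return named numeric vector of signs for \code{T_in}, \code{F_air},
#'   \code{F_spray}.
#' @export
#' @examples
#' deviation_direction_signs("wet") # F_spray +1, T_in -1, F_air -1
deviation_direction_signs <- function(direction = c("wet", "dry")) {
  direction <- match.arg(direction)
  wet <- c(T_in = -1, F_air = -1, F_spray = +1)
  if (direction == "wet") wet else -wet
}

#' Construct a disturbance profile
#'
#' Describes a coordinated deviation: which process parameters deviate, in
#' which spray subphases (or pulse windows), by how many standard deviations,
#' and in which direction.  All offsets in one profile share the direction's
#' sign pattern.
#'
#' @param params character subset of \code{c("T_in", "F_air", "F_spray")}.
#' @param spray_subphases integer indices among the recipe's spray subphases
#'   (1 = first spray subphase) where the offset applies.
#' @param magnitude deviation magnitude [sigma], >= 0; a single value shared
#'   by all affected parameters.
#' @param direction \code{"wet"} or \code{"dry"}.
#' @param pulses optional data.frame with columns \code{start} and
#'   \code{duration} [s, absolute batch clock]; when given, offsets apply
#'   only inside these windows (and still only in the affected subphases).
#' @return object of class \code{fbg_disturbance}.
#' @export
disturbance_profile <- function(params, spray_subphases, magnitude,
                                direction = c("wet", "dry"), pulses = NULL) {
  direction <- match.arg(direction)
  params <- unique(as.character(params))
  bad <- setdiff(params, .DEV_PARAMS)
  if (length(bad))
    stop("unknown process parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(length(magnitude) == 1, magnitude >= 0)
  spray_subphases <- sort(unique(as.integer(spray_subphases)))
  if (length(spray_subphases) == 0 || any(spray_subphases < 1))
    stop("spray_subphases must be positive indices", call. = FALSE)
  if (!is.null(pulses)) {
    stopifnot(is.data.frame(pulses),
              all(c("start", "duration") %in% names(pulses)),
              all(pulses$duration > 0), all(pulses$start >= 0))
  }
  structure(list(params = params, spray_subphases = spray_subphases,
                 magnitude = as.numeric(magnitude), direction = direction,
                 pulses = pulses),
            class = "fbg_disturbance")
}

# recipe phase indices of the spray subphases
.spray_phase_indices <- function(recipe) {
  which(vapply(recipe$phases, `[[`, "", "kind") == "spray")
}

#' Apply a disturbance profile to a recipe
#'
#' Returns a new recipe whose affected setpoints are
#' \code{setpoint + sign x magnitude x sigma} inside the affected spray
#' subphases (and pulse windows, if any).  Setpoints driven negative are
#' clamped at zero with a warning, so extreme dry searches never abort.
#' Phases overlapped partially by pulse windows are split at the window
#' edges; the split is a pure re-timing and leaves undisturbed segments
#' identical.
#'
#' @param recipe an \code{fbg_recipe}.
#' @param profile an \code{\link{fbg_disturbance}} (or a list of them, applied
#'   in sequence).
#' @param sigmas a \code{\link{parameter_std_devs}}.
#' @return a new \code{fbg_recipe}.
#' @export
apply_disturbance <- function(recipe, profile, sigmas) {
  if (inherits(profile, "fbg_disturbance")) profile <- list(profile)
  for (pr in profile) recipe <- .apply_one_disturbance(recipe, pr, sigmas)
  recipe
}

.apply_one_disturbance <- function(recipe, profile, sigmas) {
  stopifnot(inherits(profile, "fbg_disturbance"),
            inherits(sigmas, "fbg_sigmas"))
  spray_idx <- .spray_phase_indices(recipe)
  if (any(profile$spray_subphases > length(spray_idx)))
    stop("profile references spray subphase ",
         max(profile$spray_subphases), " but recipe has only ",
         length(spray_idx), call. = FALSE)
  if (profile$magnitude == 0) return(recipe)
  signs <- deviation_direction_signs(profile$direction)
  affected <- spray_idx[profile$spray_subphases]

  clamped <- character(0)
  offset_phase <- function(ph) {
    for (pm in profile$params) {
      delta <- signs[[pm]] * profile$magnitude * .sigma_of(sigmas, pm)
      field <- paste0(pm, "_set")
      val <- ph[[field]] + delta
      if (val < 0) { val <- 0; clamped <<- c(clamped, ph$name) }
      ph[[field]] <- val
    }
    ph
  }
  warn_clamped <- function() {
    if (length(clamped))
      warning("disturbance drove setpoint(s) negative in phase(s) ",
              paste(unique(clamped), collapse = ", "), "; clamped at 0",
              call. = FALSE)
  }

  if (is.null(profile$pulses)) {
    for (i in affected) recipe$phases[[i]] <- offset_phase(recipe$phases[[i]])
    warn_clamped()
    validate_recipe(recipe)
    return(recipe)
  }

  # pulsed: split affected phases at window edges, offset inside windows
  tab <- phase_table(recipe)
  win_lo <- profile$pulses$start
  win_hi <- profile$pulses$start + profile$pulses$duration
  new_phases <- list()
  for (i in seq_along(recipe$phases)) {
    ph <- recipe$phases[[i]]
    if (!(i %in% affected)) { new_phases <- c(new_phases, list(ph)); next }
    lo <- tab$t_start[i]; hi <- tab$t_end[i]
    cuts <- sort(unique(c(lo, hi, win_lo[win_lo > lo & win_lo < hi],
                          win_hi[win_hi > lo & win_hi < hi])))
    for (s in seq_len(length(cuts) - 1)) {
      seg <- ph
      seg$duration <- cuts[s + 1] - cuts[s]
      if (length(cuts) > 2) seg$name <- paste0(ph$name, "#", s)
      mid <- (cuts[s] + cuts[s + 1]) / 2
      if (any(mid >= win_lo & mid < win_hi)) seg <- offset_phase(seg)
      new_phases <- c(new_phases, list(seg))
    }
  }
  recipe$phases <- new_phases
  warn_clamped()
  validate_recipe(recipe)
  recipe
}
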