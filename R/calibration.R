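# Parameter estimation from batch LOD samples: pooled-RMSE objective,
# bounded log-parameter least squares with multi-start, Gauss-Newton
# covariance, RMSE acceptance gates, and the A/B/C/D train-validate-verify
# cross-validation exercise.

#' Root-mean-square error between predicted and measured LOD
#'
#' @param predicted model LOD at the sample times [\%].
#' @param measured measured LOD samples [\%].
#' @return RMSE [LOD \%].
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("rmse: predicted and measured lengths differ (",
         length(predicted), " vs ", length(measured), ")", call. = FALSE)
  if (length(predicted) < 1) stop("rmse: need at least one sample",
                                  call. = FALSE)
  sqrt(mean((predicted - measured)^2))
}

#' Default RMSE acceptance thresholds
#'
#' Calibration 0.279 LOD\%, validation/verification 0.664 LOD\% (historical
#' mean RMSE plus two standard deviations over a multi-product batch study).
#' @return named numeric vector.
#' @export
gate_thresholds <- function() {
  c(calibration = 0.279, validation = 0.664, verification = 0.664)
}

#' RMSE acceptance gate
#'
#' @param e RMSE [LOD \%], >= 0.
#' @param stage \code{"calibration"}, \code{"validation"} or
#'   \code{"verification"}.
#' @param thresholds named thresholds, overriding \code{\link{gate_thresholds}}.
#' @return \code{TRUE} (pass) iff \code{e <= threshold[stage]}.
#' @export
acceptance_gate <- function(e, stage = c("calibration", "validation",
                                         "verification"),
                            thresholds = gate_thresholds()) {
  stage <- match.arg(stage)
  stopifnot(all(e >= 0))
  if (!stage %in% names(thresholds))
    stop("no threshold configured for stage '", stage, "'", call. = FALSE)
  e <= thresholds[[stage]]
}

#' Predict LOD at sample times
#'
#' Simulates the recipe and linearly interpolates the LOD trace at the given
#' times.
#'
#' @param recipe an \code{fbg_recipe}.
#' @param params \code{\link{model_parameters}}.
#' @param sample_times times from batch start [s], within the recipe span.
#' @param props,equip property tables.
#' @param output_dt simulation output grid [s].
#' @param ... further arguments to \code{\link{simulate_recipe}}.
#' @return LOD [\%] at \code{sample_times}.
#' @export
predict_at_samples <- function(recipe, params, sample_times,
                               props = material_properties(),
                               equip = equipment_properties(),
                               output_dt = 10, ...) {
  span <- recipe_duration(recipe)
  if (any(sample_times < 0) || any(sample_times > span + 1e-9))
    stop("sample time outside the recipe span [0, ", span, "] s",
         call. = FALSE)
  traj <- simulate_recipe(recipe, params, props, equip,
                          output_dt = output_dt, ...)
  approx(traj$t, traj$lod, xout = pmin(sample_times, max(traj$t)),
         ties = "ordered")$y
}

# pooled residual vector over batches at natural-scale (theta_p, theta_e
# [, alpha_spray, alpha_air])
.fit_residuals <- function(p_nat, batches, base_params, fit_alpha,
                           props, equip, output_dt) {
  params <- model_parameters(
    theta_p = p_nat[1], theta_e = p_nat[2],
    alpha_spray = if (fit_alpha) p_nat[3] else base_params$alpha_spray,
    alpha_air = if (fit_alpha) p_nat[4] else base_params$alpha_air)
  unlist(lapply(batches, function(b) {
    predict_at_samples(b$recipe, params, b$samples$t, props, equip,
                       output_dt = output_dt) - b$samples$lod
  }))
}

#' Fit the evaporation parameters to batch LOD records
#'
#' Minimizes the pooled RMSE over (theta_p, theta_e) -- and the flow
#' correction factors (alpha_spray, alpha_air) when \code{fit_alpha} -- by
#' bounded nonlinear least squares (Levenberg-Marquardt on log-parameters)
#' with multi-start: \code{n_starts} starting points with theta_p log-spaced
#' across its bounds.  The covariance of the estimate is the Gauss-Newton
#' approximation s^2 (J'J)^-1 from the natural-scale Jacobian at the optimum.
#'
#' @param batches a single \code{fbg_batch} or list of them (pooled).
#' @param init optional \code{\link{model_parameters}} starting point /
#'   fixed-alpha source; defaults to theta_p = 2 mm, theta_e = 5, alpha = 1.
#' @param lower,upper named bounds on \code{theta_p} [m], \code{theta_e}
#'   [LOD \%] (and \code{alpha} when fitted).
#' @param fit_alpha also estimate the two flow correction factors.
#' @param n_starts number of multi-start points (default 5).
#' @param props,equip property tables.
#' @param output_dt simulation output grid used inside the objective [s].
#' @return An object of class \code{fbg_fit}: list with \code{params} (the
#'   fitted \code{\link{model_parameters}} carrying the covariance),
#'   \code{rmse_train}, \code{residuals} (list per batch label),
#'   \code{converged}, \code{n_samples}, \code{objective_history} (best RMSE
#'   after each start).
#' @export
fit_lod_model <- function(batches, init = NULL,
                          lower = c(theta_p = 2e-4, theta_e = 0.5,
                                    alpha = 0.5),
                          upper = c(theta_p = 5e-2, theta_e = 50,
                                    alpha = 2),
                          fit_alpha = FALSE, n_starts = 5,
                          props = material_properties(),
                          equip = equipment_properties(),
                          output_dt = 5) {
  if (inherits(batches, "fbg_batch")) batches <- list(batches)
  stopifnot(length(batches) >= 1,
            all(vapply(batches, inherits, TRUE, "fbg_batch")))
  n_samples <- sum(vapply(batches, function(b) nrow(b$samples), 0L))
  if (n_samples < 3)
    stop("need at least 3 samples in total to fit", call. = FALSE)
  stopifnot(all(lower > 0), all(upper > lower[names(upper)]))
  if (is.null(init)) init <- model_parameters(2e-3, 5)

  npar <- if (fit_alpha) 4L else 2L
  lo <- log(c(lower[["theta_p"]], lower[["theta_e"]],
              rep(lower[["alpha"]], 2))[seq_len(npar)])
  hi <- log(c(upper[["theta_p"]], upper[["theta_e"]],
              rep(upper[["alpha"]], 2))[seq_len(npar)])

  obj <- function(p_log)
    .fit_residuals(exp(p_log), batches, init, fit_alpha, props, equip,
                   output_dt)

  # multi-start grid: theta_p log-spaced within bounds, theta_e alternating
  # around its init to break the theta_p/theta_e compensation ridge
  thp_starts <- exp(seq(log(lower[["theta_p"]] * 2),
                        log(upper[["theta_p"]] / 2),
                        length.out = n_starts))
  the_facs <- rep(c(1, 1 / 2, 2), length.out = n_starts)
  starts <- lapply(seq_len(n_starts), function(i) {
    s <- c(log(thp_starts[i]), log(init$theta_e * the_facs[i]))
    if (fit_alpha) s <- c(s, log(init$alpha_spray), log(init$alpha_air))
    pmin(pmax(s, lo), hi)
  })
  starts[[1]] <- pmin(pmax(c(log(init$theta_p), log(init$theta_e),
                             if (fit_alpha) c(log(init$alpha_spray),
                                              log(init$alpha_air))),
                           lo), hi)

  best <- NULL
  history <- numeric(0)
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lo, upper = hi, fn = obj,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, maxfev = 2000, ptol = 1e-10,
                           ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) { history <- c(history, NA); next }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:4) converged <- TRUE
    history <- c(history, sqrt(best$deviance / n_samples))
  }
  if (is.null(best))
    stop("parameter estimation failed from every start", call. = FALSE)

  p_hat <- exp(best$par)
  resid <- obj(best$par)
  s2 <- sum(resid^2) / max(n_samples - npar, 1)
  J <- pracma::jacobian(function(p)
    .fit_residuals(p, batches, init, fit_alpha, props, equip, output_dt),
    p_hat)
  JtJ <- crossprod(J)
  covp <- tryCatch(s2 * solve(JtJ), error = function(e) {
    warning("singular Jacobian; covariance from pseudo-inverse",
            call. = FALSE)
    s2 * pracma::pinv(JtJ)
  })
  covp <- (covp + t(covp)) / 2

  params <- model_parameters(
    theta_p = p_hat[1], theta_e = p_hat[2],
    alpha_spray = if (fit_alpha) p_hat[3] else init$alpha_spray,
    alpha_air = if (fit_alpha) p_hat[4] else init$alpha_air,
    covariance = covp)

  i0 <- 0
  residuals <- lapply(batches, function(b) {
    r <- resid[i0 + seq_len(nrow(b$samples))]
    i0 <<- i0 + nrow(b$samples)
    r
  })
  names(residuals) <- vapply(batches, `[[`, "", "label")

  structure(list(params = params,
                 rmse_train = sqrt(mean(resid^2)),
                 residuals = residuals, converged = converged,
                 n_samples = n_samples, objective_history = history),
            class = "fbg_fit")
}

#' @export
print.fbg_fit <- function(x, ...) {
  cat(sprintf(
    "<fbg_fit> theta_p = %.4g m, theta_e = %.4g LOD%% (n = %d samples)\n",
    x$params$theta_p, x$params$theta_e, x$n_samples))
  cat(sprintf("rmse_train = %.4g LOD%% [calibration gate %.3f: %s]\n",
              x$rmse_train, gate_thresholds()[["calibration"]],
              if (acceptance_gate(x$rmse_train, "calibration")) "PASS"
              else "FAIL"))
  invisible(x)
}

#' Train/validate/verify cross-validation over four batches
#'
#' Runs the three calibration exercises: (a) train on batch A, predict batch
#' B; (b) train on B, predict A; (c) train on A + B jointly, predict the
#' independent pilot batch C (validation) and the commercial-scale batch D
#' (verification).  Each prediction RMSE is gated with the stage-correct
#' threshold; the training RMSEs are gated with the calibration threshold.
#'
#' @param batch_a,batch_b,batch_c,batch_d \code{fbg_batch} records; D may be
#'   at a different scale (pass \code{equip_d}).
#' @param init,lower,upper,fit_alpha,n_starts,props,equip,output_dt passed to
#'   \code{\link{fit_lod_model}}.
#' @param equip_d equipment table for batch D (defaults to \code{equip}).
#' @return An object of class \code{fbg_validation}: list with
#'   \code{rmse_per_exercise} (named: \code{a_train_A}, \code{a_predict_B},
#'   \code{b_train_B}, \code{b_predict_A}, \code{c_train_AB},
#'   \code{c_predict_C}, \code{c_predict_D}), \code{gates} (named logical),
#'   \code{fits} (the three \code{fbg_fit}s), \code{pass} (all gates).
#' @export
cross_validate <- function(batch_a, batch_b, batch_c, batch_d, init = NULL,
                           lower = c(theta_p = 2e-4, theta_e = 0.5,
                                     alpha = 0.5),
                           upper = c(theta_p = 5e-2, theta_e = 50,
                                     alpha = 2),
                           fit_alpha = FALSE, n_starts = 5,
                           props = material_properties(),
                           equip = equipment_properties(),
                           equip_d = equip, output_dt = 5) {
  run_fit <- function(batches, label) {
    tryCatch(
      fit_lod_model(batches, init = init, lower = lower, upper = upper,
                    fit_alpha = fit_alpha, n_starts = n_starts,
                    props = props, equip = equip, output_dt = output_dt),
      error = function(e)
        stop("exercise (", label, "): ", conditionMessage(e), call. = FALSE))
  }
  pred_rmse <- function(fit, batch, eq) {
    p <- predict_at_samples(batch$recipe, fit$params, batch$samples$t,
                            props, eq, output_dt = output_dt)
    rmse(p, batch$samples$lod)
  }

  fit_a <- run_fit(list(batch_a), "a")
  fit_b <- run_fit(list(batch_b), "b")
  fit_ab <- run_fit(list(batch_a, batch_b), "c")

  e <- c(a_train_A = fit_a$rmse_train,
         a_predict_B = pred_rmse(fit_a, batch_b, equip),
         b_train_B = fit_b$rmse_train,
         b_predict_A = pred_rmse(fit_b, batch_a, equip),
         c_train_AB = fit_ab$rmse_train,
         c_predict_C = pred_rmse(fit_ab, batch_c, equip),
         c_predict_D = pred_rmse(fit_ab, batch_d, equip_d))
  stage <- c(a_train_A = "calibration", a_predict_B = "validation",
             b_train_B = "calibration", b_predict_A = "validation",
             c_train_AB = "calibration", c_predict_C = "validation",
             c_predict_D = "verification")
  gates <- setNames(mapply(function(ei, st) acceptance_gate(ei, st),
                           e, stage[names(e)]), names(e))
  structure(list(rmse_per_exercise = e, gates = gates, stages = stage,
                 fits = list(a = fit_a, b = fit_b, c = fit_ab),
                 pass = all(gates)),
            class = "fbg_validation")
}

#' @export
print.fbg_validation <- function(x, ...) {
  cat("<fbg_validation>\n")
  df <- data.frame(exercise = names(x$rmse_per_exercise),
                   stage = unname(x$stages[names(x$rmse_per_exercise)]),
                   rmse = unname(x$rmse_per_exercise),
                   gate = ifelse(x$gates, "PASS", "FAIL"))
  print(df, row.names = FALSE, digits = 4)
  cat(if (x$pass) "all gates PASS\n" else "at least one gate FAILED\n")
  invisible(x)
}
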