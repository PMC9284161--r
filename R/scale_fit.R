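#' Fit drying-path parameters to observed opening angles
#'
#' The package's central estimator: least-squares fit of the drying-path
#' parameters to opening angles observed over a relative-humidity sweep.
#' For each candidate parameter vector the observation humidities are mapped
#' onto the drying path (passive modulus from the humidity curve, active
#' contraction from the drying coordinate, active modulus from the sclereid
#' regression) and the forward model predicts the opening angle relative to
#' the fully wet reference; the fit minimizes the residual sum of squares.
#'
#' One parameter is fitted at a time: either the fully dry passive modulus
#' `E_passive_dry` (one-dimensional golden-section/parabolic search within
#' the bracket) or the maximal contraction `eps_max` (closed-form ordinary
#' least squares, since the predicted angle is linear in the eigenstrain).
#' Fitting both jointly is refused: the two parameters enter the predicted
#' angle only through the ratio
#' \eqn{\varepsilon_{max} / (E_{dry} - E_{wet})} whenever the drying
#' coordinate stays unclamped over the observation humidities, so a
#' humidity sweep cannot separate them.
#'
#' @param formula model formula `angle ~ humidity` naming the observation
#'   columns, e.g. `gamma_obs_deg ~ rh_percent`.
#' @param data data frame of observations.
#' @param model a [scale_model()].
#' @param what character; the parameter to fit, `"E_passive_dry"` or
#'   `"eps_max"`.
#' @param path_template [drying_path()] supplying the fixed parameters
#'   (`E_passive_wet`, and `eps_max` when not fitted). Its `E_passive_dry`
#'   seeds nothing; the bracket does.
#' @param bracket length-2 bracket for `E_passive_dry`, MPa.
#'   Default `c(200, 5000)`.
#' @param eps_bracket length-2 bracket for `eps_max` when fitted.
#'   Default `c(0.01, 0.5)`.
#' @param curve passive-layer [material_curve()] mapping humidity to the
#'   drying coordinate.
#' @return An object of class `scale_fit` with the usual accessor methods
#'   ([coef()], [predict()][predict.scale_fit], [fitted()], [residuals()],
#'   [summary()][summary.scale_fit], [plot()][plot.scale_fit],
#'   [simulate()][simulate.scale_fit]).
#' @examples
#' obs <- generate_angle_observations(
#'   truth = list(E_passive_dry = 1170, eps_max = 0.22),
#'   n_scales = 4, noise_sd = 1, size_cv = 0, seed = 7)
#' fit <- scale_fit(gamma_obs_deg ~ rh_percent, obs)
#' coef(fit)
#' @export
scale_fit <- function(formula, data, model = scale_model(),
                      what = "E_passive_dry",
                      path_template = drying_path(),
                      bracket = c(200, 5000), eps_bracket = c(0.01, 0.5),
                      curve = material_preset("sclerenchyma_sim")) {
  stopifnot(inherits(formula, "formula"), inherits(model, "scale_model"))
  what <- match.arg(what, c("E_passive_dry", "eps_max"), several.ok = TRUE)
  if (length(what) > 1L)
    stop("scale_fit: E_passive_dry and eps_max are not jointly identifiable ",
         "from a humidity sweep (the angle depends on them only through ",
         "eps_max / (E_passive_dry - E_passive_wet)); fit one at a time",
         call. = FALSE)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  if (ncol(mf) != 2L)
    stop("scale_fit: formula must be of the form angle ~ humidity",
         call. = FALSE)
  gamma_obs <- mf[[1L]]
  rh <- mf[[2L]]
  if (anyNA(gamma_obs) || anyNA(rh))
    stop("scale_fit: observations contain missing values", call. = FALSE)

  rh_levels <- sort(unique(rh))
  E_rh <- young_modulus(curve, rh_levels)
  Ea_rh <- sclereid_modulus(rh_levels)
  idx <- match(rh, rh_levels)

  pred_levels <- function(E_dry, eps_max) {
    xi <- pmin(pmax((E_rh - path_template$E_passive_wet) /
                      (E_dry - path_template$E_passive_wet), 0), 1)
    .gamma_states(model, -eps_max * xi, Ea_rh, E_rh)
  }
  rss <- function(E_dry, eps_max)
    sum((gamma_obs - pred_levels(E_dry, eps_max)[idx])^2)

  if (identical(what, "E_passive_dry")) {
    opt <- stats::optimize(function(E) rss(E, path_template$eps_max),
                           interval = bracket, tol = 1e-7 * diff(bracket))
    E_hat <- opt$minimum
    eps_hat <- path_template$eps_max
    est <- c(E_passive_dry = E_hat)
    value <- opt$objective
    # an estimate pinned at the bracket edge has not genuinely converged
    edge_tol <- 1e-3 * diff(bracket)
    converged <- E_hat > bracket[1] + edge_tol && E_hat < bracket[2] - edge_tol
  } else {
    # the predicted angle is linear in eps_max, so the least-squares
    # contraction has a closed form given the (fixed) modulus
    E_hat <- path_template$E_passive_dry
    basis <- pred_levels(E_hat, 1)[idx]
    eps_hat <- min(max(sum(basis * gamma_obs) / sum(basis^2),
                       eps_bracket[1]), eps_bracket[2])
    est <- c(eps_max = eps_hat)
    value <- sum((gamma_obs - eps_hat * basis)^2)
    edge_tol <- 1e-6 * diff(eps_bracket)
    converged <- eps_hat > eps_bracket[1] + edge_tol &&
      eps_hat < eps_bracket[2] - edge_tol
  }

  fitted_vals <- pred_levels(E_hat, eps_hat)[idx]
  res <- gamma_obs - fitted_vals
  df_resid <- length(gamma_obs) - length(est)
  structure(
    list(coefficients = est, residuals = res, fitted.values = fitted_vals,
         rss = value, sigma = sqrt(value / max(df_resid, 1L)),
         df.residual = df_resid, converged = converged,
         formula = formula, data = mf, rh = rh, gamma_obs = gamma_obs,
         model = model, path_template = path_template, curve = curve,
         bracket = bracket, what = what,
         call = match.call()),
    class = "scale_fit")
}

# Path implied by the fitted coefficients.
.fit_path <- function(object) {
  cf <- object$coefficients
  drying_path(
    eps_max = if ("eps_max" %in% names(cf)) cf[["eps_max"]] else
      object$path_template$eps_max,
    E_passive_wet = object$path_template$E_passive_wet,
    E_passive_dry = if ("E_passive_dry" %in% names(cf))
      cf[["E_passive_dry"]] else object$path_template$E_passive_dry)
}

#' @export
print.scale_fit <- function(x, ...) {
  cat("Drying-path fit to opening angles\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  if (!x$converged)
    cat("  WARNING: estimate pinned at the bracket edge (not converged)\n")
  invisible(x)
}

#' Summarize a drying-path fit
#'
#' @param object a [scale_fit()] object.
#' @param ... unused.
#' @return `object`, invisibly, after printing coefficients, residual
#'   standard deviation and fit diagnostics.
#' @export
summary.scale_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  n = %d observations over %d humidity levels\n",
              length(object$gamma_obs), length(unique(object$rh))))
  cat(sprintf("  RSS = %.4g, sigma = %.4g deg on %d df\n",
              object$rss, object$sigma, object$df.residual))
  invisible(object)
}

#' @export
coef.scale_fit <- function(object, ...) object$coefficients

#' @export
fitted.scale_fit <- function(object, ...) object$fitted.values

#' @export
residuals.scale_fit <- function(object, ...) object$residuals

#' Predict opening angles from a drying-path fit
#'
#' @param object a [scale_fit()] object.
#' @param newdata optional data frame containing the humidity column of the
#'   fit formula (or a column `rh`); omitted, returns fitted values.
#' @param ... unused.
#' @return predicted opening angles, degrees.
#' @export
predict.scale_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  rh_name <- all.vars(object$formula)[2L]
  rh <- if (rh_name %in% names(newdata)) newdata[[rh_name]] else newdata$rh
  if (is.null(rh))
    stop("predict.scale_fit: newdata must contain column '", rh_name, "'",
         call. = FALSE)
  path <- .fit_path(object)
  xi <- xi_from_rh(path, object$curve, rh)
  .gamma_states(object$model, active_strain(path, xi),
                sclereid_modulus(rh), young_modulus(object$curve, rh))
}

#' Plot a drying-path fit
#'
#' Observed opening angles against relative humidity with the fitted
#' forward-model curve.
#'
#' @param x a [scale_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.scale_fit <- function(x, ...) {
  graphics::plot(x$rh, x$gamma_obs, xlab = "relative humidity (%)",
                 ylab = "opening angle (deg)",
                 main = "Drying-path fit", ...)
  rh_grid <- seq(min(x$rh), max(x$rh), length.out = 101L)
  graphics::lines(rh_grid, predict(x, data.frame(rh = rh_grid)))
  invisible(x)
}

#' Simulate opening-angle observations from a fitted drying path
#'
#' Draws new observation tables at the fitted parameters: forward-model
#' angles at the fit's humidity values plus Gaussian noise with the fit's
#' residual standard deviation.
#'
#' @param object a [scale_fit()] object.
#' @param nsim number of simulated response vectors. Default 1.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @param ... unused.
#' @return A data frame with `nsim` columns `sim_1 ...`, one row per
#'   original observation.
#' @export
simulate.scale_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  mu <- object$fitted.values
  out <- as.data.frame(
    replicate(nsim, mu + stats::rnorm(length(mu), sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
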