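#' Calibration result
#'
#' Container for a single-parameter inverse solve: fitted value, residual on
#' the angle, bracket, iteration count and convergence flag. Created by
#' [fit_passive_modulus()] and [fit_contraction()].
#'
#' @param parameter_name label of the fitted parameter.
#' @param fitted_value fitted value (MPa or dimensionless strain).
#' @param residual_deg remaining angle residual, degrees.
#' @param bracket numeric length-2 search bracket.
#' @param iterations root-finder iteration count.
#' @param converged logical.
#' @return An object of class `calibration_result`.
#' @keywords internal
calibration_result <- function(parameter_name, fitted_value, residual_deg,
                               bracket, iterations, converged) {
  structure(list(parameter_name = parameter_name,
                 fitted_value = fitted_value, residual_deg = residual_deg,
                 bracket = bracket, iterations = iterations,
                 converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration of %s\n", x$parameter_name))
  cat(sprintf("  fitted value : %.6g\n", x$fitted_value))
  cat(sprintf("  residual     : %.3g deg\n", x$residual_deg))
  cat(sprintf("  bracket      : [%g, %g], %d iterations, %s\n",
              x$bracket[1], x$bracket[2], x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.calibration_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.calibration_result <- function(object, ...) {
  stats::setNames(object$fitted_value, object$parameter_name)
}

# Shared bracketed scalar solve: checks strict monotonicity of `fn` on a
# grid over the bracket and a sign change at the endpoints, then runs
# Brent's method. `fn` returns the angle residual in degrees.
.bracketed_root <- function(fn, bracket, tol_deg, max_iter, what) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  grid <- seq(bracket[1], bracket[2], length.out = 33L)
  fg <- vapply(grid, fn, numeric(1))
  dg <- diff(fg)
  if (!(all(dg > 0) || all(dg < 0)))
    stop(sprintf(
      "%s: forward angle is not monotone over the bracket [%g, %g]; ",
      what, bracket[1], bracket[2]),
      "refusing to root-find (shrink the bracket)", call. = FALSE)
  if (fg[1L] * fg[33L] > 0)
    stop(sprintf(
      "%s: no sign change over the bracket; residual(lo) = %.4g deg, residual(hi) = %.4g deg",
      what, fg[1L], fg[33L]), call. = FALSE)
  sol <- stats::uniroot(fn, interval = bracket,
                        f.lower = fg[1L], f.upper = fg[33L],
                        tol = max(1e-12, diff(bracket) * 1e-13),
                        maxiter = max_iter)
  resid <- sol$f.root
  calibration_result(what, sol$root, resid, bracket, sol$iter,
                     converged = abs(resid) <= tol_deg)
}

#' Calibrate the passive-layer modulus against a target angle
#'
#' Inverse solve reproducing the dry-state calibration: find the passive
#' (sclerenchyma) modulus at which the forward model's opening angle equals
#' the target. The forward angle is checked to be strictly monotone over the
#' bracket before the bracketed root-find (Brent), so the solution is
#' unique; a non-monotone bracket is refused rather than silently returning
#' one of several roots.
#'
#' Defaults reproduce the fully dry calibration: target 24.4 degrees, 22\%
#' active contraction, dry sclereid modulus 37 MPa.
#'
#' @param model a [scale_model()].
#' @param target_gamma target opening angle, degrees. Default 24.4.
#' @param eps_active active-layer eigenstrain. Default -0.22.
#' @param E_active active-layer modulus, MPa. Default 37.
#' @param bracket search bracket for the passive modulus, MPa.
#'   Default `c(100, 5000)`.
#' @param tol_deg residual tolerance on the angle, degrees. Default 1e-4.
#' @param max_iter root-finder iteration cap. Default 200.
#' @return A [calibration_result()] for `"E_passive_dry"`.
#' @examples
#' fit_passive_modulus(scale_model(), target_gamma = 24.4)
#' @export
fit_passive_modulus <- function(model, target_gamma = 24.4,
                                eps_active = -0.22, E_active = 37,
                                bracket = c(100, 5000),
                                tol_deg = 1e-4, max_iter = 200L) {
  stopifnot(inherits(model, "scale_model"))
  fn <- function(Ep)
    .gamma_states(model, eps_active, E_active, Ep) - target_gamma
  .bracketed_root(fn, bracket, tol_deg, max_iter, "E_passive_dry")
}

#' Calibrate the active-layer contraction over a humidity interval
#'
#' Find the contraction increment \eqn{\Delta\varepsilon} such that the
#' angular change between the interval's wet-end and dry-end states equals
#' the target: the dry-end state inherits the wet-end contraction minus the
#' increment, while the endpoint moduli are held at their humidity-curve
#' values.
#'
#' @param model a [scale_model()].
#' @param target_gamma target angular change over the interval, degrees.
#'   Default 12 (the measured 80 to 30\% rh sweep).
#' @param state_wet,state_dry [scale_state()]s at the wet and dry interval
#'   endpoints; `state_dry$eps_active` is ignored and replaced by
#'   `state_wet$eps_active - increment` during the solve.
#' @param bracket search bracket for the increment. Default `c(0, 0.22)`.
#' @inheritParams fit_passive_modulus
#' @return A [calibration_result()] for `"contraction_increment"`.
#' @export
fit_contraction <- function(model, target_gamma = 12,
                            state_wet, state_dry,
                            bracket = c(0, 0.22),
                            tol_deg = 1e-4, max_iter = 200L) {
  stopifnot(inherits(model, "scale_model"),
            inherits(state_wet, "scale_state"),
            inherits(state_dry, "scale_state"))
  gamma_wet <- .gamma_states(model, state_wet$eps_active,
                             state_wet$E_active, state_wet$E_passive)
  fn <- function(de)
    .gamma_states(model, state_wet$eps_active - de,
                  state_dry$E_active, state_dry$E_passive) -
      gamma_wet - target_gamma
  .bracketed_root(fn, bracket, tol_deg, max_iter, "contraction_increment")
}

#' States at the endpoints of a humidity interval
#'
#' Maps relative humidities onto the drying path: the passive modulus comes
#' from the passive-layer humidity curve, the active contraction from the
#' drying coordinate [xi_from_rh()], and the active modulus from the
#' sclereid regression at the same humidity.
#'
#' @param path a [drying_path()].
#' @param rh numeric vector of relative humidities, percent.
#' @param curve passive-layer [material_curve()]; default the
#'   `"sclerenchyma_sim"` preset.
#' @return A list of [scale_state()]s, one per humidity.
#' @export
interval_states <- function(path, rh, curve = material_preset("sclerenchyma_sim")) {
  stopifnot(inherits(path, "drying_path"))
  if (anyNA(rh) || any(rh < 0) || any(rh > 100))
    stop("interval_states: rh must lie in [0, 100]", call. = FALSE)
  xi <- xi_from_rh(path, curve, rh)
  lapply(seq_along(rh), function(i)
    scale_state(eps_active = active_strain(path, xi[i]),
                E_active = sclereid_modulus(rh[i]),
                E_passive = young_modulus(curve, rh[i])))
}

#' Sweep the drying path
#'
#' Evaluates the forward model along a uniform grid of the drying
#' coordinate \eqn{\xi}, reporting for each state the equivalent humidity
#' (by inverting the passive-layer curve, clamped to its range), the layer
#' properties and the opening angle. The wet reference \eqn{\xi = 0} has
#' zero angle by construction.
#'
#' @param model a [scale_model()].
#' @param path a [drying_path()].
#' @param n_points number of grid points, >= 2. Default 41.
#' @param curve passive-layer [material_curve()] used for the humidity
#'   equivalent and interval states.
#' @return A data frame of class `sweep_table` with columns `xi`,
#'   `rh_percent`, `E_passive_MPa`, `E_active_MPa`, `eps_active`,
#'   `gamma_deg`.
#' @export
drying_sweep <- function(model, path, n_points = 41L,
                         curve = material_preset("sclerenchyma_sim")) {
  stopifnot(inherits(model, "scale_model"), inherits(path, "drying_path"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("drying_sweep: n_points must be at least 2", call. = FALSE)
  xi <- seq(0, 1, length.out = n_points)
  Ep <- passive_modulus(path, xi)
  rh <- rh_equivalent(curve, Ep)
  Ea <- sclereid_modulus(rh)
  eps <- active_strain(path, xi)
  gam <- .gamma_states(model, eps, Ea, Ep)
  structure(
    data.frame(xi = xi, rh_percent = rh, E_passive_MPa = Ep,
               E_active_MPa = Ea, eps_active = eps, gamma_deg = gam),
    class = c("sweep_table", "data.frame"))
}

#' Predicted angular change and modulus change over a humidity interval
#'
#' Maps the two humidities onto the calibrated drying path with
#' [interval_states()] and reports the angular change from `rh_A` to `rh_B`
#' together with the passive-modulus difference
#' \eqn{E(rh_B) - E(rh_A)} over the same interval.
#'
#' @param model a [scale_model()].
#' @param path a [drying_path()].
#' @param rh_A,rh_B interval endpoint humidities, percent (A is the start,
#'   typically the wetter state).
#' @param curve passive-layer [material_curve()].
#' @return A list of class `interval_prediction`: `angle_deg`,
#'   `modulus_difference_MPa`, `rh`, `states`.
#' @examples
#' predict_interval_angle(scale_model(), drying_path(), 80, 30)
#' @export
predict_interval_angle <- function(model, path, rh_A = 80, rh_B = 30,
                                   curve = material_preset("sclerenchyma_sim")) {
  st <- interval_states(path, c(rh_A, rh_B), curve)
  structure(
    list(angle_deg = angular_change(model, st[[1L]], st[[2L]]),
         modulus_difference_MPa =
           young_modulus(curve, rh_B) - young_modulus(curve, rh_A),
         rh = c(rh_A, rh_B), states = st),
    class = "interval_prediction")
}

#' @export
print.interval_prediction <- function(x, ...) {
  cat(sprintf("Interval %g%% -> %g%% rh: angular change %.3f deg, ",
              x$rh[1], x$rh[2], x$angle_deg))
  cat(sprintf("passive-modulus change %+.4g MPa\n", x$modulus_difference_MPa))
  invisible(x)
}
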