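# RNG hygiene: seeded generators restore the caller's RNG state.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# lognormal multiplier with mean exactly 1 at coefficient of variation cv
.lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic opening-angle observations
#'
#' Emulates the humidity-sweep experiment: per scale, opening angles over a
#' relative-humidity grid. Each synthetic scale gets a lognormal size
#' multiplier on its bending-zone length (mean 1, configurable coefficient
#' of variation), standing in for the wide range of scale sizes that
#' dominates the measured between-scale scatter; on top, i.i.d. Gaussian
#' noise is added to each angle. The defaults match the reported sweep:
#' 30 to 80\% rh in 10\% steps and an angle scatter of 4.2 degrees.
#'
#' @param truth list with elements `E_passive_dry` (MPa), `eps_max`
#'   (dimensionless) and optionally `length_mm` (defaults to the model's).
#' @param rh_grid humidity grid, percent. Default `seq(30, 80, 10)`.
#' @param n_scales number of synthetic scales, >= 1. Default 12.
#' @param noise_sd Gaussian angle noise, degrees. Default 4.2.
#' @param size_cv coefficient of variation of the per-scale length
#'   multiplier. Default 0.15.
#' @param seed integer seed; the same seed regenerates the identical table.
#' @param model a [scale_model()] supplying geometry.
#' @param curve passive-layer [material_curve()].
#' @param E_passive_wet fully wet passive modulus, MPa. Default 70.
#' @return A data frame with columns `scale` (replicate id), `rh_percent`,
#'   `gamma_obs_deg` and `size_factor`; attributes `seed` and `truth`.
#' @examples
#' obs <- generate_angle_observations(
#'   truth = list(E_passive_dry = 1170, eps_max = 0.22), seed = 1)
#' head(obs)
#' @export
generate_angle_observations <- function(truth,
                                        rh_grid = seq(30, 80, by = 10),
                                        n_scales = 12L, noise_sd = 4.2,
                                        size_cv = 0.15, seed = 1L,
                                        model = scale_model(),
                                        curve = material_preset("sclerenchyma_sim"),
                                        E_passive_wet = 70) {
  if (length(rh_grid) == 0L)
    stop("generate_angle_observations: rh_grid must be non-empty",
         call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("generate_angle_observations: noise_sd must be >= 0", call. = FALSE)
  n_scales <- as.integer(n_scales)
  if (is.na(n_scales) || n_scales < 1L)
    stop("generate_angle_observations: n_scales must be >= 1", call. = FALSE)
  stopifnot(is.list(truth), !is.null(truth$E_passive_dry),
            !is.null(truth$eps_max))
  L0 <- if (!is.null(truth$length_mm)) truth$length_mm else
    model$zone$length_mm

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  path <- drying_path(eps_max = truth$eps_max,
                      E_passive_wet = E_passive_wet,
                      E_passive_dry = truth$E_passive_dry)
  xi <- xi_from_rh(path, curve, rh_grid)
  eps <- active_strain(path, xi)
  Ea <- sclereid_modulus(rh_grid)
  Ep <- young_modulus(curve, rh_grid)

  m <- .lnorm_mult(n_scales, size_cv)
  rows <- lapply(seq_len(n_scales), function(i) {
    zone_i <- model$zone
    zone_i$length_mm <- L0 * m[i]
    model_i <- model
    model_i$zone <- zone_i
    g <- .gamma_states(model_i, eps, Ea, Ep) +
      stats::rnorm(length(rh_grid), sd = noise_sd)
    data.frame(scale = i, rh_percent = rh_grid, gamma_obs_deg = g,
               size_factor = m[i])
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- truth
  out
}

#' Generate synthetic indentation-modulus observations
#'
#' Emulates the per-location scatter of indentation moduli: for each tissue
#' curve and humidity, `n_locations` observations with multiplicative
#' lognormal noise (mean 1) around the curve value, so observations are
#' guaranteed positive. The default of 64 locations matches the indentation
#' grid measured per sample.
#'
#' @param curves a [material_curve()] or named list of them.
#' @param rh humidity levels, percent. Default `seq(30, 80, 10)`.
#' @param n_locations observations per (tissue, humidity). Default 64.
#' @param cv coefficient of variation of the multiplicative noise.
#'   Default 0.3.
#' @param seed integer seed.
#' @return A data frame with columns `tissue`, `rh_percent`, `location`,
#'   `E_obs_MPa`; attribute `seed`.
#' @export
generate_modulus_observations <- function(curves, rh = seq(30, 80, by = 10),
                                          n_locations = 64L, cv = 0.3,
                                          seed = 1L) {
  if (inherits(curves, "material_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "material_curve")))
  if (!is.numeric(cv) || cv < 0)
    stop("generate_modulus_observations: cv must be >= 0", call. = FALSE)
  n_locations <- as.integer(n_locations)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  rows <- lapply(curves, function(cu) {
    do.call(rbind, lapply(rh, function(r) {
      data.frame(tissue = cu$tissue, rh_percent = r,
                 location = seq_len(n_locations),
                 E_obs_MPa = young_modulus(cu, r) *
                   .lnorm_mult(n_locations, cv))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Bundle a synthetic study
#'
#' One complete synthetic "study": ground-truth parameters, the seeded
#' angle-observation table and (optionally) a modulus-observation table.
#'
#' @inheritParams generate_angle_observations
#' @param modulus_curves optional curves passed to
#'   [generate_modulus_observations()]; `NULL` skips the modulus table.
#' @param ... further arguments to [generate_angle_observations()].
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(truth, seed = 1L, modulus_curves = NULL, ...) {
  angle_obs <- generate_angle_observations(truth, seed = seed, ...)
  modulus_obs <- if (!is.null(modulus_curves))
    generate_modulus_observations(modulus_curves, seed = seed + 1L)
  structure(list(seed = as.integer(seed), truth = truth,
                 angle_obs = angle_obs, modulus_obs = modulus_obs),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study (seed %d): %d angle observations, truth E_passive_dry = %g MPa, eps_max = %g\n",
    x$seed, nrow(x$angle_obs), x$truth$E_passive_dry, x$truth$eps_max))
  invisible(x)
}

#' Recover drying-path parameters from synthetic studies
#'
#' For each study, fits the fully dry passive modulus (and optionally the
#' maximal contraction) to the study's angle observations with
#' [scale_fit()], then aggregates across studies: mean and median estimate,
#' bias, relative bias and root-mean-square error against the shared ground
#' truth. Studies whose estimate pins at the fit bracket are flagged
#' non-convergent and excluded from the aggregates (the exclusion count is
#' reported).
#'
#' @param studies a [synthetic_study()] or list of them (shared truth).
#' @param model a [scale_model()].
#' @param what parameters to fit; see [scale_fit()].
#' @param bracket `E_passive_dry` fit bracket, MPa.
#' @param curve passive-layer [material_curve()].
#' @return An object of class `recovery_report`: `per_study` data frame
#'   (`seed`, `E_passive_dry`, `converged`, `rss`) and `summary` list
#'   (`truth`, `n_studies`, `n_excluded`, `mean_estimate`,
#'   `median_estimate`, `bias`, `relative_bias`, `rmse`).
#' @examples
#' st <- synthetic_study(list(E_passive_dry = 1170, eps_max = 0.22),
#'                       seed = 3, n_scales = 5, noise_sd = 1)
#' recover_parameters(st)
#' @export
recover_parameters <- function(studies, model = scale_model(),
                               what = "E_passive_dry",
                               bracket = c(200, 5000),
                               curve = material_preset("sclerenchyma_sim")) {
  if (inherits(studies, "synthetic_study")) studies <- list(studies)
  stopifnot(length(studies) >= 1L,
            all(vapply(studies, inherits, logical(1), "synthetic_study")))
  truth <- studies[[1L]]$truth

  per <- lapply(studies, function(st) {
    fit <- scale_fit(gamma_obs_deg ~ rh_percent, st$angle_obs,
                     model = model, what = what,
                     path_template = drying_path(eps_max = truth$eps_max),
                     bracket = bracket, curve = curve)
    data.frame(seed = st$seed,
               E_passive_dry = coef(fit)[["E_passive_dry"]],
               converged = fit$converged, rss = fit$rss)
  })
  per <- do.call(rbind, per)
  ok <- per$converged
  est <- per$E_passive_dry[ok]
  tv <- truth$E_passive_dry
  summary <- list(
    truth = tv, n_studies = nrow(per), n_excluded = sum(!ok),
    mean_estimate = if (any(ok)) mean(est) else NA_real_,
    median_estimate = if (any(ok)) stats::median(est) else NA_real_,
    bias = if (any(ok)) mean(est) - tv else NA_real_,
    relative_bias = if (any(ok)) (stats::median(est) - tv) / tv else NA_real_,
    rmse = if (any(ok)) sqrt(mean((est - tv)^2)) else NA_real_)
  structure(list(per_study = per, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Parameter recovery over %d studies (%d excluded)\n",
              s$n_studies, s$n_excluded))
  cat(sprintf("  truth %g MPa | median estimate %s | relative bias %s | RMSE %s\n",
              s$truth,
              if (is.na(s$median_estimate)) "NA" else sprintf("%.1f", s$median_estimate),
              if (is.na(s$relative_bias)) "NA" else sprintf("%.2f%%", 100 * s$relative_bias),
              if (is.na(s$rmse)) "NA" else sprintf("%.1f MPa", s$rmse)))
  invisible(x)
}

#' Monte-Carlo recovery experiment
#'
#' Convenience driver: generates `n_seeds` independent synthetic studies
#' (seeds `base_seed + 1 ... base_seed + n_seeds`) at the given truth and
#' observation design and runs [recover_parameters()] on them.
#'
#' @inheritParams generate_angle_observations
#' @param n_seeds number of studies. Default 200.
#' @param base_seed offset for the per-study seeds. Default 0.
#' @param bracket fit bracket, MPa.
#' @param what parameters to fit.
#' @return A `recovery_report` (see [recover_parameters()]).
#' @export
recovery_experiment <- function(truth = list(E_passive_dry = 1170,
                                             eps_max = 0.22),
                                n_seeds = 200L, n_scales = 20L,
                                noise_sd = 1, size_cv = 0.15,
                                base_seed = 0L, model = scale_model(),
                                bracket = c(200, 5000),
                                what = "E_passive_dry",
                                curve = material_preset("sclerenchyma_sim")) {
  studies <- lapply(seq_len(n_seeds), function(i)
    synthetic_study(truth, seed = base_seed + i, n_scales = n_scales,
                    noise_sd = noise_sd, size_cv = size_cv, model = model,
                    curve = curve))
  recover_parameters(studies, model = model, what = what,
                     bracket = bracket, curve = curve)
}
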