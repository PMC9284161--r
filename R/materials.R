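#' Humidity-dependent tissue modulus curve
#'
#' A piecewise-linear Young's modulus vs relative-humidity curve for one
#' scale tissue. Between knots the modulus is interpolated linearly; outside
#' the measured humidity range the curve is clamped to the nearest endpoint
#' value, so a curve never extrapolates to non-physical (e.g. negative)
#' moduli.
#'
#' @param tissue character label for the tissue.
#' @param rh numeric vector of relative-humidity knots, percent, strictly
#'   increasing, in \eqn{[0, 100]}.
#' @param E numeric vector of Young's moduli at the knots, MPa, all positive.
#' @return An object of class `material_curve`.
#' @seealso [young_modulus()], [material_preset()]
#' @examples
#' sf <- material_curve("sclerenchyma_sim", rh = c(30, 80), E = c(800, 180))
#' young_modulus(sf, c(30, 55, 80))
#' @export
material_curve <- function(tissue, rh, E) {
  if (length(rh) < 1L)
    stop("material_curve: at least one (rh, E) knot is required", call. = FALSE)
  if (length(rh) != length(E))
    stop("material_curve: 'rh' and 'E' must have equal length", call. = FALSE)
  if (anyNA(rh) || anyNA(E) || !all(is.finite(rh)) || !all(is.finite(E)))
    stop("material_curve: knots must be finite", call. = FALSE)
  if (any(rh < 0) || any(rh > 100))
    stop("material_curve: rh knots must lie in [0, 100]", call. = FALSE)
  if (is.unsorted(rh, strictly = TRUE))
    stop("material_curve: rh knots must be strictly increasing", call. = FALSE)
  if (any(E <= 0))
    stop("material_curve: all moduli must be positive", call. = FALSE)
  structure(
    list(tissue = as.character(tissue)[1L],
         rh = as.numeric(rh), E = as.numeric(E)),
    class = "material_curve")
}

#' @export
print.material_curve <- function(x, ...) {
  cat("Material curve:", x$tissue, "\n")
  print(data.frame(rh_percent = x$rh, E_MPa = x$E), row.names = FALSE)
  invisible(x)
}

#' Tissue material: modulus curve plus elastic constants
#'
#' Couples a [material_curve()] with a Poisson's ratio and an optional
#' plane-strain switch. Under plane strain the effective uniaxial modulus is
#' \eqn{E/(1-\nu^2)}; the default mechanics are uniaxial and leave the
#' modulus untouched. Because both layers of the laminate are scaled by the
#' same factor, the switch changes section stiffness but not the free
#' curvature; it exists so the effect of the plane-strain idealization can
#' be reported.
#'
#' @param curve a [material_curve()].
#' @param poisson_ratio Poisson's ratio, in \eqn{[0, 0.5)}. Default 0.3.
#' @param plane_strain logical; apply the \eqn{1/(1-\nu^2)} stiffening.
#' @return An object of class `tissue_material`.
#' @export
tissue_material <- function(curve, poisson_ratio = 0.3, plane_strain = FALSE) {
  stopifnot(inherits(curve, "material_curve"))
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("tissue_material: poisson_ratio must lie in [0, 0.5)", call. = FALSE)
  structure(
    list(curve = curve, poisson_ratio = poisson_ratio,
         plane_strain = isTRUE(plane_strain)),
    class = "tissue_material")
}

#' Evaluate a Young's modulus curve
#'
#' Piecewise-linear interpolation of a tissue modulus at the requested
#' relative humidity, clamped to the endpoint values outside the knot range.
#' For a `tissue_material` with plane strain enabled the interpolated value
#' is divided by \eqn{1-\nu^2}.
#'
#' @param material a [material_curve()] or [tissue_material()].
#' @param rh relative humidity, percent; may be a vector.
#' @param ... unused.
#' @return Young's modulus in MPa, same length as `rh`.
#' @export
young_modulus <- function(material, rh, ...) UseMethod("young_modulus")

#' @rdname young_modulus
#' @export
young_modulus.material_curve <- function(material, rh, ...) {
  if (anyNA(rh) || !all(is.finite(rh)))
    stop("young_modulus: rh must be finite", call. = FALSE)
  if (length(material$rh) == 1L)
    return(rep(material$E, length(rh)))
  # rule = 2 clamps to the endpoint values outside the knot range
  stats::approx(material$rh, material$E, xout = rh, rule = 2)$y
}

#' @rdname young_modulus
#' @export
young_modulus.tissue_material <- function(material, rh, ...) {
  E <- young_modulus(material$curve, rh)
  if (material$plane_strain) E / (1 - material$poisson_ratio^2) else E
}

#' Invert a monotone modulus curve to an equivalent humidity
#'
#' For a strictly monotone [material_curve()] this returns the relative
#' humidity at which the curve takes the value `E`, clamped to the curve's
#' humidity range when `E` lies outside the attained moduli. Used to label
#' drying-path states with a humidity equivalent.
#'
#' @param curve a strictly monotone [material_curve()] with at least 2 knots.
#' @param E modulus value(s), MPa.
#' @return relative humidity, percent.
#' @export
rh_equivalent <- function(curve, E) {
  stopifnot(inherits(curve, "material_curve"))
  if (length(curve$rh) < 2L)
    stop("rh_equivalent: curve needs at least two knots", call. = FALSE)
  dE <- diff(curve$E)
  if (!(all(dE > 0) || all(dE < 0)))
    stop("rh_equivalent: curve is not strictly monotone", call. = FALSE)
  stats::approx(curve$E, curve$rh, xout = E, rule = 2)$y
}

#' Preset tissue modulus curves
#'
#' Curves digitized from atomic-force-microscopy indentation of the three
#' load-bearing scale tissues, plus the two-knot sclerenchyma curve used in
#' the bending simulations:
#' \describe{
#'   \item{`sclerenchyma_sim`}{800 MPa at 30\% rh to 180 MPa at 80\% rh;
#'     the simulation preset used by calibration and sweeps.}
#'   \item{`sclerenchyma_afm`}{the indentation trend, 800 MPa at 30\% rh to
#'     200 MPa at 75\% rh.}
#'   \item{`sclereid_afm`}{near-constant 35 MPa up to 50\% rh, step down to
#'     25 MPa at 60\% rh, constant above.}
#'   \item{`brown_tissue`}{constant 52 MPa up to 70\% rh, 43 MPa at 80\%.}
#' }
#'
#' @param name preset name; one of the names above.
#' @param file optional path to a CSV with columns
#'   `tissue,rh_percent,E_MPa` overriding the packaged table.
#' @return A [material_curve()].
#' @examples
#' young_modulus(material_preset("brown_tissue"), 50)
#' @export
material_preset <- function(name, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "material_curves.csv", package = "conebend",
                        mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("tissue", "rh_percent", "E_MPa")
  if (!all(need %in% names(tab)))
    stop("material_preset: file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  tab <- tab[tab$tissue == name, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("material_preset: no curve named '", name, "' in ", file, call. = FALSE)
  tab <- tab[order(tab$rh_percent), , drop = FALSE]
  material_curve(name, tab$rh_percent, tab$E_MPa)
}

#' Sclereid modulus regression
#'
#' The active (sclereid) layer modulus approximated by a linear regression
#' between its dry-end and wet-end values: 37 MPa at 30\% rh falling to
#' 21 MPa at 80\% rh, clamped outside that humidity range.
#'
#' @param rh relative humidity, percent; may be a vector.
#' @return modulus in MPa.
#' @export
sclereid_modulus <- function(rh) {
  rh <- pmin(pmax(rh, 30), 80)
  37 + (21 - 37) * (rh - 30) / (80 - 30)
}

#' Drying path: coupled contraction and passive-layer stiffening
#'
#' A scalar drying coordinate \eqn{\xi \in [0, 1]} (0 = fully wet, 1 = fully
#' dry) along which the active layer's longitudinal contraction and the
#' passive layer's Young's modulus both vary linearly:
#' \deqn{\varepsilon_a(\xi) = -\varepsilon_{max}\,\xi, \qquad
#'       E_p(\xi) = E_{wet} + (E_{dry} - E_{wet})\,\xi.}
#' The defaults are the fully-dry contraction of 22\% observed by micro-CT,
#' a fully wet passive modulus of 70 MPa, and the calibrated fully dry
#' passive modulus of 1170 MPa.
#'
#' @param eps_max maximal active-layer contraction (positive number,
#'   dimensionless strain). Default 0.22.
#' @param E_passive_wet passive-layer modulus when fully wet, MPa. Default 70.
#' @param E_passive_dry passive-layer modulus when fully dry, MPa.
#'   Default 1170.
#' @return An object of class `drying_path`.
#' @export
drying_path <- function(eps_max = 0.22, E_passive_wet = 70,
                        E_passive_dry = 1170) {
  stopifnot(is.numeric(eps_max), length(eps_max) == 1L, eps_max >= 0,
            is.numeric(E_passive_wet), E_passive_wet > 0,
            is.numeric(E_passive_dry), E_passive_dry > 0)
  if (E_passive_dry <= E_passive_wet)
    stop("drying_path: E_passive_dry must exceed E_passive_wet ",
         "(the passive layer stiffens on drying)", call. = FALSE)
  structure(
    list(eps_max = eps_max, E_passive_wet = E_passive_wet,
         E_passive_dry = E_passive_dry),
    class = "drying_path")
}

#' @export
print.drying_path <- function(x, ...) {
  cat(sprintf(
    "Drying path: eps_active 0 -> -%.4g, E_passive %.4g -> %.4g MPa\n",
    x$eps_max, x$E_passive_wet, x$E_passive_dry))
  invisible(x)
}

#' Active-layer contraction along the drying path
#'
#' @param path a [drying_path()].
#' @param xi drying coordinate(s) in \eqn{[0, 1]}.
#' @return longitudinal eigenstrain (non-positive), same length as `xi`.
#' @export
active_strain <- function(path, xi) {
  stopifnot(inherits(path, "drying_path"))
  if (anyNA(xi) || any(xi < 0) || any(xi > 1))
    stop("active_strain: xi must lie in [0, 1]", call. = FALSE)
  -path$eps_max * xi
}

#' Passive-layer modulus along the drying path
#'
#' @inheritParams active_strain
#' @return modulus in MPa, same length as `xi`.
#' @export
passive_modulus <- function(path, xi) {
  stopifnot(inherits(path, "drying_path"))
  if (anyNA(xi) || any(xi < 0) || any(xi > 1))
    stop("passive_modulus: xi must lie in [0, 1]", call. = FALSE)
  path$E_passive_wet + (path$E_passive_dry - path$E_passive_wet) * xi
}

#' Map relative humidity to the drying coordinate
#'
#' Places a humidity state on the drying path by matching the passive-layer
#' modulus: \eqn{\xi(rh) = (E_{curve}(rh) - E_{wet}) / (E_{dry} - E_{wet})},
#' clipped to \eqn{[0, 1]}. With the simulation sclerenchyma curve and the
#' default path, 80\% rh (180 MPa) maps to \eqn{\xi = 0.1} and 30\% rh
#' (800 MPa) to \eqn{\xi \approx 0.664}.
#'
#' @param path a [drying_path()].
#' @param curve the passive-layer [material_curve()] (modulus vs rh).
#' @param rh relative humidity, percent; may be a vector.
#' @return drying coordinate(s) in \eqn{[0, 1]}.
#' @export
xi_from_rh <- function(path, curve, rh) {
  stopifnot(inherits(path, "drying_path"))
  E <- young_modulus(curve, rh)
  xi <- (E - path$E_passive_wet) / (path$E_passive_dry - path$E_passive_wet)
  pmin(pmax(xi, 0), 1)
}
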