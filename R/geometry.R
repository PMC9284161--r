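#' Layer thickness profile
#'
#' Thickness of one laminate layer at the start and end of the bending zone;
#' between the two printed cross-sections the thickness varies linearly with
#' arclength.
#'
#' @param layer_name `"active"` (sclereid) or `"passive"` (sclerenchyma).
#' @param t_start,t_end thickness at the zone start / end, mm, positive.
#' @return An object of class `layer_profile`.
#' @export
layer_profile <- function(layer_name, t_start, t_end) {
  layer_name <- match.arg(layer_name, c("active", "passive"))
  stopifnot(is.numeric(t_start), is.numeric(t_end))
  if (t_start <= 0 || t_end <= 0)
    stop("layer_profile: thicknesses must be positive", call. = FALSE)
  structure(list(layer_name = layer_name,
                 t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
            class = "layer_profile")
}

#' Bending-zone geometry
#'
#' The proximal bending zone of the scale as a two-layer tapered stack. The
#' default dimensions are the two cross-sections measured in the dry, open
#' state: at the zone start the scale is 1.8 mm wide with a 0.8 mm sclereid
#' (active) layer under a 0.6 mm sclerenchyma (passive) layer; at the zone
#' end it is 3.5 mm wide with 0.65 mm / 0.43 mm layers. All dimensions vary
#' linearly in between. The zone length is not measured and defaults to
#' 4.0 mm; it is always echoed in downstream outputs.
#'
#' @param length_mm bending-zone length, mm. Default 4.0.
#' @param width_start_mm,width_end_mm scale width at zone start / end, mm.
#' @param active,passive [layer_profile()]s for the two layers.
#' @param n_stations number of evaluation stations along the zone
#'   (uniform spacing), integer >= 2. Default 51.
#' @return An object of class `bending_zone`.
#' @export
bending_zone <- function(length_mm = 4,
                         width_start_mm = 1.8, width_end_mm = 3.5,
                         active = layer_profile("active", 0.8, 0.65),
                         passive = layer_profile("passive", 0.6, 0.43),
                         n_stations = 51L) {
  stopifnot(inherits(active, "layer_profile"), inherits(passive, "layer_profile"))
  if (!is.numeric(length_mm) || length_mm <= 0)
    stop("bending_zone: length_mm must be positive", call. = FALSE)
  if (width_start_mm <= 0 || width_end_mm <= 0)
    stop("bending_zone: widths must be positive", call. = FALSE)
  n_stations <- as.integer(n_stations)
  if (is.na(n_stations) || n_stations < 2L)
    stop("bending_zone: n_stations must be an integer >= 2", call. = FALSE)
  structure(
    list(length_mm = as.numeric(length_mm),
         width_start_mm = as.numeric(width_start_mm),
         width_end_mm = as.numeric(width_end_mm),
         active = active, passive = passive, n_stations = n_stations),
    class = "bending_zone")
}

#' Whole-scale model
#'
#' A [bending_zone()] plus the rigid distal lever. The lever does not deform;
#' it only translates the bending-zone tip rotation into a tip displacement
#' for postprocessing. `active_side` fixes the sign convention: with the
#' active layer abaxial (below), drying bends the scale upward and the
#' opening angle is positive.
#'
#' @param zone a [bending_zone()].
#' @param lever_mm rigid lever length, mm, non-negative. Default 40.
#' @param active_side `"abaxial"` (default) or `"adaxial"`; flipping it
#'   flips the sign of curvature and angle.
#' @return An object of class `scale_model`.
#' @examples
#' m <- scale_model()
#' validate_geometry(m)
#' @export
scale_model <- function(zone = bending_zone(), lever_mm = 40,
                        active_side = c("abaxial", "adaxial")) {
  stopifnot(inherits(zone, "bending_zone"))
  active_side <- match.arg(active_side)
  if (!is.numeric(lever_mm) || lever_mm < 0)
    stop("scale_model: lever_mm must be non-negative", call. = FALSE)
  structure(list(zone = zone, lever_mm = as.numeric(lever_mm),
                 active_side = active_side),
            class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  z <- x$zone
  cat("Pine cone scale model\n")
  cat(sprintf("  bending zone: L = %g mm, %d stations\n", z$length_mm, z$n_stations))
  cat(sprintf("  width: %g -> %g mm\n", z$width_start_mm, z$width_end_mm))
  cat(sprintf("  active layer (sclereid): %g -> %g mm (%s)\n",
              z$active$t_start, z$active$t_end, x$active_side))
  cat(sprintf("  passive layer (sclerenchyma): %g -> %g mm\n",
              z$passive$t_start, z$passive$t_end))
  cat(sprintf("  rigid lever: %g mm\n", x$lever_mm))
  invisible(x)
}

#' Cross-section dimensions at an arclength station
#'
#' Linear interpolation of width and layer thicknesses between the zone's
#' start and end cross-sections. `s` runs proximal to distal, 0 at the
#' clamped base.
#'
#' @param zone a [bending_zone()].
#' @param s arclength(s) in mm, within `[0, length_mm]`.
#' @return A data frame with columns `s_mm`, `width_mm`, `t_active_mm`,
#'   `t_passive_mm`.
#' @export
section_at <- function(zone, s) {
  stopifnot(inherits(zone, "bending_zone"))
  if (anyNA(s) || any(s < 0) || any(s > zone$length_mm))
    stop("section_at: s must lie in [0, length_mm]", call. = FALSE)
  f <- s / zone$length_mm
  data.frame(
    s_mm = s,
    width_mm = zone$width_start_mm + (zone$width_end_mm - zone$width_start_mm) * f,
    t_active_mm = zone$active$t_start + (zone$active$t_end - zone$active$t_start) * f,
    t_passive_mm = zone$passive$t_start + (zone$passive$t_end - zone$passive$t_start) * f)
}

#' Check a scale model for geometric invariant violations
#'
#' Reports, rather than errors on, violated invariants: non-positive zone
#' length, widths or thicknesses (at either end, hence anywhere, since all
#' dimensions are linear in arclength), too few stations, and a negative
#' lever. The default model yields an empty report.
#'
#' @param model a [scale_model()] (or a bare list with the same fields, so
#'   deliberately broken geometries can be diagnosed).
#' @return A character vector of violation messages; empty if the geometry
#'   is valid.
#' @export
validate_geometry <- function(model) {
  z <- model$zone
  bad <- character(0)
  chk <- function(cond, msg) if (isTRUE(cond)) c(bad, msg) else bad
  bad <- chk(!is.numeric(z$length_mm) || z$length_mm <= 0,
             "bending-zone length must be positive")
  bad <- chk(z$width_start_mm <= 0 || z$width_end_mm <= 0,
             "widths must be positive at both ends")
  bad <- chk(z$active$t_start <= 0 || z$active$t_end <= 0,
             "active-layer thickness must be positive at both ends")
  bad <- chk(z$passive$t_start <= 0 || z$passive$t_end <= 0,
             "passive-layer thickness must be positive at both ends")
  bad <- chk(is.null(z$n_stations) || z$n_stations < 2,
             "n_stations must be at least 2")
  bad <- chk(!is.null(model$lever_mm) && model$lever_mm < 0,
             "lever length must be non-negative")
  bad
}
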