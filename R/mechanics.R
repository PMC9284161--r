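#' Free membrane strain and curvature of a layered cross-section
#'
#' Solves the plane-section equilibrium of a stack of rectangular layers
#' carrying per-layer eigenstrains (stress-free hygroscopic strains). The
#' relieved state carries no net axial force and no net bending moment, so
#' with axial strain \eqn{\varepsilon(z) = \varepsilon_0 + \kappa z} the
#' unknowns solve the 2x2 system
#' \deqn{\begin{pmatrix}\sum EA & \sum ES \\ \sum ES & \sum EI\end{pmatrix}
#'       \begin{pmatrix}\varepsilon_0 \\ \kappa\end{pmatrix} =
#'       \begin{pmatrix}\sum EA\,\varepsilon^* \\
#'                      \sum EA\,\bar z\,\varepsilon^*\end{pmatrix}}
#' with exact rectangle integrals per layer (\eqn{ES = EA\bar z},
#' \eqn{EI = E(wt^3/12 + A\bar z^2)}).
#'
#' Layers are listed bottom to top; `z = 0` sits at the top of the first
#' layer (for a bilayer, the active/passive interface), positive toward the
#' top (passive, adaxial) side. The curvature is independent of this choice
#' of reference axis; the membrane strain refers to it.
#'
#' @param layers data frame with columns `thickness` (mm), `width` (mm),
#'   `modulus` (MPa) and `eigenstrain` (dimensionless), one row per layer,
#'   bottom to top, stacked contiguously.
#' @param z_ref optional shift of the reference axis (mm); the returned
#'   membrane strain refers to `z = z_ref`. Curvature is unaffected.
#' @return A list of class `section_response` with elements `eps0`
#'   (membrane strain at the reference axis) and `kappa` (curvature, 1/mm).
#' @examples
#' bilayer <- data.frame(thickness = c(0.8, 0.6), width = 1.8,
#'                       modulus = c(37, 1170), eigenstrain = c(-0.22, 0))
#' section_response(bilayer)
#' @export
section_response <- function(layers, z_ref = 0) {
  need <- c("thickness", "width", "modulus", "eigenstrain")
  if (!is.data.frame(layers) || !all(need %in% names(layers)))
    stop("section_response: 'layers' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  t <- layers$thickness; w <- layers$width
  E <- layers$modulus; eps <- layers$eigenstrain
  if (any(t <= 0) || any(w <= 0))
    stop("section_response: thicknesses and widths must be positive",
         call. = FALSE)
  if (any(E <= 0))
    stop("section_response: moduli must be positive", call. = FALSE)
  nl <- length(t)
  # contiguous stack: layer 1 occupies [-t1, 0], the rest pile upward
  z_bot <- c(-t[1L], if (nl > 1L) cumsum(c(0, t[-c(1L, nl)])))
  z_c <- z_bot + t / 2 - z_ref
  A <- w * t
  EA <- sum(E * A)
  ES <- sum(E * A * z_c)
  EI <- sum(E * (w * t^3 / 12 + A * z_c^2))
  b1 <- sum(E * A * eps)
  b2 <- sum(E * A * z_c * eps)
  det <- EA * EI - ES^2
  if (!is.finite(det) || det <= 0)
    stop("section_response: singular section stiffness (zero area?)",
         call. = FALSE)
  structure(list(eps0 = (EI * b1 - ES * b2) / det,
                 kappa = (EA * b2 - ES * b1) / det),
            class = "section_response")
}

#' @export
print.section_response <- function(x, ...) {
  cat(sprintf("Section response: eps0 = %.6g, kappa = %.6g 1/mm\n",
              x$eps0, x$kappa))
  invisible(x)
}

#' Bimetallic-strip curvature (closed form)
#'
#' The classic two-layer strip curvature under a free-strain mismatch
#' \eqn{\Delta\varepsilon} between the layers,
#' \deqn{\kappa = \frac{6\,\Delta\varepsilon\,(1+m)^2}
#'   {h\left[3(1+m)^2 + (1+mn)\left(m^2 + \frac{1}{mn}\right)\right]},}
#' with \eqn{m = t_1/t_2}, \eqn{n = E_1/E_2} and \eqn{h = t_1 + t_2}.
#' Layer 1 is the top (passive) layer; \eqn{\Delta\varepsilon =
#' \varepsilon^*_1 - \varepsilon^*_2}, so a contracting bottom layer gives
#' positive \eqn{\Delta\varepsilon} and positive curvature. Serves as the
#' analytic oracle for [section_response()] on uniform bilayers.
#'
#' @param t1,t2 layer thicknesses, mm (layer 1 on top), positive.
#' @param E1,E2 layer moduli, MPa, positive.
#' @param delta_eps free-strain mismatch, top minus bottom layer.
#' @return curvature, 1/mm; same sign as `delta_eps`.
#' @export
timoshenko_curvature <- function(t1, t2, E1, E2, delta_eps) {
  if (any(c(t1, t2) <= 0))
    stop("timoshenko_curvature: thicknesses must be positive", call. = FALSE)
  if (any(c(E1, E2) <= 0))
    stop("timoshenko_curvature: moduli must be positive", call. = FALSE)
  m <- t1 / t2
  n <- E1 / E2
  h <- t1 + t2
  6 * delta_eps * (1 + m)^2 /
    (h * (3 * (1 + m)^2 + (1 + m * n) * (m^2 + 1 / (m * n))))
}

#' Mechanical state of the laminate
#'
#' Bundles the quantities that define one humidity state of the bending
#' zone: the active-layer longitudinal eigenstrain and the two layer moduli.
#'
#' @param eps_active active-layer eigenstrain (contraction is negative).
#' @param E_active active-layer (sclereid) modulus, MPa.
#' @param E_passive passive-layer (sclerenchyma) modulus, MPa.
#' @return An object of class `scale_state`.
#' @export
scale_state <- function(eps_active, E_active, E_passive) {
  stopifnot(is.numeric(eps_active), is.numeric(E_active), is.numeric(E_passive))
  if (E_active <= 0 || E_passive <= 0)
    stop("scale_state: moduli must be positive", call. = FALSE)
  structure(list(eps_active = eps_active, E_active = E_active,
                 E_passive = E_passive), class = "scale_state")
}

# Vectorized bilayer curvature over stations. Same algebra as
# section_response() restricted to two layers: active below [-ta, 0],
# passive above [0, tp]; equality with the general solver is asserted in
# the test suite.
.kappa_bilayer <- function(ta, tp, w, Ea, Ep, eps_a, eps_p = 0) {
  za <- -ta / 2
  zp <- tp / 2
  Aa <- w * ta; Ap <- w * tp
  EA <- Ea * Aa + Ep * Ap
  ES <- Ea * Aa * za + Ep * Ap * zp
  EI <- Ea * (w * ta^3 / 12 + Aa * za^2) + Ep * (w * tp^3 / 12 + Ap * zp^2)
  b1 <- Ea * Aa * eps_a + Ep * Ap * eps_p
  b2 <- Ea * Aa * za * eps_a + Ep * Ap * zp * eps_p
  (EA * b2 - ES * b1) / (EA * EI - ES^2)
}

# Cumulative quadrature on a uniform grid: composite Simpson-type rule with
# parabolic sub-interval increments (4th-order accurate). Exact for
# quadratic integrands; reduces to the trapezoid on 2 points.
.cumquad <- function(f, h) {
  n <- length(f)
  if (n == 2L) return(c(0, h * (f[1L] + f[2L]) / 2))
  inc <- h / 12 * (5 * f[1:(n - 2L)] + 8 * f[2:(n - 1L)] - f[3:n])
  inc[n - 1L] <- h / 12 * (-f[n - 2L] + 8 * f[n - 1L] + 5 * f[n])
  c(0, cumsum(inc))
}

#' Bend the scale under one mechanical state
#'
#' Forward simulation of the bending zone: at each arclength station the
#' free curvature of the local bilayer section is computed from
#' [section_response()]'s equilibrium, the rotation
#' \eqn{\theta(s) = \int_0^s \kappa\,ds} is accumulated by a 4th-order
#' quadrature on the uniform station grid, and the centerline follows by
#' integrating \eqn{(\cos\theta, \sin\theta)} — the finite-rotation
#' (elastica) geometry of a load-free eigenstrain-bent beam, whose curvature
#' field is state-determined. The rigid lever extends the centerline beyond
#' the zone at the final rotation. The reported opening angle
#' \eqn{\gamma = \theta(L)} is measured from the (unbent) wet reference, in
#' degrees.
#'
#' @param model a [scale_model()].
#' @param state a [scale_state()], or the three components as named
#'   arguments via `...`.
#' @param ... `eps_active`, `E_active`, `E_passive` if `state` is missing.
#' @return An object of class `bend_result`: list with `stations` (mm),
#'   `kappa` (1/mm), `theta` (rad), `centerline` (data frame `x_mm`, `y_mm`
#'   per station plus a final lever-tip row), `gamma_deg`, and the echoed
#'   `state` and `model`.
#' @examples
#' b <- bend_scale(scale_model(), scale_state(-0.22, 37, 1170))
#' b$gamma_deg
#' @export
bend_scale <- function(model, state, ...) {
  stopifnot(inherits(model, "scale_model"))
  if (missing(state)) state <- scale_state(...)
  stopifnot(inherits(state, "scale_state"))
  z <- model$zone
  if (z$n_stations < 2L)
    stop("bend_scale: n_stations must be at least 2", call. = FALSE)
  s <- seq(0, z$length_mm, length.out = z$n_stations)
  sec <- section_at(z, s)
  kap <- .kappa_bilayer(sec$t_active_mm, sec$t_passive_mm, sec$width_mm,
                        state$E_active, state$E_passive, state$eps_active)
  if (identical(model$active_side, "adaxial")) kap <- -kap
  h <- s[2L] - s[1L]
  theta <- .cumquad(kap, h)
  x <- .cumquad(cos(theta), h)
  y <- .cumquad(sin(theta), h)
  n <- length(s)
  centerline <- data.frame(
    x_mm = c(x, x[n] + model$lever_mm * cos(theta[n])),
    y_mm = c(y, y[n] + model$lever_mm * sin(theta[n])))
  structure(
    list(stations = s, kappa = kap, theta = theta, centerline = centerline,
         gamma_deg = theta[n] * 180 / pi, state = state, model = model),
    class = "bend_result")
}

#' @export
print.bend_result <- function(x, ...) {
  cat(sprintf(
    "Bend result: gamma = %.4f deg (eps_a = %.4g, E_a = %.4g MPa, E_p = %.4g MPa, L = %g mm)\n",
    x$gamma_deg, x$state$eps_active, x$state$E_active, x$state$E_passive,
    x$model$zone$length_mm))
  invisible(x)
}

#' @export
plot.bend_result <- function(x, ...) {
  cl <- x$centerline
  graphics::plot(cl$x_mm, cl$y_mm, type = "l", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("Deformed centerline, gamma = %.2f deg",
                                x$gamma_deg), ...)
  n <- nrow(cl)
  graphics::points(cl$x_mm[c(1L, n - 1L, n)], cl$y_mm[c(1L, n - 1L, n)],
                   pch = c(15, 16, 17))
  invisible(x)
}

#' Angular change between two mechanical states
#'
#' Difference of opening angles \eqn{\gamma(B) - \gamma(A)}; antisymmetric
#' under swapping the states. Because curvature is a state function, the
#' angular change over a drying interval does not depend on the path taken
#' between the states.
#'
#' @param model a [scale_model()].
#' @param state_A,state_B [scale_state()]s.
#' @return angular change in degrees.
#' @export
angular_change <- function(model, state_A, state_B) {
  bend_scale(model, state_B)$gamma_deg - bend_scale(model, state_A)$gamma_deg
}

# Opening angle only, vectorized over states (columns of equal-length
# numeric vectors). Fast path used by calibration and recovery fits; same
# kernel and quadrature as bend_scale().
.gamma_states <- function(model, eps_active, E_active, E_passive) {
  z <- model$zone
  s <- seq(0, z$length_mm, length.out = z$n_stations)
  sec <- section_at(z, s)
  h <- s[2L] - s[1L]
  n_states <- max(length(eps_active), length(E_active), length(E_passive))
  eps_active <- rep_len(eps_active, n_states)
  E_active <- rep_len(E_active, n_states)
  E_passive <- rep_len(E_passive, n_states)
  sgn <- if (identical(model$active_side, "adaxial")) -1 else 1
  vapply(seq_len(n_states), function(i) {
    kap <- .kappa_bilayer(sec$t_active_mm, sec$t_passive_mm, sec$width_mm,
                          E_active[i], E_passive[i], eps_active[i])
    th <- .cumquad(sgn * kap, h)
    th[length(th)] * 180 / pi
  }, numeric(1))
}
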