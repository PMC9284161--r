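# Shared fixtures and independent oracles for the suite.

default_model <- function(...) scale_model(zone = bending_zone(...))

sf_sim <- function() material_curve("sclerenchyma_sim", c(30, 80), c(800, 180))

# Draw a random physically plausible two-layer section.
random_bilayer <- function() {
  list(t_active = runif(1, 0.1, 2), t_passive = runif(1, 0.1, 2),
       width = runif(1, 0.5, 5),
       E_active = runif(1, 5, 200), E_passive = runif(1, 50, 3000),
       eps = runif(1, -0.3, 0.3))
}

# Opening angle by brute-force dense trapezoid quadrature of per-station
# section_response() calls -- independent of the vectorized bend path.
gamma_brute <- function(model, state, n = 4001) {
  z <- model$zone
  s <- seq(0, z$length_mm, length.out = n)
  kap <- vapply(s, function(si) {
    sec <- section_at(z, si)
    section_response(data.frame(
      thickness = c(sec$t_active_mm, sec$t_passive_mm),
      width = sec$width_mm,
      modulus = c(state$E_active, state$E_passive),
      eigenstrain = c(state$eps_active, 0)))$kappa
  }, numeric(1))
  h <- s[2] - s[1]
  sum((kap[-1] + kap[-n]) / 2 * h) * 180 / pi
}
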