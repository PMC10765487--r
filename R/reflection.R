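#' Reflected axial pressure at a stone surface
#'
#' At an impedance boundary the surface pressure induced by normal
#' reflection is pr = 2 pi I2 / (I1 + I2), with I1/I2 the acoustic
#' impedances of water and stone. Evaluated at the stone's proximal
#' surface and propagated back toward the source as a mirrored wave of
#' amplitude |Gamma| pi(zs), Gamma = (I2 - I1)/(I2 + I1), so that the
#' superposition with the incident wave forms the standing-wave
#' envelope.
#'
#' @param incident an [axial_profile()] of the incident amplitude
#' @param stone a [stone_spec()] whose proximal surface (`apex_z`) lies
#'   within the profile range
#' @return a list with `surface_pressure` (pr at the surface, Pa),
#'   `reflected` (an [axial_profile()] of the back-propagated reflected
#'   amplitude, nonzero for z <= apex_z) and `envelope` (an
#'   [axial_profile()] of the standing-wave amplitude envelope; requires
#'   the carrier wavelength attribute set by [standing_wave_envelope()])
#' @export
reflected_axial_pressure <- function(incident, stone) {
  stopifnot(inherits(incident, "axial_profile"), inherits(stone, "stone_spec"))
  ratio <- stone$impedance_ratio                # I2/I1
  if (1 + ratio == 0) stopf("I1 + I2 must be nonzero")
  zs <- stone$apex_z
  if (zs < min(incident$z) || zs > max(incident$z))
    stopf("stone surface position lies outside the incident profile range")
  pi_s <- linear_interp(incident$z, incident$p, zs)
  pr_s <- 2 * pi_s * ratio / (1 + ratio)
  gamma <- (ratio - 1) / (ratio + 1)            # amplitude reflection coeff.
  refl <- ifelse(incident$z <= zs, abs(gamma) * pi_s, 0)
  list(surface_pressure = pr_s,
       reflection_coefficient = gamma,
       reflected = axial_profile(incident$z, refl))
}

#' Standing-wave amplitude envelope near a reflecting surface
#'
#' Monochromatic superposition of an incident wave of local amplitude
#' pi(z) travelling toward the surface at z = zs and its reflection with
#' coefficient Gamma: |p|(z) = pi(z) |1 + Gamma exp(2 i k (z - zs))|.
#'
#' @param incident an [axial_profile()]
#' @param stone a [stone_spec()]
#' @param wavelength_m carrier wavelength in m
#' @return an [axial_profile()] of the envelope over z <= apex_z
#' @export
standing_wave_envelope <- function(incident, stone, wavelength_m) {
  stopifnot(inherits(incident, "axial_profile"))
  k <- 2 * pi / wavelength_m
  zs <- stone$apex_z
  gamma <- (stone$impedance_ratio - 1) / (stone$impedance_ratio + 1)
  sel <- incident$z <= zs
  z <- incident$z[sel]
  env <- incident$p[sel] * Mod(1 + gamma * exp(2i * k * (z - zs)))
  axial_profile(z, env)
}

#' Pressure nodes of a standing-wave envelope
#'
#' Locates the axial pressure minima (nodes) of an envelope, returned
#' sorted by increasing distance from the stone surface. For a rigid
#' reflector (pressure antinode at the surface) the first node sits at
#' lambda/4 from the surface; consecutive nodes are spaced lambda/2.
#'
#' @param envelope an [axial_profile()] (e.g. from
#'   [standing_wave_envelope()])
#' @param surface_z axial position of the reflecting surface (m)
#' @param min_depth minimum relative dip (vs neighbouring maxima) for a
#'   minimum to count as a node; default 0.2 rejects numerical ripple
#' @return numeric vector of node positions (m), nearest-surface first;
#'   empty when the envelope has no interior minima (no reflected wave)
#' @export
standing_wave_nodes <- function(envelope, surface_z, min_depth = 0.2) {
  stopifnot(inherits(envelope, "axial_profile"))
  z <- envelope$z; p <- envelope$p
  n <- length(p)
  if (n < 3) return(numeric(0))
  i <- which(p[2:(n - 1)] < p[1:(n - 2)] & p[2:(n - 1)] <= p[3:n]) + 1L
  if (length(i) == 0) return(numeric(0))
  ref <- max(p)
  i <- i[p[i] < (1 - min_depth) * ref]
  if (length(i) == 0) return(numeric(0))
  # refine each minimum with a parabola on -p
  nodes <- vapply(i, function(j) {
    if (j <= 1L || j >= n) return(z[j])
    argmax_quadratic(z[(j - 1):(j + 1)], -p[(j - 1):(j + 1)])
  }, numeric(1))
  nodes[order(abs(nodes - surface_z))]
}
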