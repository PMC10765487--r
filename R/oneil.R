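#' On-axis pressure of a focused bowl transducer (O'Neil solution)
#'
#' Amplitude of the linear monochromatic on-axis pressure for a concave
#' spherical-cap radiator vibrating with uniform normal velocity `u0`.
#' With zt the axial distance from the bowl apex, the closed form is
#'
#'   |p(zt)| = 2 rho c u0 |sin(k (Re - zt)/2)| / |1 - zt/f|
#'
#' where Re = sqrt(a^2 + (zt - h)^2) is the distance from the rim to the
#' axial point and h the bowl depth. The removable singularity at the
#' curvature centre is handled analytically through the identity
#' Re - zt = 2 h (f - zt) / (Re + zt), which gives
#' p = 2 rho c u0 f |sin(k h (f - zt)/(Re + zt))| / |f - zt| and the
#' finite limit rho c u0 k h at the geometric focus. Attenuation is
#' applied as a single-frequency exponential decay over the mean
#' propagation path (distance from the apex).
#'
#' @param spec a [transducer_spec()]
#' @param medium a [medium_spec()]
#' @param z_grid axial sample positions in m, rim-plane origin; must lie
#'   in (0, 3f\]
#' @return an object of class `axial_profile`: list with `z` (m) and
#'   `p` (Pa, amplitude)
#' @examples
#' tx <- transducer_spec(250e3, 67e-3, 32e-3, u0 = 0.01)
#' prof <- oneil_axial(tx, water(), seq(5e-3, 120e-3, by = 0.1e-3))
#' @export
oneil_axial <- function(spec, medium, z_grid) {
  stopifnot(inherits(spec, "transducer_spec"), inherits(medium, "medium_spec"))
  if (!is.numeric(z_grid) || any(!is.finite(z_grid)))
    stopf("z_grid must be finite numeric")
  if (is.unsorted(z_grid, strictly = TRUE)) stopf("z_grid must be strictly increasing")
  if (any(z_grid <= 0) || any(z_grid > 3 * spec$focus))
    stopf("z_grid must lie within (0, 3f]; z touching the bowl surface is singular")
  g <- bowl_geometry(spec)
  f <- spec$focus; a <- spec$aperture_radius; h <- g$h
  k <- 2 * pi / wavelength(spec, medium)
  rho_c_u0 <- medium$density * medium$sound_speed * spec$u0
  zt <- z_grid + h                          # distance from apex
  Re <- sqrt(a^2 + (zt - h)^2)
  s_arg <- k * h * (f - zt) / (Re + zt)     # = k (Re - zt) / 2, cancellation-free
  denom <- abs(f - zt)
  p <- ifelse(denom < 1e-9 * f,
              rho_c_u0 * k * h * 2 * f / (Re + zt),
              2 * rho_c_u0 * f * abs(sin(s_arg)) / denom)
  alpha <- attenuation_np_m(medium, spec$frequency)
  p <- p * exp(-alpha * zt)
  axial_profile(z_grid, p)
}

#' Construct an axial pressure profile
#' @param z axial grid in m (strictly increasing)
#' @param p pressure amplitude in Pa (non-negative)
#' @return an object of class `axial_profile`
#' @export
axial_profile <- function(z, p) {
  if (length(z) != length(p)) stopf("z and p must have equal length")
  if (is.unsorted(z, strictly = TRUE)) stopf("z must be strictly increasing")
  if (any(p < 0)) stopf("pressure amplitude must be non-negative")
  structure(list(z = z, p = p), class = "axial_profile")
}

#' Physical (acoustic) focus of an axial profile
#'
#' Axial coordinate of the pressure maximum, located by quadratic
#' interpolation around the discrete argmax. For a finite-aperture bowl
#' this lies pre-focally, i.e. short of the geometric focus.
#'
#' @param profile an [axial_profile()]
#' @return gamma_f in m
#' @export
physical_focus <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  argmax_quadratic(profile$z, profile$p)
}

#' Advisory closed-form estimate of the focal shift
#'
#' Evaluates beta * (1 + 2 beta^2 / (1 + 2 beta))^-1 with
#' beta = f * lambda / a. The printed form is dimensionally ambiguous
#' (beta carries units of length when taken literally), so this estimate
#' is advisory only; [physical_focus()] on a computed profile is the
#' authoritative focal position.
#'
#' @param spec a [transducer_spec()]
#' @param medium a [medium_spec()]
#' @return the closed-form value, in m when beta is taken in m
#' @export
focal_shift_estimate <- function(spec, medium) {
  beta <- spec$focus * wavelength(spec, medium) / spec$aperture_radius
  beta / (1 + 2 * beta^2 / (1 + 2 * beta))
}
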