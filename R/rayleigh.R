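#' Axisymmetric gridded pressure-amplitude map
#'
#' Container for |p|(r, z) on a rectangular (r, z) grid. The amplitude
#' matrix is indexed `[i_r, j_z]`.
#'
#' @param r radial axis in m (strictly increasing, >= 0)
#' @param z axial axis in m (strictly increasing)
#' @param amplitude matrix `length(r) x length(z)` of non-negative
#'   pressure amplitudes (Pa)
#' @param normalized logical flag: TRUE once the map has been put in the
#'   dimensionless form of [normalize_field()]
#' @return an object of class `field_map`
#' @export
field_map <- function(r, z, amplitude, normalized = FALSE) {
  if (is.unsorted(r, strictly = TRUE) || is.unsorted(z, strictly = TRUE))
    stopf("axes must be strictly monotone increasing")
  if (any(r < 0)) stopf("radial axis must be non-negative")
  if (!is.matrix(amplitude) ||
      nrow(amplitude) != length(r) || ncol(amplitude) != length(z))
    stopf("amplitude must be a length(r) x length(z) matrix")
  if (any(amplitude < 0)) stopf("amplitude must be non-negative")
  structure(list(r = r, z = z, amplitude = amplitude,
                 normalized = isTRUE(normalized)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map: %d x %d (r x z), r in [%.2f, %.2f] mm, z in [%.2f, %.2f] mm%s\n",
              length(x$r), length(x$z), min(x$r) * 1e3, max(x$r) * 1e3,
              min(x$z) * 1e3, max(x$z) * 1e3,
              if (x$normalized) " [normalized]" else ""))
  invisible(x)
}

#' Quick-look image of a field map
#' @param x a [field_map()]
#' @param ... passed to [graphics::image()]
#' @export
plot.field_map <- function(x, ...) {
  graphics::image(x$r * 1e3, x$z * 1e3, x$amplitude,
                  xlab = "r (mm)", ylab = "z (mm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Off-axis field of a focused bowl by Rayleigh surface integral
#'
#' Numerical evaluation of the Rayleigh integral
#' p(x) = i rho c k u0 / (2 pi) * surface integral of exp(-(alpha + i k) R) / R dS
#' over the spherical cap, with Gauss-Legendre quadrature along the cap
#' polar angle and uniform (trapezoidal, spectrally accurate for the
#' periodic integrand) sampling in azimuth. Returns the amplitude |p| on
#' the requested axisymmetric (r, z) grid. The on-axis column agrees
#' with [oneil_axial()] to quadrature tolerance.
#'
#' @param spec a [transducer_spec()]
#' @param medium a [medium_spec()]
#' @param r radial sample positions in m (>= 0)
#' @param z axial sample positions in m (rim-plane origin, excluding the
#'   bowl surface, i.e. z > 0)
#' @param nodes_per_wavelength Gauss-Legendre nodes per wavelength of cap
#'   arc (default 64)
#' @param n_phi azimuthal samples (default 256)
#' @return a [field_map()] of pressure amplitude in Pa
#' @export
rayleigh_field <- function(spec, medium, r, z,
                           nodes_per_wavelength = 64, n_phi = 256) {
  stopifnot(inherits(spec, "transducer_spec"), inherits(medium, "medium_spec"))
  if (any(z <= 0)) stopf("grid must exclude the bowl surface (z > 0)")
  lam <- wavelength(spec, medium)
  if ((length(r) > 1 && max(diff(r)) > lam / 4 * (1 + 1e-9)) ||
      (length(z) > 1 && max(diff(z)) > lam / 4 * (1 + 1e-9)))
    warning("grid step coarser than lambda/4: side lobes may be aliased",
            call. = FALSE)
  g <- bowl_geometry(spec)
  f <- spec$focus
  k <- 2 * pi / lam
  alpha <- attenuation_np_m(medium, spec$frequency)
  arc <- f * g$psi_max
  n_psi <- max(64L, ceiling(nodes_per_wavelength * arc / lam))
  gl <- pracma::gaussLegendre(n_psi, 0, g$psi_max)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  cphi <- cos(phi)
  # source ring radii/axial positions (curvature centre at z = z_focus)
  sr <- f * sin(gl$x)
  sz <- g$z_focus - f * cos(gl$x)
  pts <- expand.grid(r = r, z = z)   # column-major: r varies fastest
  rv <- pts$r; zv <- pts$z
  acc <- complex(length.out = length(rv))
  km <- complex(real = -alpha, imaginary = -k)
  w_phi <- 2 * pi / n_phi
  for (j in seq_len(n_psi)) {
    A <- rv^2 + sr[j]^2 + (zv - sz[j])^2
    B <- 2 * rv * sr[j]
    R <- sqrt(A - outer(B, cphi))   # recycles A down columns: A[i] - B[i]*cphi[j]
    contrib <- rowSums(exp(km * R) / R) * w_phi
    acc <- acc + gl$w[j] * f^2 * sin(gl$x[j]) * contrib
  }
  pref <- medium$density * medium$sound_speed * k * spec$u0 / (2 * pi)
  amp <- matrix(pref * Mod(acc), nrow = length(r))
  field_map(r, z, amp)
}

#' Focal-ellipsoid geometry of a computed field
#'
#' Locates the physical focus gamma_f (argmax of the on-axis amplitude,
#' quadratic interpolation), then measures the lateral full width at
#' half maximum l1 in the plane z = gamma_f and the axial FWHM l2 along
#' the axis, both on pressure amplitude with linearly interpolated
#' half-maximum crossings. The dimensionless fit coefficients follow as
#' alpha_k = l_k / (lambda (f / 2a)^k).
#'
#' @param field a [field_map()] resolving the focal lobe (>= 8 samples
#'   across l1)
#' @param spec a [transducer_spec()]
#' @param medium a [medium_spec()]
#' @return an object of class `focal_geometry` with fields `gamma_f`,
#'   `l1`, `l2` (m), `alpha1`, `alpha2`, `pmax` (Pa)
#' @export
focal_geometry_fit <- function(field, spec, medium) {
  stopifnot(inherits(field, "field_map"))
  if (field$normalized) stopf("fit on the dimensional field, not a normalized one")
  axial <- field$amplitude[1L, ]           # column nearest the axis
  if (field$r[1L] > 1e-4)
    warning("first radial sample is far from the axis; gamma_f may be biased",
            call. = FALSE)
  gamma_f <- argmax_quadratic(field$z, axial)
  pmax_ax <- max(axial)
  # axial FWHM along r ~ 0
  z_lo <- half_crossing(field$z, axial, pmax_ax / 2, direction = -1)
  z_hi <- half_crossing(field$z, axial, pmax_ax / 2, direction = +1)
  l2 <- z_hi - z_lo
  # lateral FWHM in the focal plane (profile over r >= 0; full width = 2x)
  lat <- field$amplitude[, which.min(abs(field$z - gamma_f))]
  r_half <- half_crossing(field$r, lat, max(lat) / 2, from = which.max(lat),
                          direction = +1)
  l1 <- 2 * (r_half - field$r[which.max(lat)])
  if (sum(field$r < l1 / 2) < 4L)
    warning("fewer than 8 samples across l1; FWHM poorly resolved",
            call. = FALSE)
  lam <- wavelength(spec, medium)
  fa <- spec$focus / (2 * spec$aperture_radius)
  structure(list(gamma_f = gamma_f, l1 = l1, l2 = l2,
                 alpha1 = l1 / (lam * fa), alpha2 = l2 / (lam * fa^2),
                 pmax = max(field$amplitude)),
            class = "focal_geometry")
}

#' Construct a focal geometry directly
#'
#' Builds the object returned by [focal_geometry_fit()] from known
#' values — e.g. to normalize a solver map with a geometry measured on
#' the analytic field.
#'
#' @param gamma_f physical focus in m
#' @param l1,l2 lateral/axial FWHM in m (l2 > l1)
#' @param pmax peak amplitude in Pa
#' @param alpha1,alpha2 optional fit coefficients
#' @return an object of class `focal_geometry`
#' @export
focal_geometry <- function(gamma_f, l1, l2, pmax = 1,
                           alpha1 = NA_real_, alpha2 = NA_real_) {
  check_num(gamma_f, "gamma_f", positive = TRUE)
  check_num(l1, "l1", positive = TRUE)
  check_num(l2, "l2", positive = TRUE)
  if (l2 <= l1) stopf("the focal ellipsoid is elongated: l2 > l1 required")
  structure(list(gamma_f = gamma_f, l1 = l1, l2 = l2,
                 alpha1 = alpha1, alpha2 = alpha2, pmax = pmax),
            class = "focal_geometry")
}

#' @export
print.focal_geometry <- function(x, ...) {
  cat(sprintf(
    "focal geometry: gamma_f = %.2f mm, l1 = %.2f mm, l2 = %.2f mm, alpha1 = %.3f, alpha2 = %.3f\n",
    x$gamma_f * 1e3, x$l1 * 1e3, x$l2 * 1e3, x$alpha1, x$alpha2))
  invisible(x)
}

#' Dimensionless field normalization
#'
#' Puts a field map in the dimensionless variables
#' z* = z / gamma_f, r* = r / l1, p* = p / max(p), so that max p* = 1
#' and z* = 1 at the physical focus. Re-normalizing an already
#' normalized map is rejected.
#'
#' @param field a [field_map()]
#' @param geom a [focal_geometry()] computed from the same (or a
#'   grid-compatible) field
#' @return an object of class `normalized_field` (also a `field_map`)
#'   with axes `r_star`, `z_star` and matrix `p_star`
#' @export
normalize_field <- function(field, geom) {
  stopifnot(inherits(field, "field_map"), inherits(geom, "focal_geometry"))
  if (field$normalized) stopf("field is already normalized")
  if (geom$gamma_f <= 0 || geom$l1 <= 0) stopf("gamma_f and l1 must be positive")
  pmax <- max(field$amplitude)
  out <- structure(list(r_star = field$r / geom$l1,
                        z_star = field$z / geom$gamma_f,
                        p_star = field$amplitude / pmax,
                        r = field$r, z = field$z,
                        amplitude = field$amplitude / pmax,
                        normalized = TRUE),
                   class = c("normalized_field", "field_map"))
  out
}

#' Export an axial profile as CSV (columns z_m, p_Pa, p_star)
#' @param profile an [axial_profile()]
#' @param path output file path
#' @export
write_axial_csv <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  utils::write.csv(data.frame(z_m = profile$z, p_Pa = profile$p,
                              p_star = profile$p / max(profile$p)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a field map to plain text (JSON header + CSV matrix)
#' @param field a [field_map()]
#' @param path output path (two files: `path` with the amplitude matrix
#'   in CSV, `path`.json with axes and units)
#' @export
write_field_map <- function(field, path) {
  stopifnot(inherits(field, "field_map"))
  utils::write.table(field$amplitude, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(r_m = field$r, z_m = field$z,
                            units = if (field$normalized) "dimensionless" else "Pa",
                            normalized = field$normalized),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a field map written by [write_field_map()]
#' @param path path given to [write_field_map()]
#' @return a [field_map()]
#' @export
read_field_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  amp <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(amp) <- NULL
  field_map(meta$r_m, meta$z_m, amp, normalized = isTRUE(meta$normalized))
}
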