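#' Transducer specification for a spherical-bowl source
#'
#' Describes a single-element concave (bowl) transducer by its carrier
#' frequency, geometric focus (radius of curvature) `f`, aperture radius
#' `a` and uniform normal surface velocity `u0`. The axial coordinate
#' convention used throughout the package is: z >= 0 along the beam axis
#' with the origin at the centre of the bowl rim plane, so the bowl
#' itself occupies z in [-h, 0] with h = f - sqrt(f^2 - a^2), and the
#' geometric (curvature) focus sits at z = sqrt(f^2 - a^2).
#'
#' @param frequency carrier frequency in Hz
#' @param focus geometric focus f in m (radius of curvature)
#' @param aperture_radius aperture radius a in m; must satisfy 0 < a < f
#' @param u0 normal surface velocity amplitude in m/s
#' @param drive optional [burst_spec()] describing the burst drive
#' @return an object of class `transducer_spec`
#' @examples
#' tx <- transducer_spec(250e3, 67e-3, 32e-3, u0 = 0.01)
#' @export
transducer_spec <- function(frequency, focus, aperture_radius, u0 = 1e-2,
                            drive = NULL) {
  check_num(frequency, "frequency", positive = TRUE)
  check_num(focus, "focus", positive = TRUE)
  check_num(aperture_radius, "aperture_radius", positive = TRUE)
  check_num(u0, "u0", positive = TRUE)
  if (aperture_radius >= focus)
    stopf("aperture_radius must be smaller than the geometric focus")
  if (!is.null(drive) && !inherits(drive, "burst_spec"))
    stopf("'drive' must be a burst_spec")
  structure(list(frequency = frequency, focus = focus,
                 aperture_radius = aperture_radius, u0 = u0, drive = drive),
            class = "transducer_spec")
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf("Bowl transducer: %.0f kHz, f = %.1f mm, a = %.1f mm, u0 = %.2f mm/s\n",
              x$frequency / 1e3, x$focus * 1e3, x$aperture_radius * 1e3,
              x$u0 * 1e3))
  invisible(x)
}

#' Propagation-medium specification
#'
#' Density, sound speed and a frequency power-law attenuation
#' `alpha0 * f^y` with `alpha0` in dB/(MHz)^y/cm, the convention of
#' ultrasound tissue/water attenuation tables.
#'
#' @param density mass density in kg/m^3
#' @param sound_speed speed of sound in m/s
#' @param alpha0 attenuation coefficient in dB/(MHz)^y/cm (default: water,
#'   0.0022)
#' @param y attenuation power-law exponent, in \[0, 3\] (default 2)
#' @return an object of class `medium_spec`
#' @export
medium_spec <- function(density = 1000, sound_speed = 1500,
                        alpha0 = 0.0022, y = 2) {
  check_num(density, "density", positive = TRUE)
  check_num(sound_speed, "sound_speed", positive = TRUE)
  check_num(alpha0, "alpha0", nonneg = TRUE)
  check_num(y, "y")
  if (y < 0 || y > 3) stopf("attenuation power 'y' must lie in [0, 3]")
  structure(list(density = density, sound_speed = sound_speed,
                 alpha0 = alpha0, y = y), class = "medium_spec")
}

#' Water at laboratory conditions
#' @return a `medium_spec` for water (1000 kg/m^3, 1500 m/s)
#' @export
water <- function() medium_spec()

#' Attenuation coefficient in Np/m at a given frequency
#'
#' Converts the power-law coefficient `alpha0` (dB/(MHz)^y/cm) to
#' nepers per metre at frequency `f`.
#'
#' @param medium a [medium_spec()]
#' @param frequency frequency in Hz
#' @return attenuation in Np/m
#' @export
attenuation_np_m <- function(medium, frequency) {
  db_per_cm <- medium$alpha0 * (frequency / 1e6)^medium$y
  db_per_cm * 100 / (20 * log10(exp(1)))   # dB/cm -> Np/m
}

#' Burst drive specification
#'
#' A tone burst: `n_cycles` of a sinusoid at `carrier_frequency`,
#' repeated every `repetition_period` seconds.
#'
#' @param n_cycles number of carrier cycles per burst
#' @param repetition_period burst repetition period in s
#' @param carrier_frequency carrier frequency in Hz
#' @return an object of class `burst_spec`
#' @examples
#' b <- burst_spec(500, 20e-3, 250e3)   # a 10% duty-cycle burst
#' @export
burst_spec <- function(n_cycles, repetition_period, carrier_frequency) {
  check_num(n_cycles, "n_cycles", positive = TRUE)
  check_num(repetition_period, "repetition_period", positive = TRUE)
  check_num(carrier_frequency, "carrier_frequency", positive = TRUE)
  active <- n_cycles / carrier_frequency
  if (active > repetition_period * (1 + 1e-12))
    stopf("invalid burst: active duration %.3g s exceeds repetition period %.3g s",
          active, repetition_period)
  structure(list(n_cycles = n_cycles, repetition_period = repetition_period,
                 carrier_frequency = carrier_frequency,
                 acoustic_period = 1 / carrier_frequency),
            class = "burst_spec")
}

#' Model-stone specification
#'
#' A hemispherical stone (spherical proximal face toward the source, flat
#' face distal) or a flat-faced stone, placed on the beam axis. The
#' acoustic contrast is carried by the stone/water impedance ratio
#' I2/I1 = (density ratio) x (sound-speed ratio).
#'
#' @param shape `"hemisphere"` or `"flat"`
#' @param radius hemisphere radius R in m (required for `"hemisphere"`)
#' @param side_length flat-face side length in m (required for `"flat"`)
#' @param apex_z axial position (m) of the proximal surface (the
#'   hemisphere south pole, or the flat face)
#' @param impedance_ratio stone/water acoustic impedance ratio I2/I1
#' @param speed_ratio stone/water sound-speed ratio; the density ratio is
#'   derived as `impedance_ratio / speed_ratio`
#' @return an object of class `stone_spec`
#' @examples
#' st <- stone_spec("hemisphere", radius = 10e-3, apex_z = 51e-3)
#' @export
stone_spec <- function(shape = c("hemisphere", "flat"), radius = NULL,
                       side_length = NULL, apex_z,
                       impedance_ratio = 6.5, speed_ratio = 2.77) {
  shape <- match.arg(shape)
  if (shape == "hemisphere") check_num(radius, "radius", positive = TRUE)
  else check_num(side_length, "side_length", positive = TRUE)
  check_num(apex_z, "apex_z")
  check_num(impedance_ratio, "impedance_ratio", positive = TRUE)
  check_num(speed_ratio, "speed_ratio", positive = TRUE)
  density_ratio <- impedance_ratio / speed_ratio
  structure(list(shape = shape, radius = radius, side_length = side_length,
                 apex_z = apex_z, impedance_ratio = impedance_ratio,
                 speed_ratio = speed_ratio, density_ratio = density_ratio),
            class = "stone_spec")
}

#' @export
print.stone_spec <- function(x, ...) {
  dim_txt <- if (x$shape == "hemisphere")
    sprintf("R = %.1f mm", x$radius * 1e3)
  else sprintf("side = %.1f mm", x$side_length * 1e3)
  cat(sprintf("%s stone, %s, proximal face at z = %.1f mm, I2/I1 = %.2f\n",
              x$shape, dim_txt, x$apex_z * 1e3, x$impedance_ratio))
  invisible(x)
}

#' Wavelength of the carrier in the medium
#' @param spec a [transducer_spec()]
#' @param medium a [medium_spec()]
#' @return wavelength in m
#' @export
wavelength <- function(spec, medium) medium$sound_speed / spec$frequency

#' Axial position of the geometric (curvature) focus
#'
#' With the origin at the rim-plane centre the curvature centre sits at
#' z = sqrt(f^2 - a^2); the bowl apex at z = -(f - sqrt(f^2 - a^2)).
#' @param spec a [transducer_spec()]
#' @return list with `z_focus`, `apex_z` (both m) and bowl depth `h`
#' @export
bowl_geometry <- function(spec) {
  f <- spec$focus; a <- spec$aperture_radius
  zg <- sqrt(f^2 - a^2)
  list(z_focus = zg, apex_z = zg - f, h = f - zg,
       psi_max = asin(a / f))
}

#' Read transducer/medium/burst specifications from a key/value file
#'
#' The file is YAML with top-level blocks `transducer`, `medium`, `burst`
#' and optionally `stone`; keys mirror the constructor arguments, in SI
#' units.
#'
#' @param path path to the YAML configuration file
#' @return a named list of spec objects
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$burst))
    out$burst <- do.call(burst_spec, cfg$burst)
  if (!is.null(cfg$medium))
    out$medium <- do.call(medium_spec, cfg$medium)
  if (!is.null(cfg$transducer)) {
    args <- cfg$transducer
    args$drive <- out$burst
    out$transducer <- do.call(transducer_spec, args)
  }
  if (!is.null(cfg$stone))
    out$stone <- do.call(stone_spec, cfg$stone)
  out
}
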