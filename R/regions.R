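#' Cavitation-threshold specification
#'
#' The cavitation threshold as a fraction pc* of the peak dimensionless
#' pressure. It is experiment-specific and therefore a required,
#' explicit input of the region-extraction stage; 0.46 is the value
#' inferred from stone-free cloud-trajectory envelopes at 250 kHz.
#'
#' @param pc_star threshold as a fraction of max p*, in (0, 1)
#' @return an object of class `cavitation_threshold`
#' @export
cavitation_threshold <- function(pc_star) {
  check_num(pc_star, "pc_star", positive = TRUE)
  if (pc_star >= 1) stopf("pc_star must be < 1")
  structure(list(pc_star = pc_star), class = "cavitation_threshold")
}

#' Supra-threshold mask of a normalized field
#'
#' Binary mask of the region where p* strictly exceeds the cavitation
#' threshold pc*.
#'
#' @param field a `normalized_field` from [normalize_field()]
#' @param thr a [cavitation_threshold()] (or a bare number in (0,1))
#' @return logical matrix on the field grid, with the grid attached as
#'   attributes `r` and `z`
#' @export
threshold_mask <- function(field, thr) {
  if (!inherits(field, "normalized_field") || !isTRUE(field$normalized))
    stopf("threshold_mask requires a normalized field (max p* = 1)")
  if (is.numeric(thr)) thr <- cavitation_threshold(thr)
  mask <- field$p_star > thr$pc_star
  attr(mask, "r") <- field$r
  attr(mask, "z") <- field$z
  mask
}

stone_grid_mask <- function(stone, r, z) {
  if (is.null(stone)) return(matrix(FALSE, length(r), length(z)))
  build_medium_maps(stone, medium_spec(), list(r = r, z = z))$stone_mask
}

#' Label connected supra-threshold pressure regions
#'
#' Connected-component labelling (orthogonal 2-connectivity in the
#' (r, z) plane) of a supra-threshold mask. When a stone is given, stone
#' interior pixels are removed from the mask first; the component
#' touching the stone surface within one cell is labelled `"Pi1"`, the
#' detached components on the source side are labelled `"Pi2"`,
#' `"Pi2_2"`, ... in order of increasing distance from the stone, and
#' any remaining components are `"other"`. Without a stone all
#' components are `"other"`.
#'
#' @param mask logical matrix from [threshold_mask()] (grid attached) or
#'   a bare logical matrix plus `r`, `z` arguments
#' @param stone optional [stone_spec()] on the same grid
#' @param r,z grid vectors, overriding the mask attributes
#' @return a list of `pressure_region` objects; each has `label`,
#'   `pixels` (index matrix), `r`, `z` (pixel coordinates, m),
#'   `attached_to_stone`, `spanwise_diameter` (m), `distance_to_stone`
#'   (m, NA without a stone) and `n_pixels`
#' @export
label_regions <- function(mask, stone = NULL, r = attr(mask, "r"),
                          z = attr(mask, "z")) {
  if (is.null(r) || is.null(z)) stopf("mask has no grid; supply r and z")
  m <- mask
  attributes(m) <- list(dim = dim(mask))
  smask <- stone_grid_mask(stone, r, z)
  m[smask] <- FALSE
  lab <- EBImage::bwlabel(m * 1)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  # stone-adjacency: cells within one cell of the stone mask
  near_stone <- matrix(FALSE, nrow(m), ncol(m))
  if (any(smask)) {
    near_stone <- EBImage::dilate(smask * 1,
                                  EBImage::makeBrush(3, "box")) > 0 & !smask
  }
  surf_z <- if (!is.null(stone)) stone$apex_z else NA_real_
  regions <- lapply(seq_len(nlab), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    rr <- r[idx[, 1]]; zz <- z[idx[, 2]]
    attached <- any(near_stone[idx])
    dist <- if (!is.null(stone)) {
      if (attached) 0 else min(sqrt(rr^2 + (zz - surf_z)^2))
    } else NA_real_
    structure(list(label = "other", pixels = idx, r = rr, z = zz,
                   attached_to_stone = attached,
                   spanwise_diameter = 2 * max(rr),
                   distance_to_stone = dist, n_pixels = nrow(idx)),
              class = "pressure_region")
  })
  if (!is.null(stone)) {
    att <- which(vapply(regions, `[[`, TRUE, "attached_to_stone"))
    if (length(att) > 0) {
      # a single Pi1: the largest attached component
      main <- att[which.max(vapply(regions[att], `[[`, 0L, "n_pixels"))]
      regions[[main]]$label <- "Pi1"
    }
    det <- setdiff(seq_along(regions), if (length(att)) att else integer(0))
    # detached components on the source side (below the proximal surface)
    below <- det[vapply(regions[det], function(rg) mean(rg$z) < surf_z, TRUE)]
    below <- below[order(vapply(regions[below], `[[`, 0, "distance_to_stone"))]
    for (i in seq_along(below))
      regions[[below[i]]]$label <- if (i == 1) "Pi2" else sprintf("Pi2_%d", i)
  }
  ord <- order(vapply(regions, function(rg)
    if (is.na(rg$distance_to_stone)) Inf else rg$distance_to_stone, 0))
  regions[ord]
}

#' @export
print.pressure_region <- function(x, ...) {
  cat(sprintf("%s: %d px, spanwise diameter %.2f mm%s\n", x$label, x$n_pixels,
              x$spanwise_diameter * 1e3,
              if (x$attached_to_stone) " (attached to stone)" else ""))
  invisible(x)
}

#' Spherical-cap measure from a polar edge angle
#'
#' For a hemisphere of radius R, a polar cap reaching angle theta from
#' the (downward, source-facing) vertical axis has area
#' A = 2 pi R^2 (1 - cos theta); normalized by the exposed proximal
#' area A0 = pi R^2 / 2 this gives the damage coefficient
#' A* = 4 (1 - cos theta).
#'
#' @param theta cap edge polar angle in rad, in \[0, pi/2\]
#' @param radius hemisphere radius R in m
#' @param source_kind one of `"Pi1-projection"`, `"bubble-layer"`,
#'   `"fragments"`
#' @return an object of class `cap_measure` with `theta`, `A` (m^2),
#'   `A0` (m^2), `A_star`
#' @export
cap_measure <- function(theta, radius, source_kind = "Pi1-projection") {
  check_num(theta, "theta")
  check_num(radius, "radius", positive = TRUE)
  structure(list(theta = theta, radius = radius,
                 A = 2 * pi * radius^2 * (1 - cos(theta)),
                 A0 = pi * radius^2 / 2,
                 A_star = damage_coefficient(theta),
                 source_kind = source_kind),
            class = "cap_measure")
}

#' @export
print.cap_measure <- function(x, ...) {
  cat(sprintf("cap (%s): theta = %.1f deg, A = %.2f mm^2, A* = %.3f\n",
              x$source_kind, x$theta * 180 / pi, x$A * 1e6, x$A_star))
  invisible(x)
}

#' Spherical-cap damage coefficient A* = 4 (1 - cos theta)
#'
#' @param theta polar cap edge angle in rad, in \[0, pi/2\]
#' @return A*, dimensionless, in \[0, 4\]
#' @examples
#' damage_coefficient(pi / 3)   # 2
#' @export
damage_coefficient <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < -1e-12) || any(theta > pi / 2 + 1e-12))
    stopf("theta must lie in [0, pi/2]")
  4 * (1 - cos(pmin(pmax(theta, 0), pi / 2)))
}

#' Cap angle of a pressure region projected on the stone surface
#'
#' Projects every region pixel along the local surface normal onto the
#' hemisphere (for a sphere, central projection toward the centre):
#' theta(r, z) = atan2(r, zc - z) with zc the sphere centre. The cap
#' edge theta_p is the largest projected polar angle over the proximal
#' face, capped at pi/2.
#'
#' @param region a `pressure_region` (attached to or facing the stone)
#' @param stone a hemispherical [stone_spec()]
#' @return a [cap_measure()] with `source_kind = "Pi1-projection"`
#' @export
cap_angle_of_region <- function(region, stone) {
  stopifnot(inherits(region, "pressure_region"), inherits(stone, "stone_spec"))
  if (stone$shape != "hemisphere")
    stopf("cap projection is defined for hemispherical stones")
  zc <- stone$apex_z + stone$radius
  sel <- region$z <= zc            # pixels facing the proximal hemisphere
  if (!any(sel)) stopf("projection is empty: no region pixel faces the stone")
  theta <- atan2(region$r[sel], zc - region$z[sel])
  cap_measure(min(max(theta), pi / 2), stone$radius, "Pi1-projection")
}

#' Optimum source-to-stone distance
#'
#' Scans candidate proximal-surface positions z in
#' \[gamma_f, gamma_f + l2/2\]; at each, the reflected surface pressure
#' is pr(z) = 2 pi(z) I2/(I1+I2). The optimum z+ is the largest scanned
#' z with pr >= pc (placing the surface as far as cavitation at the
#' surface allows maximizes the spanwise extent of the attached
#' supra-threshold region). When one of the closed-form cases applies it
#' takes precedence over the scan: `"focus-plus-half-ell2"` when
#' pi(gamma_f + l2/2) >= pc (z+ = gamma_f + l2/2), `"at-focus"` when
#' pi(gamma_f) = pc within 1% relative tolerance (z+ = gamma_f, the
#' marginal-cavitation placement); otherwise the `"intermediate"` regime
#' returns the scanned crossing.
#'
#' @param incident an [axial_profile()] spanning at least
#'   \[gamma_f - l2, gamma_f + l2\]
#' @param geom a [focal_geometry()]
#' @param stone a [stone_spec()] (for the impedance ratio)
#' @param pc cavitation threshold pressure in Pa
#' @param n_scan number of scan points (default 512)
#' @return an object of class `optimum_distance` with `z_plus` (m) and
#'   `regime`
#' @export
optimal_distance <- function(incident, geom, stone, pc, n_scan = 512) {
  stopifnot(inherits(incident, "axial_profile"),
            inherits(geom, "focal_geometry"), inherits(stone, "stone_spec"))
  check_num(pc, "pc", positive = TRUE)
  z_lo <- geom$gamma_f
  z_hi <- geom$gamma_f + geom$l2 / 2
  if (min(incident$z) > z_lo || max(incident$z) < z_hi)
    stopf("incident profile must span [gamma_f, gamma_f + l2/2]")
  refl_factor <- 2 * stone$impedance_ratio / (1 + stone$impedance_ratio)
  zs <- seq(z_lo, z_hi, length.out = n_scan)
  pr <- refl_factor * linear_interp(incident$z, incident$p, zs)
  ok <- pr >= pc
  if (!any(ok))
    stopf("no cavitation: reflected pressure below pc over the whole scan")
  z_plus <- max(zs[ok])
  pi_lo <- linear_interp(incident$z, incident$p, z_lo)
  pi_hi <- linear_interp(incident$z, incident$p, z_hi)
  regime <- if (pi_hi >= pc) "focus-plus-half-ell2"
  else if (abs(pi_lo - pc) <= 0.01 * pc) "at-focus"
  else "intermediate"
  if (regime == "focus-plus-half-ell2") z_plus <- z_hi
  if (regime == "at-focus") z_plus <- z_lo
  structure(list(z_plus = z_plus, regime = regime,
                 gamma_f = geom$gamma_f, l2 = geom$l2),
            class = "optimum_distance")
}

#' @export
print.optimum_distance <- function(x, ...) {
  cat(sprintf("optimum source-to-stone distance z+ = %.2f mm (%s)\n",
              x$z_plus * 1e3, x$regime))
  invisible(x)
}

#' JSON report of labelled regions
#' @param regions list from [label_regions()]
#' @param stone optional [stone_spec()]; when hemispherical, cap metrics
#'   are included for the attached region
#' @param path output JSON path
#' @export
write_region_report <- function(regions, stone = NULL, path) {
  rows <- lapply(regions, function(rg) {
    row <- list(label = rg$label, n_pixels = rg$n_pixels,
                spanwise_diameter_m = rg$spanwise_diameter,
                attached = rg$attached_to_stone)
    if (rg$attached_to_stone && !is.null(stone) && stone$shape == "hemisphere") {
      cm <- cap_angle_of_region(rg, stone)
      row$theta_rad <- cm$theta; row$A_m2 <- cm$A; row$A_star <- cm$A_star
    }
    row
  })
  jsonlite::write_json(rows, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
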