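#' Simulation configuration for the time-domain solver
#'
#' @param points_per_wavelength grid points per water wavelength at the
#'   carrier (>= 6; default 8, i.e. 0.75 mm at 250 kHz)
#' @param cfl CFL number for the time step, dt = cfl * dx / c_max
#'   (<= 0.3)
#' @param r_max radial domain extent in m (default 80 mm)
#' @param z_max axial domain extent in m (default 120 mm)
#' @param sponge_cells absorbing-layer width in cells (default 16)
#' @param n_cycles carrier cycles to drive (default 40)
#' @param source_z axial position of the bowl apex in m (default 15 mm;
#'   must leave the apex clear of the lower absorbing layer)
#' @param source `"bowl"` for the focused cap source or `"plane"` for a
#'   full-width planar source at `source_z` (1-D plane-wave runs)
#' @param walls keep rigid tank walls instead of absorbing layers
#' @param check_convergence error if the periodic steady state is not
#'   reached (relative L2 change of the per-cycle amplitude map >= 2%)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(points_per_wavelength = 8, cfl = 0.3,
                       r_max = 80e-3, z_max = 120e-3, sponge_cells = 16,
                       n_cycles = 40, source_z = 15e-3,
                       source = c("bowl", "plane"), walls = FALSE,
                       check_convergence = TRUE) {
  if (points_per_wavelength < 6) stopf("points_per_wavelength must be >= 6")
  if (cfl > 0.3 || cfl <= 0) stopf("CFL must be in (0, 0.3]")
  structure(list(points_per_wavelength = points_per_wavelength, cfl = cfl,
                 r_max = r_max, z_max = z_max, sponge_cells = sponge_cells,
                 n_cycles = n_cycles, source_z = source_z,
                 source = match.arg(source), walls = walls,
                 check_convergence = isTRUE(check_convergence)),
            class = "sim_config")
}

#' Heterogeneous density / sound-speed / attenuation maps
#'
#' Builds per-cell material maps on a given (r, z) cell-centre grid:
#' water values outside the stone mask, stone values (water values times
#' the density and speed ratios) inside. The hemisphere mask is
#' \{(r, z): r^2 + (z - (apex_z + R))^2 <= R^2, z <= apex_z + R\} with the
#' curved proximal face toward the source (low z); a flat stone is a
#' half-thickness slab of radius side_length/2.
#'
#' @param stone a [stone_spec()] or NULL for a homogeneous medium
#' @param medium a [medium_spec()]
#' @param grid list with numeric vectors `r` and `z` (cell centres, m)
#' @return list of matrices `rho`, `c`, `alpha0` (`length(r)` x
#'   `length(z)`) plus the logical `stone_mask`
#' @export
build_medium_maps <- function(stone, medium, grid) {
  nr <- length(grid$r); nz <- length(grid$z)
  rho <- matrix(medium$density, nr, nz)
  cc <- matrix(medium$sound_speed, nr, nz)
  a0 <- matrix(medium$alpha0, nr, nz)
  mask <- matrix(FALSE, nr, nz)
  if (!is.null(stone)) {
    stopifnot(inherits(stone, "stone_spec"))
    if (stone$shape == "hemisphere") {
      zc <- stone$apex_z + stone$radius
      if (stone$apex_z < min(grid$z) || zc + 0 > max(grid$z))
        stopf("stone does not fit inside the domain")
      mask <- outer(grid$r, grid$z, function(r, z)
        r^2 + (z - zc)^2 <= stone$radius^2 & z <= zc)
    } else {
      half <- stone$side_length / 2
      if (stone$apex_z < min(grid$z) || stone$apex_z + half > max(grid$z))
        stopf("stone does not fit inside the domain")
      mask <- outer(grid$r, grid$z, function(r, z)
        r <= half & z >= stone$apex_z & z <= stone$apex_z + half)
    }
    rho[mask] <- medium$density * stone$density_ratio
    cc[mask] <- medium$sound_speed * stone$speed_ratio
  }
  list(rho = rho, c = cc, alpha0 = a0, stone_mask = mask)
}

# cells painted by the bowl arc (or plane) with sub-cell hat weights
source_cells <- function(spec, sim, grid) {
  dx <- grid$r[2] - grid$r[1]
  if (sim$source == "plane") {
    j <- which.min(abs(grid$z - sim$source_z))
    w <- matrix(0, length(grid$r), length(grid$z)); w[, j] <- 1
    return(w)
  }
  g <- bowl_geometry(spec)
  centre_z <- sim$source_z + spec$focus          # curvature centre
  rim_z <- sim$source_z + g$h
  d <- outer(grid$r, grid$z, function(r, z)
    sqrt(r^2 + (z - centre_z)^2))
  w <- pmax(0, 1 - abs(d - spec$focus) / dx)
  on_cap <- outer(grid$r, grid$z, function(r, z)
    z <= rim_z + dx / 2 & r <= spec$aperture_radius)
  w * on_cap
}

#' Time-domain axisymmetric linear acoustic simulation
#'
#' First-order velocity-pressure staggered-grid finite-difference solver
#' in cylindrical (r, z) coordinates with axisymmetry, heterogeneous
#' density/sound-speed maps (stone impedance jump), power-law absorption
#' applied at the carrier frequency, absorbing boundary layers (unless
#' `walls`), and a sinusoidal pressure source painted onto the bowl cap.
#' The run is stepped to the periodic steady state; the returned map is
#' the per-pixel half peak-to-peak amplitude over the last two driven
#' cycles.
#'
#' @param spec a [transducer_spec()]
#' @param medium a [medium_spec()]
#' @param stone optional [stone_spec()]
#' @param sim a [sim_config()]
#' @param source_amplitude drive pressure amplitude in Pa (linear solver:
#'   the output scales proportionally)
#' @return a `steady_amplitude_map`: a [field_map()] with extra fields
#'   `stone_mask`, `cycle_change` (relative L2 change of the last two
#'   per-cycle amplitude maps) and `grid_step`
#' @export
simulate_linear_field <- function(spec, medium, stone = NULL, sim = sim_config(),
                                  source_amplitude = 1e5) {
  stopifnot(inherits(spec, "transducer_spec"), inherits(medium, "medium_spec"),
            inherits(sim, "sim_config"))
  lam <- wavelength(spec, medium)
  dx <- lam / sim$points_per_wavelength
  r <- seq(dx / 2, sim$r_max, by = dx)
  z <- seq(dx / 2, sim$z_max, by = dx)
  nr <- length(r); nz <- length(z)
  maps <- build_medium_maps(stone, medium, list(r = r, z = z))
  src_w <- source_cells(spec, sim, list(r = r, z = z))
  if (sum(src_w) == 0) stopf("source does not intersect the grid")
  if (any(maps$stone_mask & src_w > 0))
    stopf("stone overlaps the source arc")
  c_max <- max(maps$c)
  period <- 1 / spec$frequency
  spc <- ceiling(period / (sim$cfl * dx / c_max))   # steps per cycle
  dt <- period / spc
  n_steps <- spc * sim$n_cycles
  kappa <- maps$rho * maps$c^2                       # bulk modulus
  # absorption at the carrier: damping factor exp(-2 c alpha dt) on p
  alpha_np <- maps$alpha0 * (spec$frequency / 1e6)^medium$y *
    100 / (20 * log10(exp(1)))
  p_damp <- exp(-2 * maps$c * alpha_np * dt)
  # sponge taper (multiplicative per step) on the domain edges
  sponge <- matrix(1, nr, nz)
  if (!sim$walls && sim$sponge_cells > 0) {
    w <- sim$sponge_cells
    prof <- function(depth) exp(-3 * (depth / w)^3)  # ~e^-3 at full depth/step
    for (i in seq_len(w)) {
      if (sim$source != "plane")  # keep the duct mode planar in plane runs
        sponge[nr - w + i, ] <- pmin(sponge[nr - w + i, ], prof(i))
      sponge[, nz - w + i] <- pmin(sponge[, nz - w + i], prof(i))
      sponge[, w - i + 1] <- pmin(sponge[, w - i + 1], prof(i))
    }
  }
  rho_rf <- (maps$rho[-1, ] + maps$rho[-nr, ]) / 2   # at radial faces 2..nr
  rho_zf <- (maps$rho[, -1] + maps$rho[, -nz]) / 2   # at axial faces 2..nz
  r_face <- (seq_len(nr + 1) - 1) * dx               # face radii, r_face[1]=0
  p <- matrix(0, nr, nz)
  ur <- matrix(0, nr + 1, nz)                        # ur[1,]=axis, =0
  uz <- matrix(0, nr, nz + 1)
  omega <- 2 * pi * spec$frequency
  ramp_steps <- 3 * spc
  rec_from <- n_steps - 2 * spc
  mins <- list(matrix(Inf, nr, nz), matrix(Inf, nr, nz))
  maxs <- list(matrix(-Inf, nr, nz), matrix(-Inf, nr, nz))
  src_idx <- which(src_w > 0)
  src_val <- src_w[src_idx] * source_amplitude
  inv_rho_rf <- dt / (rho_rf * dx)
  inv_rho_zf <- dt / (rho_zf * dx)
  inv_r <- matrix(1 / (r * dx), nr, nz)
  # 4th-order staggered differences (c1, c2): keeps numerical dispersion
  # small at the default 8 points per wavelength
  c1 <- 9 / 8; c2 <- 1 / 24
  for (s in seq_len(n_steps)) {
    t <- s * dt
    ramp <- if (s < ramp_steps) 0.5 * (1 - cos(pi * s / ramp_steps)) else 1
    # radial pressure gradient at faces 2..nr; ghost rows mirror the axis
    # (p even in r) and copy the outer edge (inside the sponge)
    P <- rbind(p[1, ], p, p[nr, ])                   # rows 0..nr+1
    i <- 2:nr
    dpdr <- c1 * (P[i + 1, ] - P[i, ]) - c2 * (P[i + 2, ] - P[i - 1, ])
    ur[i, ] <- ur[i, ] - inv_rho_rf * dpdr
    Q <- cbind(p[, 1], p, p[, nz])                   # cols 0..nz+1
    j <- 2:nz
    dpdz <- c1 * (Q[, j + 1] - Q[, j]) - c2 * (Q[, j + 2] - Q[, j - 1])
    uz[, j] <- uz[, j] - inv_rho_zf * dpdz
    # divergence: (1/r) d(r ur)/dr + d(uz)/dz at cell centres
    phi <- ur * r_face                               # faces 1..nr+1; r*ur odd^2 -> even
    PH <- rbind(phi[2, ], phi, phi[nr + 1, ])        # ghost: phi(-dx)=phi(+dx)
    i <- 1:nr
    dphidr <- c1 * (PH[i + 2, ] - PH[i + 1, ]) - c2 * (PH[i + 3, ] - PH[i, ])
    UZ <- cbind(uz[, 1], uz, uz[, nz + 1])           # cols 0..nz+2
    j <- 1:nz
    duzdz <- c1 * (UZ[, j + 2] - UZ[, j + 1]) - c2 * (UZ[, j + 3] - UZ[, j])
    div <- dphidr * inv_r + duzdz / dx
    p <- (p - dt * kappa * div) * p_damp
    p[src_idx] <- p[src_idx] + src_val * sin(omega * t) * ramp * dt / period
    if (!sim$walls) {
      # plane-wave runs damp only the z edges so the duct mode stays planar
      p <- p * sponge
      ur[2:(nr + 1), ] <- ur[2:(nr + 1), ] * sponge
      uz[, 2:(nz + 1)] <- uz[, 2:(nz + 1)] * sponge
    }
    if (s > rec_from) {
      cyc <- if (s > n_steps - spc) 2L else 1L
      mins[[cyc]] <- pmin(mins[[cyc]], p)
      maxs[[cyc]] <- pmax(maxs[[cyc]], p)
    }
  }
  amp_prev <- (maxs[[1]] - mins[[1]]) / 2
  amp_last <- (maxs[[2]] - mins[[2]]) / 2
  change <- sqrt(sum((amp_last - amp_prev)^2)) / max(sqrt(sum(amp_last^2)), 1e-300)
  if (sim$check_convergence && change >= 0.02)
    stopf("no periodic steady state after %d cycles (relative change %.1f%%)",
          sim$n_cycles, 100 * change)
  amp <- pmax((pmax(maxs[[1]], maxs[[2]]) - pmin(mins[[1]], mins[[2]])) / 2, 0)
  out <- field_map(r, z, amp)
  out$stone_mask <- maps$stone_mask
  out$cycle_change <- change
  out$grid_step <- dx
  class(out) <- c("steady_amplitude_map", class(out))
  out
}
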