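make_norm_field <- function(r, z, p_star) {
  structure(list(r_star = r / max(r), z_star = z / max(z), p_star = p_star,
                 r = r, z = z, amplitude = p_star, normalized = TRUE),
            class = c("normalized_field", "field_map"))
}

test_that("threshold mask keeps strictly supra-threshold pixels only", {
  r <- seq(0.5e-3, 10e-3, by = 0.5e-3); z <- seq(0.5e-3, 20e-3, by = 0.5e-3)
  # uniform sub-threshold field -> empty mask (after forcing one max pixel)
  p <- matrix(0.4, length(r), length(z)); p[1, 1] <- 1
  m <- threshold_mask(make_norm_field(r, z, p), 0.46)
  expect_equal(sum(m), 1L)                       # only the max pixel
  # monotone shrinking in the threshold
  p2 <- matrix(runif(length(r) * length(z)), length(r))
  p2 <- p2 / max(p2)
  f2 <- make_norm_field(r, z, p2)
  m_lo <- threshold_mask(f2, 0.3); m_hi <- threshold_mask(f2, 0.6)
  expect_true(all(m_lo[m_hi]))                   # mask_hi subset of mask_lo
  # unnormalized input is rejected
  expect_error(threshold_mask(field_map(r, z, p2), 0.46), "normalized")
})

test_that("stone-free supra-threshold focal region is a single component", {
  geom <- focal_geom()
  nf <- normalize_field(focal_field(), geom)
  regs <- label_regions(threshold_mask(nf, 0.46))
  expect_equal(length(regs), 1L)
  expect_equal(regs[[1]]$label, "other")
  expect_false(regs[[1]]$attached_to_stone)
})

test_that("component labels are stable under whole-cell translation", {
  r <- seq(0.5e-3, 15e-3, by = 0.5e-3); z <- seq(0.5e-3, 30e-3, by = 0.5e-3)
  m <- matrix(FALSE, length(r), length(z))
  m[3:6, 5:9] <- TRUE; m[10:13, 20:24] <- TRUE
  shifted <- matrix(FALSE, length(r), length(z))
  shifted[, 4:ncol(m)] <- m[, 1:(ncol(m) - 3)]
  n1 <- length(label_regions(m, r = r, z = z))
  n2 <- length(label_regions(shifted, r = r, z = z))
  expect_equal(n1, 2L)
  expect_equal(n2, 2L)
})

test_that("hemisphere run yields detached lobes plus one attached region", {
  regs <- hemi_regions()
  expect_gte(length(regs), 2L)
  expect_equal(sum(vapply(regs, `[[`, TRUE, "attached_to_stone")), 1L)
  # regions come ordered by distance from the stone: the attached Pi1
  # first, then Pi2 as the nearest detached component on the source side
  labels <- vapply(regs, `[[`, "", "label")
  expect_equal(labels[1], "Pi1")
  expect_equal(labels[2], "Pi2")
})

test_that("cap projection recovers constructed polar-cap bounds", {
  st <- stone_spec("hemisphere", radius = 10e-3, apex_z = 50e-3)
  zc <- st$apex_z + st$radius
  grid_r <- seq(0.1e-3, 15e-3, by = 0.2e-3)
  grid_z <- seq(40e-3, 62e-3, by = 0.2e-3)
  region_from_angles <- function(th_lo, th_hi) {
    pts <- expand.grid(r = grid_r, z = grid_z)
    rad <- sqrt(pts$r^2 + (pts$z - zc)^2)
    th <- atan2(pts$r, zc - pts$z)
    sel <- rad > st$radius & rad < st$radius + 2e-3 &
      th >= th_lo & th <= th_hi & pts$z <= zc
    structure(list(label = "Pi1", r = pts$r[sel], z = pts$z[sel],
                   pixels = cbind(1, 1), attached_to_stone = TRUE,
                   spanwise_diameter = 2 * max(pts$r[sel]),
                   distance_to_stone = 0, n_pixels = sum(sel)),
              class = "pressure_region")
  }
  # annular band between polar angles 20 and 40 degrees -> theta_p = 40
  ann <- region_from_angles(20 * pi / 180, 40 * pi / 180)
  cm <- cap_angle_of_region(ann, st)
  expect_equal(cm$theta * 180 / pi, 40, tolerance = 0.04)
  # thin axial sliver -> theta_p ~ 0, A* ~ 0
  sliver <- region_from_angles(0, 1.2 * pi / 180)
  cm0 <- cap_angle_of_region(sliver, st)
  expect_lt(cm0$theta, 2.5 * pi / 180)
  expect_lt(cm0$A_star, 0.01)
  # band covering the whole proximal face -> theta_p = pi/2, A* = 4
  full <- region_from_angles(0, pi / 2)
  cmf <- cap_angle_of_region(full, st)
  expect_equal(cmf$theta, pi / 2, tolerance = 0.03)
  expect_equal(cmf$A_star, 4, tolerance = 0.05)
})

test_that("damage coefficient follows 4(1 - cos theta) on [0, pi/2]", {
  expect_equal(damage_coefficient(0), 0)
  expect_equal(damage_coefficient(pi / 3), 2)
  expect_equal(damage_coefficient(pi / 2), 4)
  th <- seq(0, pi / 2, length.out = 50)
  a <- damage_coefficient(th)
  expect_true(all(diff(a) > 0))                  # strictly increasing
  expect_true(all(a >= 0 & a <= 4))
  expect_error(damage_coefficient(-0.2), "pi/2")
  expect_error(damage_coefficient(2), "pi/2")
})

test_that("scan-based optimum distance matches the closed-form cases", {
  st <- stone_spec("hemisphere", radius = 10e-3, apex_z = 60e-3)
  gf <- 50e-3; l2 <- 30e-3
  geom <- focal_geometry(gf, l1 = 6e-3, l2 = l2)
  z <- seq(10e-3, 90e-3, by = 0.05e-3)
  refl <- 2 * st$impedance_ratio / (1 + st$impedance_ratio)
  # gaussian post-focal decay with known pc crossing
  sig <- 12e-3
  prof <- axial_profile(z, 1e5 * exp(-(z - gf)^2 / (2 * sig^2)))
  # case 2: threshold low enough that pi(gf + l2/2) >= pc
  pc2 <- 0.9 * 1e5 * exp(-(l2 / 2)^2 / (2 * sig^2))
  o2 <- optimal_distance(prof, geom, st, pc2)
  expect_equal(o2$regime, "focus-plus-half-ell2")
  expect_equal(o2$z_plus, gf + l2 / 2)
  # case 1: pc equal to pi(gamma_f) within tolerance -> z+ = gamma_f
  o1 <- optimal_distance(prof, geom, st, 1e5 * 0.9999)
  expect_equal(o1$regime, "at-focus")
  expect_equal(o1$z_plus, gf)
  # intermediate: pr crosses pc at a known z0 inside the scan
  z0 <- gf + 10e-3
  pc_mid <- refl * 1e5 * exp(-(z0 - gf)^2 / (2 * sig^2))
  om <- optimal_distance(prof, geom, st, pc_mid * (1 + 1e-9))
  expect_equal(om$regime, "intermediate")
  expect_equal(om$z_plus, z0, tolerance = (l2 / 2) / 512 / z0 * 2)
  # bounds invariant over thresholds that admit cavitation
  for (fac in c(0.2, 0.5, 0.9)) {
    oo <- optimal_distance(prof, geom, st, fac * refl * 1e5)
    expect_true(oo$z_plus >= gf && oo$z_plus <= gf + l2 / 2)
  }
  expect_error(optimal_distance(prof, geom, st, 2 * refl * 1e5),
               "no cavitation")
})
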