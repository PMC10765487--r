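test_that("axial field is linear in the drive velocity", {
  z <- seq(20e-3, 90e-3, by = 0.5e-3)
  p1 <- oneil_axial(default_tx(u0 = 1e-3), water(), z)$p
  p2 <- oneil_axial(default_tx(u0 = 2e-3), water(), z)$p
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
})

test_that("O'Neil closed form matches an independent midpoint quadrature", {
  # crude Rayleigh-Sommerfeld double sum over the cap, written here from
  # scratch as an oracle for the closed form
  oracle <- function(spec, medium, z) {
    g <- bowl_geometry(spec)
    f <- spec$focus
    k <- 2 * pi / wavelength(spec, medium)
    npsi <- 600
    psi <- (seq_len(npsi) - 0.5) * g$psi_max / npsi
    tot <- 0i
    for (i in seq_len(npsi)) {
      sr <- f * sin(psi[i]); sz <- g$z_focus - f * cos(psi[i])
      R <- sqrt(sr^2 + (z - sz)^2)           # on-axis: phi-independent
      tot <- tot + f^2 * sin(psi[i]) * (g$psi_max / npsi) *
        (exp(-1i * k * R) / R) * 2 * pi
    }
    medium$density * medium$sound_speed * k * spec$u0 / (2 * pi) * Mod(tot)
  }
  med <- medium_spec(alpha0 = 0)             # lossless comparison
  geoms <- list(c(67e-3, 32e-3), c(50e-3, 20e-3), c(80e-3, 40e-3))
  for (ga in geoms) {
    spec <- transducer_spec(250e3, ga[1], ga[2], u0 = 1e-2)
    zg <- bowl_geometry(spec)$z_focus
    z <- seq(0.4 * zg, 1.6 * zg, length.out = 9)
    po <- oneil_axial(spec, med, z)$p
    pq <- vapply(z, function(zz) oracle(spec, med, zz), 0)
    expect_lt(max(abs(po - pq) / po), 0.01)
  }
})

test_that("Rayleigh field on-axis column agrees with the closed form", {
  z <- seq(30e-3, 90e-3, by = 2e-3)
  fm <- suppressWarnings(      # axis-only column: lobe aliasing is irrelevant
    rayleigh_field(default_tx(), water(), r = c(0, 0.5e-3), z = z))
  po <- oneil_axial(default_tx(), water(), z)$p
  expect_lt(max(abs(fm$amplitude[1, ] - po) / po), 0.01)
})

test_that("lateral focal profile has a single main lobe with monotone decay", {
  geom <- focal_geom()
  fm <- focal_field()
  lat <- fm$amplitude[, which.min(abs(fm$z - geom$gamma_f))]
  i_null <- which(diff(lat) > 0)[1]          # first rise marks the first null
  expect_gt(i_null, 5)
  expect_true(all(diff(lat[1:i_null]) < 0))  # monotone to the first null
  expect_lt(lat[i_null] / lat[1], 0.2)       # deep null
})

test_that("physical focus sits pre-focally and tightens as a -> f", {
  gf <- gamma_f_default()
  expect_lt(gf, bowl_geometry(default_tx())$z_focus)
  # monotone sweep: larger aperture (tighter focusing) moves gamma_f toward
  # the geometric focus (in units of z_focus)
  ratio <- vapply(c(20e-3, 28e-3, 36e-3), function(a) {
    spec <- transducer_spec(250e3, 67e-3, a, u0 = 1e-2)
    prof <- oneil_axial(spec, water(), seq(5e-3, 120e-3, by = 0.1e-3))
    physical_focus(prof) / bowl_geometry(spec)$z_focus
  }, 0)
  expect_true(all(diff(ratio) > 0))
  expect_true(all(ratio < 1))
})

test_that("scaling lengths x2 and halving frequency leaves gamma_f/f fixed", {
  p1 <- oneil_axial(transducer_spec(250e3, 67e-3, 32e-3, u0 = 1e-2),
                    medium_spec(alpha0 = 0), seq(5e-3, 120e-3, by = 0.1e-3))
  p2 <- oneil_axial(transducer_spec(125e3, 134e-3, 64e-3, u0 = 1e-2),
                    medium_spec(alpha0 = 0), seq(10e-3, 240e-3, by = 0.2e-3))
  expect_equal(physical_focus(p2) / physical_focus(p1), 2, tolerance = 1e-6)
})

test_that("profile maximum on the grid boundary is an error", {
  # monotone rise toward the focal lobe: argmax lands on the last sample
  z <- seq(35e-3, 48e-3, by = 0.5e-3)
  expect_error(physical_focus(oneil_axial(default_tx(), water(), z)),
               "boundary")
})

test_that("FWHM fit round-trips a synthetic Gaussian-lobe field", {
  r <- seq(0, 10e-3, by = 0.1e-3)
  z <- seq(20e-3, 90e-3, by = 0.25e-3)
  l1_true <- 6e-3; l2_true <- 30e-3; gf_true <- 55e-3
  sig1 <- l1_true / (2 * sqrt(2 * log(2)))
  sig2 <- l2_true / (2 * sqrt(2 * log(2)))
  amp <- outer(r, z, function(r, z)
    1e5 * exp(-r^2 / (2 * sig1^2) - (z - gf_true)^2 / (2 * sig2^2)))
  geom <- focal_geometry_fit(field_map(r, z, amp), default_tx(), water())
  expect_equal(geom$gamma_f, gf_true, tolerance = 0.5 * 0.25e-3 / gf_true)
  expect_equal(geom$l1, l1_true, tolerance = 0.5 * 0.1e-3 / l1_true)
  expect_equal(geom$l2, l2_true, tolerance = 0.5 * 0.25e-3 / l2_true)
})

test_that("focal geometry is decoupled from the drive amplitude", {
  r <- seq(0, 10e-3, by = 0.25e-3)
  z <- seq(35e-3, 90e-3, by = 1e-3)
  # a 2^7 amplitude ratio scales every float exactly, so geometry and the
  # normalized map must come out bit-identical
  u0a <- 1e-3; u0b <- u0a * 128
  f1 <- rayleigh_field(default_tx(u0 = u0a), water(), r, z)
  f2 <- rayleigh_field(default_tx(u0 = u0b), water(), r, z)
  g1 <- focal_geometry_fit(f1, default_tx(u0 = u0a), water())
  g2 <- focal_geometry_fit(f2, default_tx(u0 = u0b), water())
  # geometry identical once the amplitude scale divides out
  expect_identical(c(g1$gamma_f, g1$l1, g1$l2), c(g2$gamma_f, g2$l1, g2$l2))
  expect_identical(f1$amplitude / max(f1$amplitude),
                   f2$amplitude / max(f2$amplitude))
})

test_that("normalization maps the focus to (0, 1, 1) and rejects reuse", {
  geom <- focal_geom()
  nf <- normalize_field(focal_field(), geom)
  expect_equal(max(nf$p_star), 1)
  i <- which(nf$p_star == 1, arr.ind = TRUE)
  expect_equal(nf$r_star[i[1]], 0, tolerance = 1e-9)
  expect_equal(nf$z_star[i[2]], 1, tolerance = 0.02)
  expect_error(normalize_field(nf, geom), "already normalized")
  # any amplitude rescaling yields the identical dimensionless map
  fm <- focal_field()
  scaled <- field_map(fm$r, fm$z, fm$amplitude * 37.5)
  expect_equal(normalize_field(scaled, geom)$p_star, nf$p_star)
})
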