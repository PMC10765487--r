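test_that("MinIP equals the brute-force per-pixel loop and its algebra", {
  set.seed(42)
  frames <- array(runif(20 * 15 * 10), dim = c(20, 15, 10))
  st <- image_stack(frames, pixel_scale = 1e-5, frame_rate = 1e4)
  proj <- minip(st)
  brute <- matrix(0, 20, 15)
  for (i in 1:20) for (j in 1:15) brute[i, j] <- min(frames[i, j, ])
  expect_equal(proj, brute)
  # single frame projects to itself
  expect_equal(minip(st, 3), frames[, , 3])
  # adding frames can only darken or preserve
  expect_true(all(minip(st, 1:5) >= proj))
  # idempotent on its own output; commutes with frame permutation
  st2 <- image_stack(array(rep(proj, 4), dim = c(20, 15, 4)), 1e-5, 1e4)
  expect_equal(minip(st2), proj)
  expect_equal(minip(st, sample(10)), proj)
  expect_error(minip(st, integer(0)), "empty")
})

test_that("blank frames yield no detections", {
  expect_equal(nrow(detect_bubbles(matrix(0.9, 64, 64), 1e-5)), 0L)
  expect_equal(nrow(detect_bubbles(matrix(1, 64, 64), 1e-5)), 0L)
})

test_that("number density follows count over interrogation volume", {
  sp <- scene_spec(density_mm3 = 25, n_frames = 2, seed = 9)
  cen <- bubble_census(synth_bubble_stack(sp)$stack)
  n1 <- number_density(cen)
  # doubling the depth of field halves the density at fixed counts
  expect_equal(number_density(cen, volume_mm3 = 2 * attr(cen, "fov_m2") *
                                attr(cen, "depth_of_field") * 1e9),
               n1 / 2)
  # zero bubbles -> zero density
  sp0 <- scene_spec(density_mm3 = 0, n_frames = 2, seed = 9)
  cen0 <- bubble_census(synth_bubble_stack(sp0)$stack)
  expect_equal(number_density(cen0), 0)
  # missing depth-of-field metadata is an error
  attr(cen, "depth_of_field") <- NULL
  expect_error(number_density(cen), "depth-of-field")
})

test_that("size distribution recovers unimodal and bimodal truths", {
  uni <- scene_spec(density_mm3 = 35, size_weights = c(1, 0), n_frames = 6,
                    seed = 21)
  cen_u <- bubble_census(synth_bubble_stack(uni)$stack)
  sd_u <- size_distribution(cen_u)
  expect_equal(length(sd_u$peaks_m), 1L)
  expect_lt(abs(sd_u$peaks_m[1] - 150e-6), 25e-6)      # within one bin
  bi <- scene_spec(density_mm3 = 35, size_weights = c(0.6, 0.4), n_frames = 6,
                   seed = 11)
  cen_b <- bubble_census(synth_bubble_stack(bi)$stack)
  sd_b <- size_distribution(cen_b)
  expect_gte(length(sd_b$peaks_m), 2L)
  pk <- sort(sd_b$peaks_m[1:2])
  expect_lt(abs(pk[1] - 50e-6), 25e-6)
  expect_lt(abs(pk[2] - 150e-6), 25e-6)
  # all-equal diameters: single peak at the common value
  cen_c <- data.frame(d_m = rep(120e-6, 30), individual = TRUE)
  expect_equal(size_distribution(cen_c)$peaks_m, 120e-6)
  expect_error(size_distribution(data.frame(d_m = 1e-4, individual = TRUE)),
               "too few")
})

test_that("dimensionless rise speed reproduces the cloud-velocity table", {
  expect_identical(dimensionless_speed(0.92, 1.32), 0.70)
  expect_identical(dimensionless_speed(0.39, 1.32), 0.30)
  expect_identical(dimensionless_speed(2.70, 1.32), 2.05)
  expect_identical(dimensionless_speed(1.32, 1.32), 1.00)
  # linear in uz before rounding
  expect_equal(dimensionless_speed(2 * 0.5, 1), 2 * dimensionless_speed(0.5, 1))
})

test_that("rise speed is the least-squares slope and needs 3+ samples", {
  tr <- structure(list(id = 1L, frames = 1:5, t_s = (1:5) / 1e4,
                       x_m = rep(0, 5),
                       z_m = 1e-3 + 1.2 * (1:5) / 1e4 + c(1, -1, 0, 1, -1) * 1e-7,
                       parents = integer(0)), class = "cloud_track")
  expect_equal(rise_speed(tr), 1.2, tolerance = 1e-2)
  expect_error(rise_speed(tr, window = 1:2), "3 samples")
})

test_that("surface profile localizes dips at occupied polar angles", {
  img <- matrix(0.9, 200, 200)
  circle <- list(row = 60, col = 100, radius_px = 60)
  img <- lithocav:::render_discs(img, circle$row, circle$col, 120, dark = 0.05)
  # uniform background: flat profile
  prof0 <- surface_intensity_profile(matrix(0.7, 200, 200), circle, 5)
  expect_true(all(prof0$I_star == 1))
  # dark blobs only between 0 and 30 degrees (both sides)
  th_occ <- seq(-30, 30, by = 4) * pi / 180
  rows <- circle$row + (circle$radius_px + 5) * cos(th_occ)
  cols <- circle$col + (circle$radius_px + 5) * sin(th_occ)
  img2 <- lithocav:::render_discs(img, rows, cols, rep(6, length(th_occ)))
  prof <- surface_intensity_profile(img2, circle, 5)
  # rendered discs have ~2.6 degrees of angular half-width on this arc
  occupied <- prof$theta < 34 * pi / 180
  expect_lt(min(prof$I_star[occupied]), 0.2)
  expect_true(all(prof$I_star[!occupied] > 0.6))
  cm <- cap_angle_from_profile(prof, 0.5, stone_radius = 10e-3)
  expect_lt(abs(cm$theta * 180 / pi - 30), 3.5)
  # flat bright profile -> zero cap
  expect_equal(cap_angle_from_profile(prof0, 0.5, stone_radius = 10e-3)$theta,
               0)
})

test_that("bubble and fragment dips overlap on co-located scenes", {
  ssp <- scene_spec(shape = c(220, 220),
                    stone = list(row = 60, col = 110, radius_px = 70),
                    theta_b = 35 * pi / 180, theta_d = 35 * pi / 180,
                    seed = 14)
  ss <- synth_stone_scene(ssp)
  pb <- surface_intensity_profile(minip(ss$stack, ss$truth$phase1),
                                  ssp$stone, ss$arc_offset_px)
  pd <- surface_intensity_profile(minip(ss$stack, ss$truth$phase2),
                                  ssp$stone, ss$arc_offset_px)
  dip_b <- pb$I_star < 0.5
  dip_d <- pd$I_star < 0.5
  jaccard <- sum(dip_b & dip_d) / sum(dip_b | dip_d)
  expect_gt(jaccard, 0.7)
})
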