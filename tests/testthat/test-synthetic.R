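test_that("generators are bit-identical under a fixed seed", {
  sp <- scene_spec(density_mm3 = 20, n_frames = 3, seed = 5)
  a <- synth_bubble_stack(sp); b <- synth_bubble_stack(sp)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  csp <- cloud_scene(seed = 5)
  expect_identical(synth_cloud_stack(csp)$stack$frames,
                   synth_cloud_stack(csp)$stack$frames)
  ssp <- scene_spec(shape = c(180, 180),
                    stone = list(row = 50, col = 90, radius_px = 55), seed = 5)
  expect_identical(synth_stone_scene(ssp)$stack$frames,
                   synth_stone_scene(ssp)$stack$frames)
})

test_that("zero density renders blank frames with empty truth", {
  sp <- scene_spec(density_mm3 = 0, n_frames = 2, noise_sd = 0, seed = 2)
  out <- synth_bubble_stack(sp)
  expect_equal(nrow(out$truth$bubbles), 0L)
  expect_gt(min(out$stack$frames), 0.7)          # nothing dark anywhere
})

test_that("rendered disc diameters match truth within a pixel", {
  sp <- scene_spec(shape = c(512, 512), density_mm3 = 0, noise_sd = 0,
                   n_frames = 1, seed = 8)
  out <- synth_bubble_stack(sp, n_bubbles = 100, min_clearance_px = 4)
  det <- detect_bubbles(out$stack$frames[, , 1], sp$pixel_scale)
  tr <- out$truth$bubbles
  err_px <- vapply(seq_len(nrow(tr)), function(i) {
    dd <- sqrt((det$x_m - tr$x_m[i])^2 + (det$z_m - tr$z_m[i])^2)
    j <- which.min(dd)
    if (dd[j] < 40e-6) abs(det$d_m[j] - tr$d_m[i]) / sp$pixel_scale else NA
  }, 0)
  expect_gt(mean(!is.na(err_px)), 0.98)
  expect_lt(mean(err_px, na.rm = TRUE), 1)       # MAE under one pixel
})

test_that("cloud kinematics follow speed / frame_rate per frame", {
  csp <- scene_spec(shape = c(400, 120), frame_rate = 50e3,
                    clouds = list(list(x0 = 0.45e-3, z0 = 0.5e-3, speed = 1.32,
                                       n_bubbles = 10, sigma = 40e-6,
                                       d = 50e-6)),
                    n_frames = 5, seed = 3)
  out <- synth_cloud_stack(csp)
  tr <- out$truth$trajectories
  dz <- diff(tr$z_m[tr$cloud == 1])
  expect_equal(dz, rep(1.32 / 50e3, 4))          # 26.4 um per frame
  # zero speed: static cluster
  csp0 <- scene_spec(shape = c(120, 120),
                     clouds = list(list(x0 = 0.45e-3, z0 = 0.45e-3, speed = 0,
                                        n_bubbles = 10, sigma = 40e-6,
                                        d = 50e-6)),
                     n_frames = 4, seed = 3)
  tr0 <- synth_cloud_stack(csp0)$truth$trajectories
  expect_equal(diff(tr0$z_m), rep(0, 3))
  # out-of-frame trajectory is an error
  cspx <- scene_spec(shape = c(60, 60),
                     clouds = list(list(x0 = 0.2e-3, z0 = 0.4e-3, speed = 2,
                                        n_bubbles = 5, sigma = 20e-6,
                                        d = 50e-6)),
                     n_frames = 10, seed = 3)
  expect_error(synth_cloud_stack(cspx), "leaves the frame")
})

test_that("merge schedule lineage is preserved in the truth", {
  sched <- list(list(frame = 10, parents = c(1, 2), child = 5),
                list(frame = 20, parents = c(5, 3), child = 6),
                list(frame = 30, parents = c(6, 4), child = 7))
  csp <- scene_spec(shape = c(200, 200),
                    clouds = replicate(4, list(list(x0 = 0.8e-3, z0 = 0.8e-3,
                                                    speed = 0, n_bubbles = 4,
                                                    sigma = 30e-6, d = 50e-6))),
                    merge_schedule = sched, n_frames = 3, seed = 4)
  out <- synth_cloud_stack(csp)
  expect_equal(length(out$truth$merges), 3L)     # 4 subclouds -> 3 merges
  expect_equal(out$truth$merges[[3]]$child, 7)
})

test_that("fragment plumes are absent at theta_d = 0 and follow normals", {
  ssp0 <- scene_spec(shape = c(180, 180),
                     stone = list(row = 50, col = 90, radius_px = 55),
                     theta_d = 0, n_plumes = 0, seed = 6)
  out0 <- synth_stone_scene(ssp0, n_phase1 = 2, n_phase2 = 3)
  expect_null(out0$truth$particles)
  ssp <- scene_spec(shape = c(220, 220),
                    stone = list(row = 60, col = 110, radius_px = 70),
                    theta_d = 40 * pi / 180, seed = 6)
  out <- synth_stone_scene(ssp, n_phase1 = 2, n_phase2 = 6)
  # leading particle displacement over early frames vs the surface normal
  pt <- out$truth$particles
  st <- ssp$stone
  for (th in unique(pt$theta)[c(1, 11, 21)]) {
    lead <- pt[pt$theta == th & pt$trail == 0, ]
    lead <- lead[order(lead$frame), ]
    step <- c(lead$row[2] - lead$row[1], lead$col[2] - lead$col[1])
    ang <- acos(sum(step * c(cos(th), sin(th))) / sqrt(sum(step^2)))
    expect_lt(ang * 180 / pi, 5)
  }
})

test_that("image stacks round-trip through TIFF with sidecar metadata", {
  sp <- scene_spec(shape = c(64, 64), density_mm3 = 20, n_frames = 3, seed = 13)
  st <- synth_bubble_stack(sp)$stack
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(dim(back$frames), dim(st$frames))
  expect_lt(max(abs(back$frames - st$frames)), 2e-5)   # 16-bit quantization
  expect_equal(back$pixel_scale, st$pixel_scale)
  expect_equal(back$frame_rate, st$frame_rate)
  expect_equal(back$depth_of_field, st$depth_of_field)
})
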