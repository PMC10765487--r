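#' Synthetic shadowgraph scene specification
#'
#' Ground-truth parameters for generated shadowgraph scenes emulating
#' the statistical structure of 250-kHz HIFU cavitation imaging: dark
#' bubbles on a bright background with a lognormal-mixture size law
#' (single ~150 um mode early, an added ~50 um mode later), a number
#' density of tens per mm^3, clouds rising at ~1-1.5 m/s with merge
#' events, and a stone silhouette with fragment plumes ejected normal to
#' the surface over a polar cap.
#'
#' @param shape image size in pixels, c(rows, cols)
#' @param pixel_scale metres per pixel (default 8 um)
#' @param frame_rate frames per second (default 50 kHz)
#' @param n_frames frames to render (default 10)
#' @param size_medians lognormal mode medians in m (default
#'   c(150e-6, 50e-6))
#' @param size_weights mixture weights, summing to 1 (default c(1, 0):
#'   the early unimodal law)
#' @param size_sdlog lognormal sigma of each mode (default 0.25)
#' @param density_mm3 target bubble number density in mm^-3 (default 33)
#' @param depth_of_field interrogation depth of field in m (default
#'   0.1 mm)
#' @param clouds list of cloud descriptors: each
#'   `list(x0, z0, speed, n_bubbles, sigma, d)` (m, m, m/s upward,
#'   count, cluster radius m, bubble diameter m)
#' @param merge_schedule list of `list(frame, parents, child)` truth
#'   merge events
#' @param stone `list(row, col, radius_px)` stone circle, or NULL
#' @param theta_b bubble-layer cap edge angle in rad, in \[0, pi/2\]
#' @param theta_d fragment cap edge angle in rad, in \[0, pi/2\]
#' @param n_plumes fragment plumes over the cap (default 21)
#' @param noise_sd additive Gaussian noise sd (default 0.01)
#' @param bg_gradient peak-to-peak vertical background gradient
#'   (default 0.05)
#' @param seed integer RNG seed; every generator draw derives from it
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(shape = c(256, 256), pixel_scale = 8e-6,
                       frame_rate = 50e3, n_frames = 10,
                       size_medians = c(150e-6, 50e-6),
                       size_weights = c(1, 0), size_sdlog = 0.25,
                       density_mm3 = 33, depth_of_field = 1e-4,
                       clouds = list(), merge_schedule = list(),
                       stone = NULL, theta_b = 40 * pi / 180,
                       theta_d = 40 * pi / 180, n_plumes = 21,
                       noise_sd = 0.01, bg_gradient = 0.05, seed = 1L) {
  if (abs(sum(size_weights) - 1) > 1e-9) stopf("size weights must sum to 1")
  if (theta_b < 0 || theta_b > pi / 2 || theta_d < 0 || theta_d > pi / 2)
    stopf("cap angles must lie in [0, pi/2]")
  for (cl in clouds) if (cl$speed < 0) stopf("cloud speeds must be >= 0")
  check_num(density_mm3, "density_mm3", nonneg = TRUE)
  structure(list(shape = shape, pixel_scale = pixel_scale,
                 frame_rate = frame_rate, n_frames = n_frames,
                 size_medians = size_medians, size_weights = size_weights,
                 size_sdlog = size_sdlog, density_mm3 = density_mm3,
                 depth_of_field = depth_of_field, clouds = clouds,
                 merge_schedule = merge_schedule, stone = stone,
                 theta_b = theta_b, theta_d = theta_d, n_plumes = n_plumes,
                 noise_sd = noise_sd, bg_gradient = bg_gradient,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# bright canvas with a mild vertical gradient
blank_canvas <- function(spec) {
  rows <- matrix(seq_len(spec$shape[1]), spec$shape[1], spec$shape[2])
  0.85 + spec$bg_gradient * (rows / spec$shape[1] - 0.5)
}

# render opaque discs with a ~1-px soft (logistic) edge; darkest wins
render_discs <- function(canvas, row, col, d_px, dark = 0.08, edge = 0.6) {
  H <- nrow(canvas); W <- ncol(canvas)
  for (b in seq_along(row)) {
    r_px <- d_px[b] / 2
    ext <- ceiling(r_px + 4 * edge)
    r0 <- max(1, floor(row[b] - ext)); r1 <- min(H, ceiling(row[b] + ext))
    c0 <- max(1, floor(col[b] - ext)); c1 <- min(W, ceiling(col[b] + ext))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    dist <- sqrt(outer((rr - row[b])^2, (cc - col[b])^2, `+`))
    s <- stats::plogis((dist - r_px) / edge)
    patch <- dark + (canvas[rr, cc] - dark) * s
    canvas[rr, cc] <- pmin(canvas[rr, cc], patch)
  }
  canvas
}

draw_sizes <- function(spec, n) {
  comp <- sample.int(length(spec$size_weights), n, replace = TRUE,
                     prob = spec$size_weights)
  stats::rlnorm(n, meanlog = log(spec$size_medians[comp]),
                sdlog = spec$size_sdlog)
}

add_noise <- function(frame, spec) {
  pmin(pmax(frame + stats::rnorm(length(frame), 0, spec$noise_sd), 0), 1)
}

#' Synthetic bubble-field stack with ground truth
#'
#' Draws a Poisson number of bubbles from the target density times the
#' interrogation volume, sizes from the lognormal mixture, positions
#' uniform over the field of view, and renders them as static dark
#' anti-aliased discs (each bubble shown at its maximum size) over
#' `n_frames` frames with per-frame noise. Bit-identical under a fixed
#' seed.
#'
#' @param spec a [scene_spec()]
#' @param n_bubbles fixed bubble count, overriding the Poisson draw from
#'   density x volume
#' @param min_clearance_px when set, positions are rejection-sampled so
#'   rendered discs keep at least this clearance (non-overlapping
#'   ground-truth layouts for detection-rate tests)
#' @return list with `stack` (an [image_stack()]) and `truth` (list with
#'   per-bubble records and the realized density)
#' @export
synth_bubble_stack <- function(spec, n_bubbles = NULL,
                               min_clearance_px = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$shape[1]; W <- spec$shape[2]
  fov_mm2 <- H * W * (spec$pixel_scale * 1e3)^2
  vol_mm3 <- fov_mm2 * spec$depth_of_field * 1e3
  n <- n_bubbles %||% stats::rpois(1, spec$density_mm3 * vol_mm3)
  d <- if (n > 0) draw_sizes(spec, n) else numeric(0)
  d_px <- d / spec$pixel_scale
  if (sum(pi * (d_px / 2)^2) > 0.9 * H * W)
    stopf("requested density renders > 90%% overlap; reduce density or sizes")
  margin <- if (n > 0) max(d_px) / 2 + 2 else 0
  if (is.null(min_clearance_px)) {
    row <- stats::runif(n, 1 + margin, H - margin)
    col <- stats::runif(n, 1 + margin, W - margin)
  } else {
    row <- col <- numeric(n)
    for (b in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(2000)) {
        rr <- stats::runif(1, 1 + margin, H - margin)
        cc <- stats::runif(1, 1 + margin, W - margin)
        sep <- if (b == 1) Inf else
          sqrt((row[1:(b - 1)] - rr)^2 + (col[1:(b - 1)] - cc)^2) -
          (d_px[1:(b - 1)] + d_px[b]) / 2
        if (all(sep >= min_clearance_px)) {
          row[b] <- rr; col[b] <- cc; placed <- TRUE; break
        }
      }
      if (!placed) stopf("cannot place %d non-overlapping bubbles", n)
    }
  }
  base <- blank_canvas(spec)
  scene <- render_discs(base, row, col, d_px)
  frames <- lapply(seq_len(spec$n_frames), function(f) add_noise(scene, spec))
  xz <- if (n > 0) px_to_xz(row, col, H, spec$pixel_scale) else
    cbind(x = numeric(0), z = numeric(0))
  truth <- list(bubbles = data.frame(bubble = seq_len(n),
                                     x_m = xz[, "x"], z_m = xz[, "z"],
                                     d_m = d),
                volume_mm3 = vol_mm3, density_mm3 = n / vol_mm3)
  list(stack = image_stack(frames, spec$pixel_scale, spec$frame_rate,
                           spec$depth_of_field),
       truth = truth)
}

#' Synthetic rising-cloud stack with ground truth
#'
#' Each cloud is a rigid cluster of small bubbles advected upward at its
#' constant rise speed; the merge schedule is recorded as truth lineage.
#' Trajectories must remain inside the frame for the full duration.
#'
#' @param spec a [scene_spec()] with a non-empty `clouds` list
#' @return list with `stack` and `truth` (per-cloud per-frame centroids
#'   and the merge events)
#' @export
synth_cloud_stack <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!length(spec$clouds)) stopf("no clouds in the scene spec")
  set.seed(spec$seed)
  H <- spec$shape[1]; W <- spec$shape[2]
  dt <- 1 / spec$frame_rate
  offsets <- lapply(spec$clouds, function(cl)
    list(dr = stats::rnorm(cl$n_bubbles, 0, cl$sigma / spec$pixel_scale),
         dc = stats::rnorm(cl$n_bubbles, 0, cl$sigma / spec$pixel_scale)))
  traj <- list()
  frames <- vector("list", spec$n_frames)
  base <- blank_canvas(spec)
  for (f in seq_len(spec$n_frames)) {
    canvas <- base
    for (ci in seq_along(spec$clouds)) {
      cl <- spec$clouds[[ci]]
      z <- cl$z0 + cl$speed * (f - 1) * dt
      row_c <- H - z / spec$pixel_scale + 0.5
      col_c <- cl$x0 / spec$pixel_scale + 0.5
      rows <- row_c + offsets[[ci]]$dr
      cols <- col_c + offsets[[ci]]$dc
      pad <- cl$d / spec$pixel_scale
      if (any(rows < 1 + pad) || any(rows > H - pad) ||
          any(cols < 1 + pad) || any(cols > W - pad))
        stopf("cloud %d leaves the frame at frame %d", ci, f)
      canvas <- render_discs(canvas, rows, cols,
                             rep(cl$d / spec$pixel_scale, cl$n_bubbles))
      traj[[length(traj) + 1]] <- data.frame(cloud = ci, frame = f,
                                             t_s = f * dt, x_m = cl$x0,
                                             z_m = z)
    }
    frames[[f]] <- add_noise(canvas, spec)
  }
  list(stack = image_stack(frames, spec$pixel_scale, spec$frame_rate,
                           spec$depth_of_field),
       truth = list(trajectories = do.call(rbind, traj),
                    merges = spec$merge_schedule,
                    speeds = vapply(spec$clouds, `[[`, 0, "speed")))
}

#' Synthetic stone scene: bubble layer, then falling fragment plumes
#'
#' Phase 1 frames show a bubble layer hugging the stone surface over the
#' polar cap \[0, theta_b\] (both azimuthal sides); phase 2 frames show
#' fragment plumes seeded at angles evenly spanning \[-theta_d, theta_d\]
#' and advected radially outward along the local surface normal with a
#' growing downward drift. Both cap angles are recorded as truth.
#'
#' @param spec a [scene_spec()] with a `stone` circle
#' @param n_phase1 bubble-layer frames (default 8)
#' @param n_phase2 fragment frames (default 10)
#' @param arc_offset_px bubble/plume seeding offset from the surface in
#'   pixels (default 5)
#' @param bubbles_per_frame bubbles rendered per phase-1 frame (default
#'   25)
#' @return list with `stack`, `truth` (theta_b, theta_d, plume angles,
#'   per-frame plume particle positions, phase frame indices) and the
#'   `arc_offset_px` used
#' @export
synth_stone_scene <- function(spec, n_phase1 = 8, n_phase2 = 10,
                              arc_offset_px = 5, bubbles_per_frame = 25) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(spec$stone)) stopf("scene spec has no stone circle")
  set.seed(spec$seed)
  st <- spec$stone
  H <- spec$shape[1]; W <- spec$shape[2]
  base <- blank_canvas(spec)
  # stone silhouette: opaque disc
  base <- render_discs(base, st$row, st$col, 2 * st$radius_px, dark = 0.05,
                       edge = 0.8)
  frames <- vector("list", n_phase1 + n_phase2)
  # phase 1: bubble layer over [0, theta_b], both sides
  for (f in seq_len(n_phase1)) {
    canvas <- base
    if (spec$theta_b > 0) {
      th <- stats::runif(bubbles_per_frame, -spec$theta_b, spec$theta_b)
      rad <- st$radius_px + arc_offset_px + stats::rnorm(bubbles_per_frame, 0, 1)
      rows <- st$row + rad * cos(th)
      cols <- st$col + rad * sin(th)
      canvas <- render_discs(canvas, rows, cols,
                             rep(40e-6 / spec$pixel_scale, bubbles_per_frame))
    }
    frames[[f]] <- add_noise(canvas, spec)
  }
  # phase 2: fragment plumes ejected along the surface normal
  plume_theta <- if (spec$theta_d > 0)
    seq(-spec$theta_d, spec$theta_d, length.out = spec$n_plumes) else numeric(0)
  v_out <- 2.5          # px/frame radial ejection speed
  g_fall <- 0.07        # px/frame^2 downward drift (weak early, grows late)
  particles <- list()
  for (s in seq_len(n_phase2)) {
    canvas <- base
    for (pt in plume_theta) {
      n_hat <- c(cos(pt), sin(pt))   # (row, col) direction, outward
      for (trail in 0:2) {           # short particle trail along the plume
        adv <- v_out * max(s - trail, 0)
        rows <- st$row + (st$radius_px + 1 + adv) * n_hat[1] +
          g_fall * max(s - trail, 0)^2
        cols <- st$col + (st$radius_px + 1 + adv) * n_hat[2]
        canvas <- render_discs(canvas, rows + stats::rnorm(1, 0, 0.3),
                               cols + stats::rnorm(1, 0, 0.3),
                               30e-6 / spec$pixel_scale)
        particles[[length(particles) + 1]] <-
          data.frame(frame = n_phase1 + s, theta = pt, trail = trail,
                     row = rows, col = cols)
      }
    }
    frames[[n_phase1 + s]] <- add_noise(canvas, spec)
  }
  list(stack = image_stack(frames, spec$pixel_scale, spec$frame_rate,
                           spec$depth_of_field),
       truth = list(theta_b = spec$theta_b, theta_d = spec$theta_d,
                    plume_theta = plume_theta,
                    particles = if (length(particles))
                      do.call(rbind, particles) else NULL,
                    phase1 = seq_len(n_phase1),
                    phase2 = n_phase1 + seq_len(n_phase2)),
       arc_offset_px = arc_offset_px)
}
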