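#' Track bubble clouds through an image stack
#'
#' Per-frame cloud masks are built with a coarse threshold plus a
#' morphological dilation that merges the constituent bubbles into one
#' blob per cloud. Cloud centroids are then linked frame-to-frame by
#' nearest-neighbour assignment under a displacement gate (3x the median
#' per-frame displacement unless given). When two or more tracks land on
#' the same component and their previous masks overlap it, a merge event
#' is recorded: the parents terminate and a child track starts with
#' `parents` lineage.
#'
#' @param stack an [image_stack()]
#' @param threshold intensity threshold for cloud pixels (default: Otsu
#'   on the first non-blank frame)
#' @param dilate_px dilation radius in pixels used to fuse the bubbles
#'   of one cloud (default 7)
#' @param gate_m displacement gate in m; default 3x the median linked
#'   displacement estimated in a first pass
#' @param min_area_px minimum component area (default 9)
#' @return list of `cloud_track` objects with fields `id`, `frames`,
#'   `t_s`, `x_m`, `z_m`, `parents`
#' @export
track_clouds <- function(stack, threshold = NULL, dilate_px = 7,
                         gate_m = NULL, min_area_px = 9) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  brush <- EBImage::makeBrush(2 * dilate_px + 1, "disc")
  detect <- function(f) {
    fr <- stack$frames[, , f]
    if (diff(range(fr)) < 1e-3) return(NULL)
    thr <- threshold %||% EBImage::otsu(EBImage::Image(fr), range = range(fr))
    mask <- EBImage::dilate(EBImage::Image((fr < thr) * 1), brush)
    lab <- EBImage::bwlabel(mask)
    nl <- max(lab)
    if (nl == 0) return(NULL)
    comps <- lapply(seq_len(nl), function(l) which(lab == l, arr.ind = TRUE))
    comps <- comps[vapply(comps, nrow, 0L) >= min_area_px]
    if (!length(comps)) return(NULL)
    lapply(comps, function(px) {
      xz <- px_to_xz(mean(px[, 1]), mean(px[, 2]), nrow(fr), stack$pixel_scale)
      list(x = xz[, "x"], z = xz[, "z"],
           cells = px[, 1] + nrow(fr) * (px[, 2] - 1L))
    })
  }
  per_frame <- lapply(seq_len(nf), detect)
  # first pass: estimate the per-frame displacement scale
  if (is.null(gate_m)) {
    disp <- c()
    for (f in 2:nf) {
      a <- per_frame[[f - 1]]; b <- per_frame[[f]]
      if (is.null(a) || is.null(b)) next
      for (cb in b) {
        dd <- vapply(a, function(ca) sqrt((ca$x - cb$x)^2 + (ca$z - cb$z)^2), 0)
        disp <- c(disp, min(dd))
      }
    }
    gate_m <- if (length(disp)) max(3 * stats::median(disp),
                                    3 * stack$pixel_scale) else Inf
  }
  tracks <- list()        # each: id, frames, t, x, z, parents, active, cells
  next_id <- 1L
  active <- integer(0)
  dt <- 1 / stack$frame_rate
  for (f in seq_len(nf)) {
    comps <- per_frame[[f]]
    if (is.null(comps)) { active <- integer(0); next }
    # assign each active track to the component overlapping its previous
    # mask (robust through merges); fall back to nearest-in-gate centroid
    assign <- rep(NA_integer_, length(active))
    for (ai in seq_along(active)) {
      tr <- tracks[[active[ai]]]
      ov <- vapply(comps, function(cb)
        length(intersect(tr$cells, cb$cells)), 0L)
      if (any(ov > 0)) { assign[ai] <- which.max(ov); next }
      dd <- vapply(comps, function(cb)
        sqrt((cb$x - tr$x_m[length(tr$x_m)])^2 +
             (cb$z - tr$z_m[length(tr$z_m)])^2), 0)
      j <- which.min(dd)
      if (length(j) && dd[j] <= gate_m) assign[ai] <- j
    }
    new_active <- integer(0)
    for (j in seq_along(comps)) {
      owners <- active[which(assign == j)]
      cb <- comps[[j]]
      if (length(owners) == 0) {                 # new track
        tracks[[next_id]] <- list(id = next_id, frames = f, t_s = f * dt,
                                  x_m = cb$x, z_m = cb$z,
                                  parents = integer(0), cells = cb$cells)
        new_active <- c(new_active, next_id)
        next_id <- next_id + 1L
      } else if (length(owners) == 1) {          # continuation
        tr <- tracks[[owners]]
        tr$frames <- c(tr$frames, f); tr$t_s <- c(tr$t_s, f * dt)
        tr$x_m <- c(tr$x_m, cb$x); tr$z_m <- c(tr$z_m, cb$z)
        tr$cells <- cb$cells
        tracks[[owners]] <- tr
        new_active <- c(new_active, owners)
      } else {                                   # merge event
        overlap <- vapply(owners, function(o)
          length(intersect(tracks[[o]]$cells, cb$cells)) > 0, TRUE)
        parents <- owners[overlap]
        if (length(parents) < 2) parents <- owners
        tracks[[next_id]] <- list(id = next_id, frames = f, t_s = f * dt,
                                  x_m = cb$x, z_m = cb$z,
                                  parents = sort(parents), cells = cb$cells)
        new_active <- c(new_active, next_id)
        next_id <- next_id + 1L
      }
    }
    active <- new_active
  }
  lapply(tracks, function(tr) {
    tr$cells <- NULL
    class(tr) <- "cloud_track"
    tr
  })
}

#' @export
print.cloud_track <- function(x, ...) {
  cat(sprintf("track %d: frames %d-%d (%d pts)%s\n", x$id, min(x$frames),
              max(x$frames), length(x$frames),
              if (length(x$parents))
                paste0(", merged from {", paste(x$parents, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' Rise speed of a cloud track
#'
#' Least-squares slope of z(t) over the requested window; the cloud rise
#' is linear in time for constant-speed propagation.
#'
#' @param track a `cloud_track`
#' @param window optional index range (e.g. `1:10`) into the track
#'   samples
#' @return uz in m/s (positive upward)
#' @export
rise_speed <- function(track, window = NULL) {
  stopifnot(inherits(track, "cloud_track"))
  t <- track$t_s; z <- track$z_m
  if (!is.null(window)) { t <- t[window]; z <- z[window] }
  if (length(t) < 3 || diff(range(t)) == 0)
    stopf("rise speed needs >= 3 samples spanning a nonzero time window")
  unname(stats::coef(stats::lm(z ~ t))[2])
}

#' Dimensionless rise speed uz* = uz / mean rise speed
#'
#' Reported rounded to 2 decimals, matching the convention of cloud
#' velocity tables.
#'
#' @param uz cloud rise speed in m/s
#' @param mean_uz mean stone-free rise speed in m/s
#' @return uz*, rounded to 2 decimals
#' @examples
#' dimensionless_speed(0.92, 1.32)   # 0.70
#' @export
dimensionless_speed <- function(uz, mean_uz) {
  check_num(uz, "uz"); check_num(mean_uz, "mean_uz", positive = TRUE)
  round(uz / mean_uz, 2)
}

#' Write tracks as CSV (track, frame, t_s, x_mm, z_mm)
#' @param tracks list from [track_clouds()]
#' @param path output path
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track = tr$id, frame = tr$frames, t_s = tr$t_s,
               x_mm = tr$x_m * 1e3, z_mm = tr$z_m * 1e3)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
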