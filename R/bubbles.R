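#' Detect bubbles in a single shadowgraph frame
#'
#' Bright-background shadowgraphs show bubbles as dark blobs. The frame
#' is segmented by an automatic histogram threshold (Otsu inter-class
#' variance maximization), holes are filled, connected dark blobs are
#' labelled and measured. The equivalent-circle diameter follows from
#' the blob area; blobs with circularity 4 pi A / P^2 >= `circ_min` are
#' flagged `individual` (well-resolved single bubbles), the rest are
#' retained as unresolved volumes.
#'
#' @param frame grayscale matrix in \[0, 1\]
#' @param pixel_scale metres per pixel
#' @param circ_min circularity cut for the individual flag (default
#'   0.85)
#' @param min_area_px discard specks below this pixel area (default 4)
#' @return data.frame with columns `x_m`, `z_m` (centroid, z up), `d_m`
#'   (equivalent diameter), `circularity`, `area_px`, `individual`;
#'   empty for blank or saturated frames
#' @export
detect_bubbles <- function(frame, pixel_scale, circ_min = 0.85,
                           min_area_px = 4) {
  stopifnot(is.matrix(frame))
  empty <- data.frame(x_m = numeric(0), z_m = numeric(0), d_m = numeric(0),
                      circularity = numeric(0), area_px = numeric(0),
                      individual = logical(0))
  if (diff(range(frame)) < 1e-3) return(empty)   # blank / saturated
  thr <- EBImage::otsu(EBImage::Image(frame), range = range(frame))
  # noise-only frames put the Otsu split inside the background mode;
  # require real contrast between background and threshold
  if (stats::median(frame) - thr < 0.1) return(empty)
  mask <- frame < thr
  if (!any(mask) || mean(mask) > 0.9) return(empty)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  # watershed on the distance map splits touching bubbles
  lab <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  shape <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(shape) || nrow(shape) == 0) return(empty)
  area <- shape[, "s.area"]
  per <- pmax(shape[, "s.perimeter"], 1)
  keep <- area >= min_area_px
  if (!any(keep)) return(empty)
  area <- area[keep]; per <- per[keep]
  # m.cx is the first-array-index (row) centroid, m.cy the column one
  row_c <- mom[keep, "m.cx"]; col_c <- mom[keep, "m.cy"]
  circ <- pmin(4 * pi * area / per^2, 1)
  xz <- px_to_xz(row_c, col_c, nrow(frame), pixel_scale)
  data.frame(x_m = xz[, "x"], z_m = xz[, "z"],
             d_m = 2 * pixel_scale * sqrt(area / pi),
             circularity = circ, area_px = area,
             individual = circ >= circ_min)
}

#' Bubble census over an image stack
#'
#' Runs [detect_bubbles()] on every frame and stacks the results.
#'
#' @param stack an [image_stack()]
#' @param ... passed to [detect_bubbles()]
#' @return a `bubble_census` data.frame with an extra `frame` column and
#'   the stack metadata attached as attributes
#' @export
bubble_census <- function(stack, ...) {
  stopifnot(inherits(stack, "image_stack"))
  per_frame <- lapply(seq_len(n_frames(stack)), function(f) {
    d <- detect_bubbles(stack$frames[, , f], stack$pixel_scale, ...)
    if (nrow(d)) d$frame <- f else d$frame <- integer(0)
    d
  })
  out <- do.call(rbind, per_frame)
  attr(out, "pixel_scale") <- stack$pixel_scale
  attr(out, "depth_of_field") <- stack$depth_of_field
  attr(out, "fov_m2") <- prod(dim(stack$frames)[1:2]) * stack$pixel_scale^2
  attr(out, "n_frames") <- n_frames(stack)
  class(out) <- c("bubble_census", class(out))
  out
}

#' Bubble size distribution and its peaks
#'
#' Histogram of maximum per-bubble diameters over individual bubbles,
#' with peaks located as local maxima of a kernel-smoothed density.
#' When the census carries a `bubble_id` column (linked detections) the
#' per-bubble maximum diameter is used; otherwise each individual
#' detection counts once.
#'
#' @param census a `bubble_census` (or any data.frame with `d_m` and
#'   `individual`)
#' @param binwidth histogram bin width in m (default 25 um, matching the
#'   smallest resolvable size classes)
#' @param min_bubbles minimum number of individual bubbles (default 10)
#' @return list with `hist` (a [graphics::hist()] object, not plotted),
#'   `peaks_m` (peak diameters, decreasing prominence order) and `d_m`
#'   (the diameters used)
#' @export
size_distribution <- function(census, binwidth = 25e-6, min_bubbles = 10) {
  d <- census$d_m[census$individual]
  if (!is.null(census$bubble_id)) {
    ind <- census$individual
    d <- tapply(census$d_m[ind], census$bubble_id[ind], max)
    d <- as.numeric(d)
  }
  if (length(d) < min_bubbles)
    stopf("too few individual bubbles (%d < %d)", length(d), min_bubbles)
  breaks <- seq(0, max(d) + binwidth, by = binwidth)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  if (length(unique(d)) == 1L)
    return(list(hist = h, peaks_m = unique(d), d_m = d))
  dens <- stats::density(d, bw = binwidth, cut = 1)
  y <- dens$y; n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  loc <- loc[y[loc] > 0.1 * max(y)]          # reject shoulder ripple
  peaks <- dens$x[loc][order(y[loc], decreasing = TRUE)]
  list(hist = h, peaks_m = peaks, d_m = d)
}

#' Bubble number density
#'
#' n = (individual-bubble count per frame) / interrogation volume, in
#' mm^-3. The interrogation volume is the field-of-view area times the
#' depth of field; the depth of field must be provided explicitly (via
#' the stack metadata or `volume_mm3`), it is never defaulted.
#'
#' @param census a `bubble_census`
#' @param volume_mm3 interrogation volume in mm^3; by default computed
#'   from the census attributes (FOV area x depth of field)
#' @return number density in mm^-3 (mean over frames)
#' @export
number_density <- function(census, volume_mm3 = NULL) {
  if (is.null(volume_mm3)) {
    dof <- attr(census, "depth_of_field")
    if (is.null(dof))
      stopf("depth-of-field metadata is required for a number density")
    volume_mm3 <- attr(census, "fov_m2") * dof * 1e9
  }
  check_num(volume_mm3, "volume_mm3", positive = TRUE)
  nf <- attr(census, "n_frames") %||% max(1L, length(unique(census$frame)))
  sum(census$individual) / nf / volume_mm3
}

#' Link census detections across frames into bubble identities
#'
#' Greedy nearest-neighbour linking of detections between consecutive
#' frames within a displacement gate; used to take per-bubble maximum
#' sizes in [size_distribution()].
#'
#' @param census a `bubble_census`
#' @param gate_m maximum frame-to-frame displacement in m (default 5
#'   pixels)
#' @return the census with a `bubble_id` column added
#' @export
link_bubbles <- function(census, gate_m = 5 * attr(census, "pixel_scale")) {
  if (nrow(census) == 0) { census$bubble_id <- integer(0); return(census) }
  census$bubble_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(census$frame))
  prev <- NULL
  for (f in frames) {
    cur <- which(census$frame == f)
    if (is.null(prev)) {
      census$bubble_id[cur] <- seq.int(next_id, next_id + length(cur) - 1L)
      next_id <- next_id + length(cur)
    } else {
      taken <- logical(length(prev))
      for (i in cur) {
        dd <- sqrt((census$x_m[prev] - census$x_m[i])^2 +
                   (census$z_m[prev] - census$z_m[i])^2)
        dd[taken] <- Inf
        j <- which.min(dd)
        if (length(j) && dd[j] <= gate_m) {
          census$bubble_id[i] <- census$bubble_id[prev[j]]
          taken[j] <- TRUE
        } else {
          census$bubble_id[i] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    prev <- cur
  }
  census
}

#' Write a census as CSV (frame, x_mm, z_mm, d_um, circ, individual)
#' @param census a `bubble_census`
#' @param path output path
#' @export
write_census_csv <- function(census, path) {
  utils::write.csv(data.frame(frame = census$frame,
                              x_mm = census$x_m * 1e3,
                              z_mm = census$z_m * 1e3,
                              d_um = census$d_m * 1e6,
                              circ = census$circularity,
                              individual = census$individual),
                   path, row.names = FALSE)
  invisible(path)
}
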