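#' Shadowgraph image stack
#'
#' A sequence of grayscale frames (values in \[0, 1\], bright background,
#' dark bubbles) with pixel scale and frame rate metadata. The image
#' convention is row 1 = top of frame; the acoustic beam travels upward,
#' so the physical z coordinate increases with decreasing row index:
#' z = (nrow - row + 0.5) * pixel_scale, x = (col - 0.5) * pixel_scale.
#'
#' @param frames 3-D array `nrow x ncol x n_frames`, or a list of equal
#'   sized matrices
#' @param pixel_scale metres per pixel
#' @param frame_rate frames per second (Hz)
#' @param depth_of_field optional optical depth of field in m (required
#'   for volumetric number densities)
#' @return an object of class `image_stack`
#' @export
image_stack <- function(frames, pixel_scale, frame_rate,
                        depth_of_field = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stopf("all frames must have the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) == 2) frames <- array(frames, dim = c(dim(frames), 1))
  if (length(dim(frames)) != 3) stopf("frames must be a H x W x n array")
  check_num(pixel_scale, "pixel_scale", positive = TRUE)
  check_num(frame_rate, "frame_rate", positive = TRUE)
  if (!is.null(depth_of_field))
    check_num(depth_of_field, "depth_of_field", positive = TRUE)
  structure(list(frames = frames, pixel_scale = pixel_scale,
                 frame_rate = frame_rate, depth_of_field = depth_of_field),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, %.1f um/px, %.0f kHz\n",
              d[3], d[1], d[2], x$pixel_scale * 1e6, x$frame_rate / 1e3))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

# pixel (row, col) -> physical (x, z) in metres, z up
px_to_xz <- function(row, col, nrow_img, pixel_scale) {
  cbind(x = (col - 0.5) * pixel_scale,
        z = (nrow_img - row + 0.5) * pixel_scale)
}

#' Minimum intensity projection (MinIP)
#'
#' Per-pixel minimum across a frame range: the reconstructed pixel
#' intensity is Ir(i, j) = min over frames of I(i, j). Dark transient
#' features (bubbles, falling fragments) from every frame are compiled
#' into a single image.
#'
#' @param stack an [image_stack()]
#' @param frames frame indices to project (default: all)
#' @return a matrix, the projected image
#' @export
minip <- function(stack, frames = seq_len(n_frames(stack))) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(frames) < 1) stopf("empty frame range")
  if (any(frames < 1 | frames > n_frames(stack))) stopf("frame index out of range")
  Reduce(pmin, lapply(frames, function(f) stack$frames[, , f]))
}

#' Write an image stack as multi-page TIFF plus a sidecar metadata file
#' @param stack an [image_stack()]
#' @param path output TIFF path; metadata goes to `path`.json
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(f)
    pmin(pmax(stack$frames[, , f], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_scale_um = stack$pixel_scale * 1e6,
                            frame_rate_hz = stack$frame_rate,
                            depth_of_field_mm =
                              if (is.null(stack$depth_of_field)) NULL
                              else stack$depth_of_field * 1e3),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack()] (or any multi-page
#' TIFF with a sidecar metadata JSON)
#' @param path TIFF path; metadata is read from `path`.json unless
#'   `meta` is given
#' @param meta optional metadata path
#' @return an [image_stack()]
#' @export
read_stack <- function(path, meta = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  image_stack(pages, pixel_scale = md$pixel_scale_um * 1e-6,
              frame_rate = md$frame_rate_hz,
              depth_of_field = if (is.null(md$depth_of_field_mm)) NULL
              else md$depth_of_field_mm * 1e-3)
}
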