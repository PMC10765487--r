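#' Normalized intensity profile along an arc offset from the stone
#' surface
#'
#' Samples the image along a circular arc at `offset_px` outside the
#' stone silhouette, by bilinear interpolation, as a function of the
#' polar angle theta measured from the vertical (beam) axis at the
#' proximal (bottom) pole. Both azimuthal sides of the axisymmetric
#' image are averaged. The intensity is normalized to \[0, 1\] by the
#' min/max along the arc; dips (I* toward 0) mark bubbles or fragments
#' on the optical path.
#'
#' @param image grayscale matrix
#' @param circle list with `row`, `col`, `radius_px`: the stone circle
#'   in image coordinates (row 1 = top; the proximal pole is at
#'   `row + radius_px`)
#' @param offset_px radial arc offset from the surface in pixels
#'   (default 3)
#' @param n_theta samples over \[0, pi/2\] (default 181)
#' @return an object of class `surface_profile` with `theta` (rad) and
#'   `I_star`
#' @export
surface_intensity_profile <- function(image, circle, offset_px = 3,
                                      n_theta = 181) {
  stopifnot(is.matrix(image))
  theta <- seq(0, pi / 2, length.out = n_theta)
  rad <- circle$radius_px + offset_px
  # proximal pole points down the image: theta=0 at (row + rad)
  rows <- circle$row + rad * cos(theta)
  cols_p <- circle$col + rad * sin(theta)
  cols_m <- circle$col - rad * sin(theta)
  inside <- function(rr, cc)
    rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
  ok <- inside(rows, cols_p) & inside(rows, cols_m)
  if (!all(ok)) {
    warning("arc leaves the image bounds; profile clipped", call. = FALSE)
    theta <- theta[ok]; rows <- rows[ok]
    cols_p <- cols_p[ok]; cols_m <- cols_m[ok]
  }
  if (!length(theta)) stopf("arc lies entirely outside the image")
  I <- (bilinear_sample(image, rows, cols_p) +
        bilinear_sample(image, rows, cols_m)) / 2
  rng <- range(I)
  I_star <- if (diff(rng) < 1e-12) rep(1, length(I)) else (I - rng[1]) / diff(rng)
  structure(list(theta = theta, I_star = I_star), class = "surface_profile")
}

bilinear_sample <- function(img, rows, cols) {
  r0 <- pmin(pmax(floor(rows), 1), nrow(img) - 1)
  c0 <- pmin(pmax(floor(cols), 1), ncol(img) - 1)
  fr <- rows - r0; fc <- cols - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Cap edge angle from a surface intensity profile
#'
#' The occupied polar cap (bubble layer or fragment plumes) darkens the
#' arc; its edge is the largest angle where the normalized intensity
#' falls below the dip threshold. A flat bright profile yields a
#' zero-extent cap.
#'
#' @param profile a `surface_profile`
#' @param dip_threshold I* level below which the arc counts as occupied
#'   (default 0.5)
#' @param stone_radius hemisphere radius in m, to build the
#'   [cap_measure()]
#' @param source_kind `"bubble-layer"` (theta_b) or `"fragments"`
#'   (theta_d)
#' @return a [cap_measure()]
#' @export
cap_angle_from_profile <- function(profile, dip_threshold = 0.5,
                                   stone_radius, source_kind = "bubble-layer") {
  stopifnot(inherits(profile, "surface_profile"))
  below <- which(profile$I_star < dip_threshold)
  theta <- if (length(below)) max(profile$theta[below]) else 0
  cap_measure(theta, stone_radius, source_kind)
}

#' Write a surface profile as CSV (theta_rad, I_star)
#' @param profile a `surface_profile`
#' @param path output path
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(theta_rad = profile$theta,
                              I_star = profile$I_star),
                   path, row.names = FALSE)
  invisible(path)
}
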