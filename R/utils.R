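#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_num <- function(x, name, positive = FALSE, nonneg = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)))
    stopf("'%s' must be a finite numeric of length %d", name, len)
  if (positive && any(x <= 0)) stopf("'%s' must be > 0", name)
  if (nonneg && any(x < 0)) stopf("'%s' must be >= 0", name)
  invisible(x)
}

#' Locate the half-maximum crossing of a sampled profile by linear
#' interpolation
#'
#' Scans outward from the index of the maximum until the profile first
#' drops below `level`, then interpolates the crossing coordinate.
#'
#' @param x coordinate grid (monotone increasing)
#' @param y sampled non-negative profile
#' @param level threshold (same units as `y`)
#' @param from index to start from (default: argmax of `y`)
#' @param direction +1 to scan toward larger x, -1 toward smaller x
#' @return the interpolated crossing coordinate
#' @keywords internal
half_crossing <- function(x, y, level, from = which.max(y), direction = +1) {
  n <- length(x)
  i <- from
  repeat {
    j <- i + direction
    if (j < 1L || j > n)
      stopf("half-maximum level not bracketed on the grid (direction %+d)",
            direction)
    if (y[j] < level) {
      # linear interpolation between samples i and j
      return(x[i] + (level - y[i]) * (x[j] - x[i]) / (y[j] - y[i]))
    }
    i <- j
  }
}

#' Quadratic-interpolated location of a discrete maximum
#' @keywords internal
argmax_quadratic <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y))
    stopf("maximum lies on the grid boundary; extend the grid")
  # three-point parabola through (x[i-1..i+1], y[i-1..i+1]); grid may be uneven
  x0 <- x[i - 1L]; x1 <- x[i]; x2 <- x[i + 1L]
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  d <- (x0 - x1) * (x0 - x2) * (x1 - x2)
  a <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / d
  b <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / d
  if (a >= 0) return(x1)  # degenerate curvature: fall back to grid argmax
  -b / (2 * a)
}

linear_interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}
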