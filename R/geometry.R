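#' Cumulative arc length of a 2D polyline
#'
#' @param points numeric matrix with two columns (x, y) in micrometers.
#' @return numeric vector of cumulative arc lengths, starting at 0.
#' @keywords internal
polyline_arclength <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("polyline needs at least one point")
  if (nrow(points) == 1L) return(0)
  d <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(d))
}

#' Interpolate a point at a given arc length along a polyline
#'
#' @param points two-column matrix of vertices (um).
#' @param s arc length(s) from the first vertex (um); clamped to the
#'   polyline's range.
#' @return matrix of interpolated points, one row per `s`.
#' @keywords internal
point_at_arclength <- function(points, s) {
  points <- as.matrix(points)
  cs <- polyline_arclength(points)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  x <- stats::approx(cs, points[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cs, points[, 2], xout = s, ties = "ordered")$y
  cbind(x = x, y = y)
}

#' Unit tangent and normal of a centerline at an arc-length position
#'
#' The tangent is estimated by central differences on the polyline
#' (one-sided at the ends); the normal is the tangent rotated by 90
#' degrees counter-clockwise. This is the "perpendicular to the center
#' axis" direction along which line scans are taken.
#'
#' @param points two-column matrix of centerline vertices (um).
#' @param s arc length from the first vertex (um), within the segment.
#' @param h finite-difference half-step (um); default 0.1.
#' @return list with unit `tangent` and `normal` (length-2 vectors).
#' @export
#' @examples
#' seg <- cbind(x = c(0, 10), y = c(0, 0))
#' tangent_and_normal(seg, 5)$normal  # (0, 1)
tangent_and_normal <- function(points, s, h = 0.1) {
  points <- as.matrix(points)
  cs <- polyline_arclength(points)
  total <- cs[length(cs)]
  if (total <= 0) stop("degenerate (zero-length) segment")
  if (length(s) != 1L || is.na(s) || s < 0 || s > total)
    stop("arc position must lie within [0, ", format(total), "]")
  h <- min(h, total / 2)
  s0 <- max(0, s - h)
  s1 <- min(total, s + h)
  p <- point_at_arclength(points, c(s0, s1))
  v <- unname(p[2, ] - p[1, ])
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate tangent at s = ", format(s))
  tangent <- v / nv
  list(tangent = tangent, normal = c(-tangent[2], tangent[1]))
}
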