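# Polygon primitives shared by the isotherm and lesion-metric modules.
# Vertices are k x 2 matrices of (x, y) in pixel coordinates (origin
# top-left, pixel centers at integers). Closed polygons repeat the first
# vertex as the last row.

.poly_vertices <- function(poly) {
  if (inherits(poly, "iso_contour")) poly <- poly$vertices
  if (!is.matrix(poly) || ncol(poly) != 2L)
    stop("polygon must be a k x 2 matrix of (x, y) vertices", call. = FALSE)
  poly
}

.poly_is_closed <- function(v, tol = 1e-9) {
  nrow(v) >= 2L && all(abs(v[1L, ] - v[nrow(v), ]) <= tol)
}

# distinct vertex rows of a closed polygon (closing duplicate dropped)
.poly_open <- function(v) v[-nrow(v), , drop = FALSE]

#' Even-odd (ray casting) point-in-polygon test
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param poly closed polygon: k x 2 vertex matrix or [iso_contour()].
#' @return Logical vector; points exactly on an edge have an unspecified
#'   but deterministic value (callers needing strict interiors exclude
#'   on-edge points via [dist_to_polygon()]).
#' @export
point_in_polygon <- function(px, py, poly) {
  v <- .poly_vertices(poly)
  vx <- v[, 1L]; vy <- v[, 2L]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Minimum distance from points to a polygon outline
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances (0 for points on the outline).
#' @export
dist_to_polygon <- function(px, py, poly) {
  v <- .poly_vertices(poly)
  n <- nrow(v)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    ax <- v[i, 1L]; ay <- v[i, 2L]
    bx <- v[i + 1L, 1L]; by <- v[i + 1L, 2L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
  }
  sqrt(d2)
}

#' Polygon centroid (area-weighted; vertex mean for degenerate polygons)
#'
#' @inheritParams point_in_polygon
#' @return Numeric `c(x, y)`.
#' @export
polygon_centroid <- function(poly) {
  v <- .poly_vertices(poly)
  if (!.poly_is_closed(v)) v <- rbind(v, v[1L, ])
  x <- v[, 1L]; y <- v[, 2L]
  n <- nrow(v)
  cross <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a2 <- sum(cross)
  if (abs(a2) < 1e-12) {
    vv <- .poly_open(v)
    return(c(mean(vv[, 1L]), mean(vv[, 2L])))
  }
  c(sum((x[-n] + x[-1L]) * cross) / (3 * a2),
    sum((y[-n] + y[-1L]) * cross) / (3 * a2))
}
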