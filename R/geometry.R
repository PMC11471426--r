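# Planar geometry helpers (km coordinate system). No geodesy: the synthetic
# grids live in an equal-area plane, so Euclidean distance is exact.

#' Test whether points fall inside a polygon
#'
#' Ray-casting test; points exactly on an edge count as inside.
#'
#' @param x,y point coordinates.
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- validate_polygon(poly)
  nv <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    on_edge <- on_edge | point_segment_distance(x, y, xi, yi, xj, yj) < 1e-12
    j <- i
  }
  inside | on_edge
}

#' Distance from points to a segment
#' @param x,y point coordinates.
#' @param x1,y1,x2,y2 segment endpoints.
#' @return numeric distances.
#' @keywords internal
point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2))
  sqrt((x - x1 - t * dx)^2 + (y - y1 - t * dy)^2)
}

#' Distance from points to a polygon
#'
#' Zero for points inside or on the boundary; otherwise the minimum Euclidean
#' distance to any edge.
#'
#' @param x,y point coordinates (km).
#' @param poly two-column vertex matrix.
#' @return numeric distances (km).
#' @export
point_polygon_distance <- function(x, y, poly) {
  poly <- validate_polygon(poly)
  nv <- nrow(poly)
  d <- rep(Inf, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    d <- pmin(d, point_segment_distance(x, y, poly[j, 1], poly[j, 2],
                                        poly[i, 1], poly[i, 2]))
    j <- i
  }
  d[point_in_polygon(x, y, poly)] <- 0
  d
}

validate_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || anyNA(poly) || any(!is.finite(poly))) {
    stop("invalid polygon geometry: need a finite 2-column matrix with >= 3 vertices")
  }
  poly
}

#' Convex hull polygon of a point set
#' @param x,y point coordinates.
#' @return two-column vertex matrix in counter-clockwise order.
#' @export
convex_hull <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points for a hull")
  h <- grDevices::chull(x, y)
  cbind(x = x[h], y = y[h])
}
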