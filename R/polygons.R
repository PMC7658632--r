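# Planar polygon primitives used by the region and hex-grid code.
#
# Polygons live in the image coordinate frame (micrometres, y increasing
# downward).  Every statistic downstream is translation/rotation invariant,
# so only consistency matters.  A "ring" is an n x 2 numeric matrix of
# vertices, open (the closing edge is implicit).  A "polygon" is a list of
# rings: the first is the outer boundary, any further rings are holes
# (even-odd semantics).

#' Signed area of a ring (shoelace formula)
#'
#' @param ring n x 2 matrix of vertices, open ring.
#' @return Signed area in the square of the coordinate unit; sign encodes
#'   orientation.
#' @keywords internal
ring_area_signed <- function(ring) {
  x <- ring[, 1L]
  y <- ring[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_area_signed(ring))

#' Area of a polygon with holes, in the square of the coordinate unit
#' @keywords internal
polygon_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  outer <- ring_area(rings[[1L]])
  holes <- if (length(rings) > 1L) sum(vapply(rings[-1L], ring_area, 0)) else 0
  max(outer - holes, 0)
}

# Drop a repeated closing vertex if present; validate shape.
as_ring <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop("ring must have two coordinate columns")
  if (!all(is.finite(m))) stop("ring contains non-finite coordinates")
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop("ring must have at least 3 distinct vertices")
  m
}

#' Even-odd point-in-ring test, vectorized over points
#'
#' Crossing-number test; points exactly on an edge follow the half-open
#' convention of the ray casting (consistent, not symmetric).
#' @keywords internal
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Even-odd membership in a polygon (outer ring minus holes)
#' @keywords internal
points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

#' Membership in a union of polygons
#' @keywords internal
points_in_any_polygon <- function(px, py, polygons) {
  inside <- rep(FALSE, length(px))
  for (rings in polygons) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- points_in_polygon(px[todo], py[todo], rings)
  }
  inside
}

#' Minimum distance from points to the edges of a set of rings
#' @keywords internal
dist_to_rings <- function(px, py, rings) {
  best <- rep(Inf, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      ax <- ring[j, 1L]; ay <- ring[j, 2L]
      bx <- ring[i, 1L]; by <- ring[i, 2L]
      dx <- bx - ax; dy <- by - ay
      len2 <- dx * dx + dy * dy
      if (len2 == 0) {
        d2 <- (px - ax)^2 + (py - ay)^2
      } else {
        t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
        d2 <- (px - ax - t * dx)^2 + (py - ay - t * dy)^2
      }
      best <- pmin(best, d2)
      j <- i
    }
  }
  sqrt(best)
}

# Orient a ring counter-clockwise in the mathematical sense (positive signed
# area).  Sutherland-Hodgman below assumes a CCW convex clip ring.
orient_ccw <- function(ring) {
  if (ring_area_signed(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Clip a ring by a convex ring (Sutherland-Hodgman)
#'
#' The clip ring must be convex; the subject ring may be any simple polygon.
#' Returns an m x 2 matrix (possibly with 0 rows).  Degenerate collinear
#' output vertices are harmless for area computation.
#' @keywords internal
clip_ring_convex <- function(subject, clip) {
  clip <- orient_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    # signed distance proxy: >= 0 means inside the half-plane left of a->b
    side <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1L], 1L)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (i in seq_len(n)) {
      j <- nxt[i]
      si <- side[i]; sj <- side[j]
      if (si >= 0) {
        keep_x <- c(keep_x, out[i, 1L]); keep_y <- c(keep_y, out[i, 2L])
      }
      if ((si >= 0) != (sj >= 0)) {
        t <- si / (si - sj)
        keep_x <- c(keep_x, out[i, 1L] + t * (out[j, 1L] - out[i, 1L]))
        keep_y <- c(keep_y, out[i, 2L] + t * (out[j, 2L] - out[i, 2L]))
      }
    }
    out <- cbind(keep_x, keep_y)
  }
  if (nrow(out) > 0L) dimnames(out) <- NULL
  out
}

#' Area of the intersection of a polygon (with holes) and a convex ring
#' @keywords internal
polygon_convex_intersection_area <- function(rings, clip) {
  if (length(rings) == 0L) return(0)
  a <- 0
  outer_clip <- clip_ring_convex(rings[[1L]], clip)
  if (nrow(outer_clip) >= 3L) a <- ring_area(outer_clip)
  if (length(rings) > 1L) {
    for (hole in rings[-1L]) {
      hc <- clip_ring_convex(hole, clip)
      if (nrow(hc) >= 3L) a <- a - ring_area(hc)
    }
  }
  max(a, 0)
}

# Axis-aligned bounding box over a list of rings.
rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1L]))
  ys <- unlist(lapply(rings, function(r) r[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

is_convex_ring <- function(ring) {
  ring <- orient_ccw(ring)
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1L], 1L)
  nx2 <- nxt[nxt]
  ex <- ring[nxt, 1L] - ring[, 1L]
  ey <- ring[nxt, 2L] - ring[, 2L]
  fx <- ring[nx2, 1L] - ring[nxt, 1L]
  fy <- ring[nx2, 2L] - ring[nxt, 2L]
  all(ex * fy - ey * fx >= -1e-9 * max(abs(c(ex, ey, fx, fy)))^2)
}

#' Numeric area of an implicitly defined region by grid integration
#'
#' @param member function(px, py) -> logical membership
#' @param bbox c(xmin, ymin, xmax, ymax)
#' @param res grid step in coordinate units
#' @return area in squared coordinate units
#' @keywords internal
grid_area <- function(member, bbox, res) {
  xs <- seq(bbox[1L] + res / 2, bbox[3L], by = res)
  ys <- seq(bbox[2L] + res / 2, bbox[4L], by = res)
  total <- 0
  # row-chunked to bound memory on fine grids
  chunk <- max(1L, floor(4e6 / length(xs)))
  i <- 1L
  while (i <= length(ys)) {
    yy <- ys[i:min(i + chunk - 1L, length(ys))]
    px <- rep(xs, times = length(yy))
    py <- rep(yy, each = length(xs))
    total <- total + sum(member(px, py))
    i <- i + chunk
  }
  total * res * res
}
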