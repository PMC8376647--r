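# Plain polygon geometry on base-level pixel coordinates.
#
# Convention used throughout the package: 0-based coordinates, x rightward,
# y downward, rectangles half-open [x, x + w) x [y, y + h). Polygons are
# n x 2 matrices of (x, y) vertices, implicitly closed.

#' Signed and absolute polygon area
#'
#' Shoelace formula. The sign depends on vertex orientation; most callers
#' want the absolute area.
#'
#' @param poly Numeric matrix with columns x, y (>= 3 rows).
#' @return Absolute enclosed area in square pixels.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) {
    abort("a polygon needs an n x 2 matrix with n >= 3 vertices", "ihctriage_validation_error")
  }
  storage.mode(poly) <- "double"
  poly
}

# Drop exactly repeated consecutive vertices (and a repeated closing vertex).
clean_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2L) {
    keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-12)
    poly <- poly[keep, , drop = FALSE]
    n <- nrow(poly)
    if (n >= 2L && all(abs(poly[1, ] - poly[n, ]) < 1e-12)) {
      poly <- poly[-n, , drop = FALSE]
    }
  }
  poly
}

# Proper segment-crossing test between non-adjacent edges. Shared endpoints
# between adjacent edges are not self-intersections.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_self_intersects <- function(poly) {
  poly <- clean_polygon(poly)
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(poly[idx[i, 1], ], poly[idx[i, 2], ],
                         poly[idx[j, 1], ], poly[idx[j, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland–Hodgman clipping against the half-open rectangle
#' `[x, x + w) x [y, y + h)` (treated as a closed box for the continuous
#' clip; the half-open convention matters only for pixel indexing).
#'
#' @param poly n x 2 vertex matrix.
#' @param rect Numeric `c(x, y, w, h)`.
#' @return Clipped vertex matrix (possibly with 0 rows).
#' @export
clip_polygon_rect <- function(poly, rect) {
  poly <- as_polygon(poly)
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[1] + rect[3]; y1 <- rect[2] + rect[4]
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= x0, function(p, q) ix(p, q, x0, 1))
  pts <- clip_edge(pts, function(p) p[1] <= x1, function(p, q) ix(p, q, x1, 1))
  pts <- clip_edge(pts, function(p) p[2] >= y0, function(p, q) ix(p, q, y0, 2))
  pts <- clip_edge(pts, function(p) p[2] <= y1, function(p, q) ix(p, q, y1, 2))
  pts
}

# Area of polygon-rectangle overlap in square pixels.
polygon_rect_overlap <- function(poly, rect) {
  clipped <- clip_polygon_rect(poly, rect)
  if (nrow(clipped) < 3L) return(0)
  polygon_area(clipped)
}
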