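# Planar polygon primitives.
#
# Polygons are n x 2 numeric matrices of vertices (x, y) in micrometres,
# open rings (last vertex != first), oriented counter-clockwise in a
# y-downward image frame after .ensure_ccw(). All routines assume simple
# polygons; repair is the caller's responsibility.

.poly_signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  0.5 * sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])
}

.poly_area <- function(xy) abs(.poly_signed_area(xy))

.poly_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cross <- xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]
  a <- sum(cross) / 2
  if (abs(a) < .AREA_TOL) return(colMeans(xy))
  c(sum((xy[, 1L] + xy[j, 1L]) * cross), sum((xy[, 2L] + xy[j, 2L]) * cross)) / (6 * a)
}

# Standard orientation: positive signed area (counter-clockwise for the
# stored vertex order; interior on the left of each directed edge).
.ensure_ccw <- function(xy) {
  if (.poly_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Drop a repeated closing vertex and consecutive duplicates.
.clean_ring <- function(xy, tol = 1e-12) {
  xy <- as.matrix(xy)
  if (nrow(xy) > 1L && all(abs(xy[1L, ] - xy[nrow(xy), ]) < tol)) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  if (nrow(xy) > 1L) {
    d <- rowSums(abs(xy - xy[c(2:nrow(xy), 1L), , drop = FALSE]))
    if (any(d < tol)) xy <- xy[d >= tol, , drop = FALSE]
  }
  xy
}

# Clip a polygon by the half-plane d >= 0 where d holds the signed distance
# (any positive multiple) of each vertex. Sutherland-Hodgman step.
.clip_halfplane <- function(xy, d) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  j <- c(seq_len(n)[-1L], 1L)
  di <- d
  dj <- d[j]
  keep <- di >= 0
  cross <- keep != (dj >= 0)
  m <- keep + cross
  total <- sum(m)
  if (total == 0L) return(xy[0L, , drop = FALSE])
  t <- numeric(n)
  cs <- which(cross)
  t[cs] <- di[cs] / (di[cs] - dj[cs])
  ox <- numeric(total)
  oy <- numeric(total)
  pos <- cumsum(m) - m + 1L
  vs <- which(keep)
  ox[pos[vs]] <- xy[vs, 1L]
  oy[pos[vs]] <- xy[vs, 2L]
  ox[pos[cs] + keep[cs]] <- xy[cs, 1L] + t[cs] * (xy[j[cs], 1L] - xy[cs, 1L])
  oy[pos[cs] + keep[cs]] <- xy[cs, 2L] + t[cs] * (xy[j[cs], 2L] - xy[cs, 2L])
  cbind(ox, oy, deparse.level = 0L)
}

# Intersection of a polygon with the axis-aligned rectangle
# [x0, x1] x [y0, y1]; returns the clipped polygon (possibly empty).
.clip_rect <- function(xy, x0, y0, x1, y1) {
  xy <- .clip_halfplane(xy, xy[, 1L] - x0)
  if (nrow(xy) == 0L) return(xy)
  xy <- .clip_halfplane(xy, x1 - xy[, 1L])
  if (nrow(xy) == 0L) return(xy)
  xy <- .clip_halfplane(xy, xy[, 2L] - y0)
  if (nrow(xy) == 0L) return(xy)
  .clip_halfplane(xy, y1 - xy[, 2L])
}

# Area of polygon-rectangle intersection. The workhorse of the spatial join.
.rect_clip_area <- function(xy, x0, y0, x1, y1) {
  clipped <- .clip_rect(xy, x0, y0, x1, y1)
  if (nrow(clipped) < 3L) return(0)
  .poly_area(clipped)
}

# Vectorised even-odd ray-casting point-in-polygon test; boundary points may
# fall on either side (measure-zero set, irrelevant for area bookkeeping).
.points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  xj <- xy[n, 1L]
  yj <- xy[n, 2L]
  for (i in seq_len(n)) {
    xi <- xy[i, 1L]
    yi <- xy[i, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi
    yj <- yi
  }
  inside
}

# Outward mitre offset of a simple CCW polygon by `dist` >= 0: each edge is
# translated along its outward normal and consecutive offset edge lines are
# intersected to form the new vertex (square joins). Near-parallel joins
# fall back to translating the shared vertex along the vertex normal.
.mitre_offset <- function(xy, dist) {
  if (dist == 0) return(xy)
  xy <- .ensure_ccw(xy)
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  ex <- xy[nxt, 1L] - xy[, 1L]
  ey <- xy[nxt, 2L] - xy[, 2L]
  len <- sqrt(ex^2 + ey^2)
  # outward normal for CCW in a y-down frame: (ey, -ex) / |e|
  nx <- ey / len
  ny <- -ex / len
  # offset line i passes through p_i + dist * n_i with direction (ex, ey)
  ax <- xy[, 1L] + dist * nx
  ay <- xy[, 2L] + dist * ny
  prv <- c(n, seq_len(n - 1L))
  out <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    p <- prv[i]
    den <- ex[p] * ey[i] - ey[p] * ex[i]
    if (abs(den) < 1e-12) {
      out[i, ] <- c(xy[i, 1L] + dist * nx[i], xy[i, 2L] + dist * ny[i])
    } else {
      t <- ((ax[i] - ax[p]) * ey[i] - (ay[i] - ay[p]) * ex[i]) / den
      out[i, ] <- c(ax[p] + t * ex[p], ay[p] + t * ey[p])
    }
  }
  out
}

# O(n^2) simplicity check: any two non-adjacent edges properly intersecting.
.is_self_intersecting <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  j <- c(2:n, 1L)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (a in seq_len(n - 2L)) {
    for (b in (a + 2L):n) {
      if (a == 1L && b == n) next
      if (seg_int(xy[a, ], xy[j[a], ], xy[b, ], xy[j[b], ])) return(TRUE)
    }
  }
  FALSE
}
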