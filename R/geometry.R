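# Planar geometry primitives for the land-cover map: polygon areas,
# half-plane clipping (used both for Voronoi cell construction and for
# clipping cells to the classification disc) and point-in-polygon tests.
# All coordinates are planar metres; polygons are two-column matrices of
# vertices without a repeated closing vertex.

# Shoelace area (absolute value, vertex order irrelevant).
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Clip a polygon against the half-plane nx*x + ny*y <= d
# (Sutherland-Hodgman step). Returns a matrix, possibly with 0 rows.
clip_halfplane <- function(poly, nx, ny, d) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(matrix(numeric(0), ncol = 2))
  side <- nx * poly[, 1] + ny * poly[, 2] - d
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pin <- side[i] <= 0
    qin <- side[j] <= 0
    if (pin) out <- rbind(out, poly[i, ])
    if (xor(pin, qin)) {
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Clip a polygon against a convex counter-clockwise polygon.
clip_convex <- function(poly, clip) {
  m <- nrow(clip)
  out <- poly
  for (k in seq_len(m)) {
    if (nrow(out) == 0) break
    k2 <- if (k == m) 1L else k + 1L
    x1 <- clip[k, 1]; y1 <- clip[k, 2]
    x2 <- clip[k2, 1]; y2 <- clip[k2, 2]
    # inside = left of directed edge (CCW polygon)
    nx <- y2 - y1
    ny <- -(x2 - x1)
    out <- clip_halfplane(out, nx, ny, nx * x1 + ny * y1)
  }
  out
}

# Regular n-gon inscribed in a circle, counter-clockwise.
disc_polygon <- function(centre, radius, n = 128L) {
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang))
}

# Vectorised even-odd (crossing number) point-in-polygon test; points on the
# boundary are counted as inside so that the caller's first-polygon-wins
# tie-break is deterministic.
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # collinear with the edge and within its bounding box
    d2 <- (xj - xi)^2 + (yj - yi)^2
    if (d2 > 0) {
      cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
      tol <- eps * max(1, sqrt(d2))
      within <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
        py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
      on_edge <- on_edge | (abs(cr) <= tol * sqrt(d2) & within)
    }
    j <- i
  }
  inside | on_edge
}
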