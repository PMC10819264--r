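# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive each quantity by a different route than the
# package implementation.

# crossing number as the brute-force count of 0->1 transitions around the
# cyclic 8-neighborhood
cn_oracle <- function(neigh) {
  p <- as.numeric(neigh[cbind(c(1, 2, 3, 3, 3, 2, 1, 1),
                              c(1, 1, 1, 2, 3, 3, 3, 2))] != 0)
  q <- c(p[-1], p[1])
  sum(p == 0 & q == 1)
}

# build a 3x3 neighborhood (centre set) from the 8 cyclic neighbour bits
neigh_from_bits <- function(bits) {
  m <- matrix(0, 3, 3)
  m[2, 2] <- 1
  m[cbind(c(1, 2, 3, 3, 3, 2, 1, 1),
          c(1, 1, 1, 2, 3, 3, 3, 2))] <- bits
  m
}

# hull vertex set via the all-pairs half-plane test: directed edge (i, j)
# is a hull edge iff every other point lies strictly left of it or on it
hull_vertices_oracle <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  verts <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cr[-c(i, j)] > 1e-12)) verts[c(i, j)] <- TRUE
  }
  pts[verts, , drop = FALSE]
}

# point-in-polygon by ray casting (horizontal ray to +x)
point_in_poly_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# min distance from points to the boundary of a polygon, by direct
# point-to-segment projection
dist_to_boundary_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    t <- ((px - a[1]) * abx + (py - a[2]) * aby) / (abx^2 + aby^2)
    t <- pmin(1, pmax(0, t))
    d <- pmin(d, sqrt((px - a[1] - t * abx)^2 + (py - a[2] - t * aby)^2))
  }
  d
}

# random valid polygon around the origin: n vertices at distinct angles
# with all gaps < pi (rejection sampling)
random_valid_polygon <- function(n = 5, rmin = 20, rmax = 80) {
  repeat {
    ang <- sort(stats::runif(n, 0, 2 * pi))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    if (max(gaps) < pi && min(gaps) > 1e-3) break
  }
  r <- stats::runif(n, rmin, rmax)
  cbind(r * cos(ang), r * sin(ang))
}

# scattered minutia set as a plain data frame builder for fixtures
fixture_set <- function(x, y, type = NULL, extent = 300) {
  if (is.null(type)) type <- rep(c("T", "B"), length.out = length(x))
  minutia_set(x, y, type, width = extent, height = extent)
}
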