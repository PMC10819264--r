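# ---- model parameters ----

#' Polygon model parameters
#'
#' @param n number of polygon vertices (>= 3); the feature vector has
#'   length `2n` (n edge lengths + n central angles). Default 5, the best
#'   configuration reported for the method.
#' @param r_step radius increment in pixels of the neighbour search
#'   (default 5).
#' @param r_max maximum search radius in pixels (default 120).
#' @return a named list of class `model_params`.
#' @export
model_params <- function(n = 5L, r_step = 5, r_max = 120) {
  n <- as.integer(n)
  stopifnot(n >= 3, r_step > 0, r_step <= r_max)
  structure(list(n = n, r_step = r_step, r_max = r_max),
            class = "model_params")
}

# quadrant of (dx, dy) around the reference, axis boundaries assigned to
# the lower-index quadrant: Q1 (+,+], Q2 (-,+], Q3 (-,-], Q4 (+,-)
quadrant_of <- function(dx, dy) {
  ang <- atan2(dy, dx) %% (2 * pi)
  findInterval(ang, c(pi / 2, pi, 3 * pi / 2), left.open = TRUE) + 1L
}

#' Find the neighbour set used to build a minutia's polygons
#'
#' A circle centred on the reference minutia grows by `r_step` until it
#' contains at least `n + 2` other minutiae with at least one in every
#' axis-aligned quadrant. If the maximum radius is reached without that,
#' the within-`r_max` set is accepted anyway when it has at least `n`
#' members (the quadrant condition is waived for this fallback); otherwise
#' the minutia cannot be represented.
#'
#' @param ref_idx index of the reference minutia in `s`.
#' @param s a validated [minutia_set()].
#' @param params a [model_params()].
#' @return integer vector of neighbour row indices, or `NULL` when the
#'   minutia is unregistrable.
#' @export
find_neighbors <- function(ref_idx, s, params = model_params()) {
  dx <- s$x - s$x[ref_idx]
  dy <- s$y - s$y[ref_idx]
  d <- sqrt(dx^2 + dy^2)
  d[ref_idx] <- Inf
  for (r in seq(params$r_step, params$r_max, by = params$r_step)) {
    inside <- which(d <= r)
    if (length(inside) >= params$n + 2 &&
        length(unique(quadrant_of(dx[inside], dy[inside]))) == 4L) {
      return(inside)
    }
  }
  inside <- which(d <= params$r_max)
  if (length(inside) >= params$n) inside else NULL
}

#' Order polygon vertices around the reference minutia
#'
#' Sorts the candidate vertices counter-clockwise by angle around the
#' reference. For angularly sorted vertices the polygon is simple and
#' strictly contains the reference exactly when the largest angular gap
#' between consecutive vertices is below 180 degrees; subsets failing that
#' (all vertices in one half-plane), or with two vertices at the same angle
#' from the reference, are invalid.
#'
#' @param ref numeric `c(x, y)` of the reference minutia.
#' @param verts matrix with one row per vertex, columns x, y.
#' @return list with `verts` (reordered matrix) and `angles` (sorted vertex
#'   angles, radians), or `NULL` when the subset does not form a valid
#'   polygon around the reference.
#' @export
order_vertices <- function(ref, verts) {
  verts <- as.matrix(verts)
  ang <- atan2(verts[, 2] - ref[2], verts[, 1] - ref[1]) %% (2 * pi)
  if (anyDuplicated(ang)) return(NULL)
  ord <- order(ang)
  a <- ang[ord]
  gaps <- diff(c(a, a[1] + 2 * pi))
  if (max(gaps) >= pi) return(NULL)
  list(verts = verts[ord, , drop = FALSE], angles = a)
}

#' Canonical feature vector of a minutia polygon
#'
#' Encodes a valid polygon as `n` edge lengths (pixels, cyclic order) and
#' `n` central angles (degrees; the angle at the reference between
#' consecutive vertices, summing to 360). The cyclic order is rotated so
#' the largest edge comes first, preserving relative order — this, plus
#' using only distances and relative angles, makes the vector invariant to
#' rotation and translation. Ties on the largest edge are broken by taking
#' the lexicographically largest full `(edges, angles)` vector.
#'
#' @param ordered result of [order_vertices()].
#' @return numeric vector of length `2n`: `c(edges, angles)`.
#' @export
describe_polygon <- function(ordered) {
  v <- ordered$verts
  n <- nrow(v)
  nxt <- c(2:n, 1)
  edges <- sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2)
  gaps <- diff(c(ordered$angles, ordered$angles[1] + 2 * pi))
  angles <- gaps * 180 / pi
  rot <- function(vec, k) if (k == 0) vec else c(vec[-seq_len(k)], vec[seq_len(k)])
  cand <- which(edges == max(edges))
  best <- NULL
  for (k in cand - 1L) {
    full <- c(rot(edges, k), rot(angles, k))
    if (is.null(best) || vec_greater(full, best)) best <- full
  }
  unname(best)
}

# lexicographic a > b for numeric vectors
vec_greater <- function(a, b) {
  i <- which(a != b)
  length(i) > 0 && a[i[1]] > b[i[1]]
}

#' Build the polygon model of a fingerprint
#'
#' For every minutia in a validated set, finds its neighbour set, forms all
#' `choose(k, n)` candidate vertex subsets, keeps the valid polygons and
#' stores their canonical feature vectors. Minutiae with at least one valid
#' polygon are *registered*; the others carry no descriptors and take no
#' part in matching.
#'
#' @param s a validated [minutia_set()].
#' @param params a [model_params()].
#' @return object of class `fingerprint_model`: list with `minutiae` (the
#'   set), `descriptors` (per-minutia matrix with `2n` columns, one row per
#'   polygon; `NULL` rows of unregistered minutiae), `registered` (indices)
#'   and `params`.
#' @export
build_model <- function(s, params = model_params()) {
  n <- params$n
  descriptors <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    nb <- find_neighbors(i, s, params)
    if (is.null(nb) || length(nb) < n) next
    subsets <- utils::combn(nb, n)
    ref <- c(s$x[i], s$y[i])
    rows <- list()
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      ordered <- order_vertices(ref, cbind(s$x[idx], s$y[idx]))
      if (!is.null(ordered)) rows[[length(rows) + 1L]] <- describe_polygon(ordered)
    }
    if (length(rows)) descriptors[[i]] <- do.call(rbind, rows)
  }
  registered <- which(!vapply(descriptors, is.null, logical(1)))
  if (!length(registered)) warning("no minutia could be registered as a polygon model")
  structure(list(minutiae = s, descriptors = descriptors,
                 registered = registered, params = params),
            class = "fingerprint_model")
}

#' @export
print.fingerprint_model <- function(x, ...) {
  np <- sum(vapply(x$descriptors, function(d) if (is.null(d)) 0L else nrow(d),
                   integer(1)))
  cat(sprintf(
    "<fingerprint_model> %d/%d minutiae registered, %d polygons (n = %d)\n",
    length(x$registered), nrow(x$minutiae), np, x$params$n))
  invisible(x)
}
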