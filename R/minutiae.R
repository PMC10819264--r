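# ---- minutia set container ----

#' Minutia set
#'
#' A data frame of labeled feature points with columns `x`, `y` (0-based
#' pixel coordinates; real-valued after cloud averaging) and `type` (one of
#' `"T"` termination, `"B"` bifurcation, `"A"` averaged). Image dimensions
#' and a provenance tag (`"raw"` or `"validated"`) ride along as attributes.
#'
#' @param x,y numeric coordinate vectors.
#' @param type character vector in `c("T", "B", "A")`.
#' @param width,height source image dimensions in pixels.
#' @param provenance `"raw"` or `"validated"`.
#' @return an object of class `minutia_set` (a data frame).
#' @export
minutia_set <- function(x = numeric(), y = numeric(), type = character(),
                        width = NA_integer_, height = NA_integer_,
                        provenance = "raw") {
  stopifnot(length(x) == length(y), length(x) == length(type))
  if (!all(type %in% c("T", "B", "A"))) {
    stop("minutia type must be one of 'T', 'B', 'A'")
  }
  if (anyDuplicated(paste(x, y))) stop("duplicate minutia coordinates")
  if (!is.na(width) && length(x) &&
      (any(x < 0 | x >= width) || any(y < 0 | y >= height))) {
    stop("minutia coordinates outside image bounds")
  }
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       type = as.character(type), stringsAsFactors = FALSE),
            width = width, height = height, provenance = provenance,
            class = c("minutia_set", "data.frame"))
}

set_meta <- function(s, template) {
  attr(s, "width") <- attr(template, "width")
  attr(s, "height") <- attr(template, "height")
  class(s) <- c("minutia_set", "data.frame")
  s
}

#' @export
print.minutia_set <- function(x, ...) {
  tab <- table(factor(x$type, levels = c("T", "B", "A")))
  cat(sprintf("<minutia_set> %d minutiae (%d T, %d B, %d A), %s, image %s x %s\n",
              nrow(x), tab[["T"]], tab[["B"]], tab[["A"]],
              attr(x, "provenance"), attr(x, "width"), attr(x, "height")))
  invisible(x)
}

#' Validation parameters
#'
#' @param delta minimum distance in pixels between same-type minutiae;
#'   closer pairs are discarded (default 10).
#' @param gamma erosion depth in pixels of the convex-hull region of
#'   interest (default 10).
#' @param cloud_radius proximity in pixels under which minutiae are merged
#'   into one averaged minutia; defaults to `delta`.
#' @return a named list of class `validation_params`.
#' @export
validation_params <- function(delta = 10, gamma = 10, cloud_radius = delta) {
  stopifnot(delta >= 0, gamma >= 0, cloud_radius >= 0)
  structure(list(delta = delta, gamma = gamma, cloud_radius = cloud_radius),
            class = "validation_params")
}

# ---- crossing numbers ----

#' Crossing number of a 3x3 skeleton neighborhood
#'
#' Half the sum of absolute differences between consecutive pixels in the
#' cyclic 8-neighborhood of the centre, i.e. the number of 0-to-1
#' transitions around the cycle. CN 1 marks a ridge termination, CN 2 a
#' middle ridge point, CN 3 a bifurcation.
#'
#' @param neigh 3x3 binary matrix; the centre pixel is assumed to be ridge.
#' @return integer in 0..4.
#' @export
crossing_number <- function(neigh) {
  stopifnot(identical(dim(neigh), c(3L, 3L)))
  # cyclic counter-clockwise traversal of the 8 neighbours
  p <- as.numeric(neigh[cbind(c(1, 2, 3, 3, 3, 2, 1, 1),
                              c(1, 1, 1, 2, 3, 3, 3, 2))] != 0)
  sum(abs(p - c(p[-1], p[1]))) / 2
}

#' Extract raw minutiae from a skeleton
#'
#' Scans every interior ridge pixel of a unit-width skeleton and emits those
#' with crossing number 1 as terminations and 3 as bifurcations; CN 2
#' (middle ridge points) and border pixels are ignored.
#'
#' @param skel a [skeleton_image()].
#' @return a raw [minutia_set()].
#' @export
extract_minutiae <- function(skel) {
  P <- skel$pixels
  nr <- nrow(P); nc <- ncol(P)
  # the 8 neighbours in cyclic order, as shifted copies of P
  offs <- list(c(-1, -1), c(0, -1), c(1, -1), c(1, 0),
               c(1, 1), c(0, 1), c(-1, 1), c(-1, 0))
  nb <- lapply(offs, function(o) shift_mat(P, -o[2], -o[1]))  # value at (r+dy, c+dx)
  cn <- Reduce(`+`, lapply(seq_along(nb), function(i) {
    abs(nb[[i]] - nb[[if (i == 8) 1 else i + 1]])
  })) / 2
  interior <- matrix(FALSE, nr, nc)
  interior[2:(nr - 1), 2:(nc - 1)] <- TRUE
  term <- which(P == 1 & interior & cn == 1, arr.ind = TRUE)
  bif <- which(P == 1 & interior & cn == 3, arr.ind = TRUE)
  minutia_set(x = c(term[, 2], bif[, 2]) - 1,
              y = c(term[, 1], bif[, 1]) - 1,
              type = c(rep("T", nrow(term)), rep("B", nrow(bif))),
              width = nc, height = nr, provenance = "raw")
}

# ---- validation rules ----

#' Discard same-type minutiae closer than delta
#'
#' Every pair of minutiae of the same type at Euclidean distance < `delta`
#' signals a spur or bridge artifact; both members of each close pair are
#' removed. Pairs of different types are left to the cloud-merging step.
#'
#' @param s a [minutia_set()].
#' @param delta minimum same-type distance in pixels.
#' @return the filtered [minutia_set()].
#' @export
filter_same_type_distance <- function(s, delta) {
  if (delta <= 0 || nrow(s) < 2) return(s)
  drop <- rep(FALSE, nrow(s))
  for (tp in unique(s$type)) {
    idx <- which(s$type == tp)
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(s[idx, c("x", "y")]))
    diag(d) <- Inf
    drop[idx[apply(d < delta, 1, any)]] <- TRUE
  }
  set_meta(s[!drop, , drop = FALSE], s)
}

#' Convex hull of a point set
#'
#' Returns the vertices of the smallest convex polygon containing all
#' points, in counter-clockwise order (in the x right / y down frame used
#' throughout, counter-clockwise means positive signed area).
#'
#' @param pts matrix or data frame with columns x, y.
#' @return numeric matrix of hull vertices (columns `x`, `y`), CCW.
#' @export
convex_hull <- function(pts) {
  pts <- as.matrix(pts[, 1:2])
  colnames(pts) <- c("x", "y")
  pts <- unique(pts)
  if (nrow(pts) < 3) stop("degenerate hull: fewer than 3 distinct points")
  ord <- order(pts[, 1], pts[, 2])
  p <- pts[ord, , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(p[h[length(h) - 1], ], p[h[length(h)], ], p[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(nrow(p))), build(rev(seq_len(nrow(p)))))
  if (length(hull) < 3) stop("degenerate hull: all points collinear")
  p[hull, , drop = FALSE]
}

# signed distance from points to a CCW convex polygon boundary:
# positive inside, negative outside
hull_signed_distance <- function(px, py, hull) {
  nv <- nrow(hull)
  d <- rep(Inf, length(px))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(nv)) {
    a <- hull[i, ]; b <- hull[if (i == nv) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len2 <- ex^2 + ey^2
    t <- pmin(1, pmax(0, ((px - a[1]) * ex + (py - a[2]) * ey) / len2))
    dx <- px - (a[1] + t * ex); dy <- py - (a[2] + t * ey)
    d <- pmin(d, sqrt(dx^2 + dy^2))
    # CCW (positive-area) polygon keeps the interior on the positive side
    inside <- inside & (ex * (py - a[2]) - ey * (px - a[1])) >= 0
  }
  ifelse(inside, d, -d)
}

#' Region-of-interest filter by hull erosion
#'
#' Border minutiae are unreliable; the valid region is the convex hull of
#' the set eroded inward by `gamma` pixels (realized exactly as
#' distance-to-boundary thresholding). Minutiae strictly closer than
#' `gamma` to the hull boundary, or outside it, are removed; hull vertices
#' themselves always fall when `gamma > 0`.
#'
#' @param s a [minutia_set()] (at least 3 non-collinear points).
#' @param gamma erosion depth in pixels; 0 keeps everything.
#' @return the filtered [minutia_set()].
#' @export
roi_filter <- function(s, gamma) {
  if (gamma <= 0 || nrow(s) == 0) return(s)
  hull <- convex_hull(s[, c("x", "y")])
  keep <- hull_signed_distance(s$x, s$y, hull) >= gamma
  if (!any(keep)) warning("ROI erosion removed every minutia")
  set_meta(s[keep, , drop = FALSE], s)
}

#' Replace minutiae clouds by their average point
#'
#' Minutiae of any types closer than `cloud_radius` are linked; each
#' connected component of two or more is replaced by a single minutia of
#' type `"A"` at the component centroid. Singletons pass through untouched.
#'
#' @param s a [minutia_set()].
#' @param cloud_radius linking distance in pixels; 0 disables merging.
#' @return the merged [minutia_set()].
#' @export
merge_clouds <- function(s, cloud_radius) {
  if (cloud_radius <= 0 || nrow(s) < 2) return(s)
  d <- as.matrix(stats::dist(s[, c("x", "y")]))
  adj <- d < cloud_radius
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  rows <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    if (length(idx) == 1) s[idx, , drop = FALSE]
    else data.frame(x = mean(s$x[idx]), y = mean(s$y[idx]), type = "A",
                    stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  set_meta(out, s)
}

#' Validate a raw minutia set
#'
#' Applies the three validation rules in order: same-type minimum distance
#' `delta`, convex-hull region-of-interest eroded by `gamma`, and
#' minutiae-cloud averaging at `cloud_radius`.
#'
#' @param s a raw [minutia_set()].
#' @param params a [validation_params()].
#' @return a validated [minutia_set()] (provenance `"validated"`).
#' @export
validate_minutiae <- function(s, params = validation_params()) {
  out <- filter_same_type_distance(s, params$delta)
  out <- roi_filter(out, params$gamma)
  out <- merge_clouds(out, params$cloud_radius)
  rownames(out) <- NULL
  attr(out, "provenance") <- "validated"
  out
}
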