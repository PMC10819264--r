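# ---- matching parameters ----

#' Matching thresholds
#'
#' Defaults are the best configuration reported for the method on optical
#' 500 dpi imagery: `th_rel = 11` (%), `th_l = 5` (px), `th_a = 10`
#' (degrees), `tmc = 12` minutiae.
#'
#' @param th_rel relative error threshold in percent, applied element-wise
#'   to edges and angles.
#' @param th_l absolute edge-length threshold in pixels; rescues small
#'   edges whose relative error is large.
#' @param th_a absolute angle threshold in degrees.
#' @param tmc minimum matched-minutiae count to declare a fingerprint
#'   match; real-valued for threshold sweeps.
#' @return a named list of class `match_params`.
#' @export
match_params <- function(th_rel = 11, th_l = 5, th_a = 10, tmc = 12) {
  stopifnot(th_rel >= 0, th_l >= 0, th_a >= 0, tmc >= 0)
  structure(list(th_rel = th_rel, th_l = th_l, th_a = th_a, tmc = tmc),
            class = "match_params")
}

#' Euclidean distance between two polygon descriptors
#'
#' Unweighted Euclidean norm of the element-wise difference of the
#' `2n`-vectors (edges in pixels, angles in degrees mixed in one vector;
#' unit-aware thresholds live in [validate_pair()], not here).
#'
#' @param d1,d2 descriptor vectors of equal length.
#' @return non-negative scalar.
#' @export
polygon_distance <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("descriptor lengths differ")
  sqrt(sum((d1 - d2)^2))
}

#' Element-wise validation of a descriptor pair
#'
#' Each of the `2n` slots passes if its relative error is at most `th_rel`
#' percent OR its absolute difference is within the unit-specific absolute
#' threshold (`th_l` for edges, `th_a` for angles); the pair is valid only
#' if every slot passes. Relative error uses the symmetric denominator
#' `max(a, b)`. The OR combination lets the absolute criterion rescue
#' small edges whose relative error is inflated.
#'
#' @param d1,d2 descriptor vectors of equal (even) length.
#' @param params a [match_params()].
#' @return logical scalar.
#' @export
validate_pair <- function(d1, d2, params = match_params()) {
  if (length(d1) != length(d2)) stop("descriptor lengths differ")
  n <- length(d1) / 2
  rel <- 100 * abs(d1 - d2) / pmax(d1, d2)
  rel[d1 == d2] <- 0
  absd <- abs(d1 - d2)
  th_abs <- rep(c(params$th_l, params$th_a), each = n)
  all(rel <= params$th_rel | absd <= th_abs)
}

# squared cross-distance matrix between descriptor row-matrices
descriptor_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Match one minutia against another
#'
#' Scans all pairs of polygon descriptors of the two minutiae, takes the
#' minimum-distance pair, and validates that single best pair with the
#' element-wise error criteria (a worse pair that would validate is never
#' consulted).
#'
#' @param da,db descriptor matrices (rows = polygons, `2n` columns).
#' @param params a [match_params()].
#' @return list with `distance` (best-pair Euclidean distance), `pa`, `pb`
#'   (row indices of the best pair) and `validated`.
#' @export
match_minutia <- function(da, db, params = match_params()) {
  D <- descriptor_cross_dist(da, db)
  k <- arrayInd(which.min(D), dim(D))
  pa <- k[1, 1]; pb <- k[1, 2]
  list(distance = D[pa, pb], pa = pa, pb = pb,
       validated = validate_pair(da[pa, ], db[pb, ], params))
}

#' Match two fingerprint models
#'
#' Every pair of registered minutiae is compared with [match_minutia()];
#' validated candidates are then reduced to a one-to-one correspondence
#' greedily by ascending descriptor distance (ties broken by minutia
#' indices, so the result is deterministic). The fingerprints match when
#' the number of corresponding minutiae reaches `tmc`.
#'
#' @param A,B `fingerprint_model` objects sharing the same `n`.
#' @param params a [match_params()].
#' @return object of class `match_result`: list with `matches` (data frame
#'   `index_a`, `index_b`, `distance`), `matched_count`, `decision`
#'   (`TRUE` = match) and `params`.
#' @export
match_fingerprints <- function(A, B, params = match_params()) {
  if (A$params$n != B$params$n) stop("models use different polygon vertex counts")
  ra <- A$registered; rb <- B$registered
  if (!length(ra) || !length(rb)) {
    warning("empty model: no registered minutiae to match")
    return(structure(list(matches = data.frame(index_a = integer(),
                                               index_b = integer(),
                                               distance = numeric()),
                          matched_count = 0L,
                          decision = 0L >= params$tmc, params = params),
                     class = "match_result"))
  }
  cand <- list()
  for (ia in ra) for (ib in rb) {
    m <- match_minutia(A$descriptors[[ia]], B$descriptors[[ib]], params)
    if (m$validated) {
      cand[[length(cand) + 1L]] <- c(ia, ib, m$distance)
    }
  }
  matches <- data.frame(index_a = integer(), index_b = integer(),
                        distance = numeric())
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    used_a <- logical(max(ra)); used_b <- logical(max(rb))
    for (r in seq_len(nrow(cm))) {
      ia <- cm[r, 1]; ib <- cm[r, 2]
      if (!used_a[ia] && !used_b[ib]) {
        used_a[ia] <- TRUE; used_b[ib] <- TRUE
        matches[nrow(matches) + 1L, ] <- cm[r, ]
      }
    }
  }
  structure(list(matches = matches, matched_count = nrow(matches),
                 decision = nrow(matches) >= params$tmc, params = params),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d corresponding minutiae, TMC %.6g -> %s\n",
              x$matched_count, x$params$tmc,
              if (x$decision) "MATCH" else "NON-MATCH"))
  invisible(x)
}
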