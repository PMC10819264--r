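test_that("crossing number matches the exhaustive transition-count oracle", {
  for (code in 0:255) {
    bits <- as.integer(intToBits(code)[1:8])
    m <- neigh_from_bits(bits)
    expect_equal(crossing_number(m), cn_oracle(m))
  }
})

test_that("canonical crossing-number patterns map to the right types", {
  # one ridge neighbour -> CN 1 (termination)
  expect_equal(crossing_number(neigh_from_bits(c(1, 0, 0, 0, 0, 0, 0, 0))), 1)
  # straight ridge through the centre -> CN 2 (middle ridge point)
  expect_equal(crossing_number(neigh_from_bits(c(0, 1, 0, 0, 0, 1, 0, 0))), 2)
  # three pairwise non-adjacent neighbours -> CN 3 (bifurcation)
  expect_equal(crossing_number(neigh_from_bits(c(1, 0, 0, 1, 0, 0, 1, 0))), 3)
  # isolated point
  expect_equal(crossing_number(neigh_from_bits(rep(0, 8))), 0)
})

test_that("extraction finds terminations and bifurcations where CN says so", {
  # straight 1-px line of length 10: exactly the 2 endpoints
  line <- matrix(0, 20, 20)
  line[10, 6:15] <- 1
  s <- extract_minutiae(skeleton_image(line))
  expect_equal(nrow(s), 2)
  expect_true(all(s$type == "T"))
  expect_setequal(s$x, c(5, 14))

  # perfect "Y": 1 bifurcation + 3 terminations, cross-checked pixel by
  # pixel with the oracle
  Y <- matrix(0, 25, 25)
  Y[13:20, 13] <- 1                      # stem down
  for (i in 1:7) { Y[13 - i, 13 - i] <- 1; Y[13 - i, 13 + i] <- 1 }
  sy <- extract_minutiae(skeleton_image(Y))
  expect_equal(sum(sy$type == "B"), 1)
  expect_equal(sum(sy$type == "T"), 3)
  for (r in 2:24) for (cc in 2:24) {
    if (Y[r, cc] == 1) {
      cn <- cn_oracle(Y[(r - 1):(r + 1), (cc - 1):(cc + 1)])
      hit <- any(sy$x == cc - 1 & sy$y == r - 1)
      expect_equal(hit, cn %in% c(1, 3))
    }
  }

  # empty skeleton -> empty set
  expect_equal(nrow(extract_minutiae(skeleton_image(matrix(0, 16, 16)))), 0)
})

test_that("same-type distance rule removes both members of close pairs only", {
  s <- fixture_set(x = c(10, 13, 100, 101, 200),
                   y = c(10, 10, 100, 100, 200),
                   type = c("T", "T", "T", "B", "B"))
  out <- filter_same_type_distance(s, delta = 5)
  # the two close terminations die; the T/B pair 1 px apart survives
  expect_equal(nrow(out), 3)
  expect_true(all(out$x %in% c(100, 101, 200)))
  # oracle: recompute by direct pairwise distances
  d <- as.matrix(dist(s[, c("x", "y")]))
  for (i in seq_len(nrow(s))) {
    close_same <- any(d[i, -i] < 5 & s$type[-i] == s$type[i])
    expect_equal(!(s$x[i] %in% out$x & s$y[i] %in% out$y), close_same)
  }
  expect_identical(filter_same_type_distance(s, 0), s)
})

test_that("convex hull equals the brute-force half-plane oracle", {
  # square + centre
  sq <- cbind(x = c(0, 100, 100, 0, 50), y = c(0, 0, 100, 100, 50))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4)
  expect_false(any(h[, 1] == 50))
  # CCW = positive shoelace area
  shoelace <- function(p) {
    nxt <- c(2:nrow(p), 1)
    sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2
  }
  expect_gt(shoelace(h), 0)

  set.seed(42)
  for (rep in 1:5) {
    pts <- cbind(x = runif(50, 0, 300), y = runif(50, 0, 300))
    h <- convex_hull(pts)
    oracle <- hull_vertices_oracle(pts)
    expect_equal(nrow(h), nrow(oracle))
    expect_setequal(paste(round(h[, 1], 9), round(h[, 2], 9)),
                    paste(round(oracle[, 1], 9), round(oracle[, 2], 9)))
    expect_gt(shoelace(h), 0)
  }

  expect_error(convex_hull(cbind(c(0, 1), c(0, 1))), "degenerate")
  expect_error(convex_hull(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  tri <- convex_hull(cbind(c(0, 10, 0), c(0, 0, 10)))
  expect_equal(nrow(tri), 3)
})

test_that("ROI filter matches the point-to-hull-boundary oracle", {
  # square hull 100x100: a point 5 px from an edge dies at gamma = 10
  s <- fixture_set(x = c(0, 100, 100, 0, 5, 50),
                   y = c(0, 0, 100, 100, 50, 50),
                   type = rep("T", 6))
  out <- roi_filter(s, gamma = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 50)

  # gamma = 0 keeps everything
  expect_identical(roi_filter(s, 0), s)

  # gamma beyond the inradius empties the set with a warning
  expect_warning(out2 <- roi_filter(s, gamma = 60), "removed every")
  expect_equal(nrow(out2), 0)

  # randomized agreement with the independent ray-casting + segment oracle
  set.seed(7)
  for (rep in 1:20) {
    pts <- fixture_set(runif(25, 0, 300), runif(25, 0, 300),
                       rep("T", 25))
    gamma <- runif(1, 2, 30)
    out <- roi_filter(pts, gamma)
    hull <- convex_hull(pts[, c("x", "y")])
    inside <- point_in_poly_oracle(pts$x, pts$y, hull)
    d <- dist_to_boundary_oracle(pts$x, pts$y, hull)
    keep_oracle <- (inside | d < 1e-9) & d >= gamma
    expect_equal(paste(out$x, out$y),
                 paste(pts$x[keep_oracle], pts$y[keep_oracle]))
  }
})

test_that("ROI filter is monotone in gamma below the kept minimum distance", {
  set.seed(3)
  pts <- fixture_set(runif(30, 0, 300), runif(30, 0, 300), rep("T", 30))
  out <- roi_filter(pts, 15)
  # decreasing gamma never removes a kept minutia
  for (g in c(15, 10, 5, 1e-6)) {
    again <- roi_filter(pts, g)
    expect_true(all(paste(out$x, out$y) %in% paste(again$x, again$y)))
  }
  # and the kept set is unchanged while gamma stays above every removed
  # minutia's boundary distance
  hull <- convex_hull(pts[, c("x", "y")])
  removed <- !(paste(pts$x, pts$y) %in% paste(out$x, out$y))
  d_removed <- dist_to_boundary_oracle(pts$x[removed], pts$y[removed], hull)
  g_safe <- max(d_removed) + 1e-6
  if (g_safe <= 15) {
    expect_equal(nrow(roi_filter(pts, g_safe)), nrow(out))
  }
})

test_that("cloud merging averages connected components", {
  s <- fixture_set(x = c(10, 12, 200), y = c(10, 10, 200),
                   type = c("T", "B", "T"))
  out <- merge_clouds(s, cloud_radius = 5)
  expect_equal(nrow(out), 2)
  avg <- out[out$type == "A", ]
  expect_equal(c(avg$x, avg$y), c(11, 10))

  # a chain of three mutually close minutiae collapses to one centroid
  s3 <- fixture_set(x = c(10, 13, 16, 200), y = c(10, 10, 10, 200),
                    type = c("T", "B", "T", "B"))
  out3 <- merge_clouds(s3, cloud_radius = 4)
  expect_equal(nrow(out3), 2)
  expect_equal(out3$x[out3$type == "A"], 13)

  expect_identical(merge_clouds(s, 0), s)
})

test_that("validation pipeline applies the three rules in order", {
  # crafted fixture: a close same-type pair, a border point, a mixed-type
  # cloud, and safely interior singletons
  s <- fixture_set(
    x = c(150, 153, 10, 140, 142, 100, 200, 150, 100, 200, 60, 240),
    y = c(150, 150, 10, 160, 160, 100, 100, 60, 200, 200, 150, 150),
    type = c("T", "T", "B", "T", "B", "B", "T", "B", "T", "B", "T", "B"))
  p <- validation_params(delta = 5, gamma = 15, cloud_radius = 5)
  out <- validate_minutiae(s, p)
  # hand application: (150,150)+(153,150) die by delta; corner (10,10) and
  # the other hull/border points die by ROI; (140,160)+(142,160)
  # merge to (141,160) type A; interior singletons survive untouched
  expect_true(any(out$x == 141 & out$type == "A"))
  expect_false(any(out$x %in% c(150, 153) & out$y == 150))
  expect_false(any(out$x == 10))
  expect_true(nrow(out) < nrow(s))
  expect_equal(attr(out, "provenance"), "validated")

  # deterministic: identical input gives identical output order
  expect_identical(validate_minutiae(s, p), out)

  # all-zero parameters leave the set unchanged (as a set)
  out0 <- validate_minutiae(s, validation_params(0, 0, 0))
  expect_setequal(paste(out0$x, out0$y), paste(s$x, s$y))

  # each pre-merge step is non-increasing in count
  s1 <- filter_same_type_distance(s, p$delta)
  s2 <- roi_filter(s1, p$gamma)
  expect_lte(nrow(s1), nrow(s))
  expect_lte(nrow(s2), nrow(s1))
  expect_lt(nrow(merge_clouds(s2, p$cloud_radius)), nrow(s2))
})
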