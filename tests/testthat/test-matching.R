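test_that("polygon distance is the plain Euclidean norm", {
  d1 <- c(30, 20, 10, 90, 180, 90)
  expect_equal(polygon_distance(d1, d1), 0)
  d2 <- d1; d2[2] <- 23
  expect_equal(polygon_distance(d1, d2), 3)
  set.seed(2)
  a <- runif(10, 1, 100); b <- runif(10, 1, 100)
  expect_equal(polygon_distance(a, b), sqrt(sum((a - b)^2)))
  expect_error(polygon_distance(a, b[-1]), "lengths differ")
})

test_that("pair validation combines relative and absolute criteria with OR", {
  p <- match_params(th_rel = 11, th_l = 5, th_a = 10)
  base <- c(10, 10, 10, 120, 120, 120)
  # edge 10 vs 10.4: relative error 3.8% <= 11 -> passes
  ok <- base; ok[1] <- 10.4
  expect_true(validate_pair(base, ok, p))
  # edge 4 vs 8: relative 50% fails but |diff| = 4 <= th_l rescues it
  small_a <- c(4, 10, 10, 120, 120, 120)
  small_b <- c(8, 10, 10, 120, 120, 120)
  expect_true(validate_pair(small_a, small_b, p))
  # angle 90 vs 120: relative 25% and |diff| 30 both fail -> pair invalid
  bad_a <- c(10, 10, 10, 90, 135, 135)
  bad_b <- c(10, 10, 10, 120, 120, 120)
  expect_false(validate_pair(bad_a, bad_b, p))
  # slot-wise oracle on random pairs
  set.seed(8)
  for (rep in 1:20) {
    n <- 5
    a <- c(runif(n, 1, 80), runif(n, 10, 170))
    b <- a + rnorm(2 * n, 0, 4)
    b <- pmax(b, 0.1)
    rel <- 100 * abs(a - b) / pmax(a, b)
    pass <- (rel <= p$th_rel) |
      (abs(a - b) <= rep(c(p$th_l, p$th_a), each = n))
    expect_equal(validate_pair(a, b, p), all(pass))
  }
})

test_that("minutia matching validates only the best-distance pair", {
  p <- match_params(th_rel = 11, th_l = 5, th_a = 10)
  # identical descriptor sets: zero distance, validated
  da <- rbind(c(30, 25, 20, 120, 120, 120), c(50, 40, 30, 100, 130, 130))
  m <- match_minutia(da, da, p)
  expect_equal(m$distance, 0)
  expect_true(m$validated)

  # craft a best pair that fails validation while a worse pair would pass:
  # db row 1 is near da row 1 overall but breaks one angle slot badly is
  # impossible at small distance, so use a small edge-vector distance with
  # a concentrated angle violation vs a larger distance that validates
  da2 <- rbind(c(30, 25, 20, 120, 120, 120))
  db2 <- rbind(c(30, 25, 20, 135, 105, 120),   # distance ~21, angle slot fails
               c(33, 27, 22, 124, 124, 112))   # distance ~11, all slots pass
  stopifnot(polygon_distance(da2[1, ], db2[2, ]) <
            polygon_distance(da2[1, ], db2[1, ]))
  m2 <- match_minutia(da2, db2, p)
  expect_equal(m2$pb, 2)
  expect_true(m2$validated)
  # now make the invalid row the closer one
  db3 <- rbind(c(30, 25, 20, 135, 105, 120),   # closer, angle slot fails
               c(35, 30, 25, 133, 133, 133))   # farther, would validate
  d_best <- polygon_distance(da2[1, ], db3[1, ])
  d_other <- polygon_distance(da2[1, ], db3[2, ])
  stopifnot(d_best < d_other)
  m3 <- match_minutia(da2, db3, p)
  expect_equal(m3$pb, 1)
  expect_false(m3$validated)   # the worse-but-valid pair is never consulted
})

make_model <- function(s, n = 5, r_max = 200) {
  build_model(s, model_params(n = n, r_step = 5, r_max = r_max))
}

test_that("fingerprint matching is complete on self and stable under rigid motion", {
  s <- generate_minutia_set(synthetic_params(k = 25, extent = 300, seed = 17))
  v <- validate_minutiae(s)
  A <- make_model(v)
  p <- match_params(tmc = 5)
  self <- match_fingerprints(A, A, p)
  expect_equal(self$matched_count, length(A$registered))
  expect_true(all(self$matches$index_a == self$matches$index_b))
  expect_true(all(self$matches$distance == 0))
  expect_true(self$decision)

  for (tr in list(c(45, 0, 0), c(90, 0, 0),
                  c(0, 0.1 * 300 / sqrt(2), 0.1 * 300 / sqrt(2)))) {
    xy <- rigid_transform(as.matrix(v[, c("x", "y")]), tr[1], tr[2:3],
                          center = c(150, 150))
    vt <- minutia_set(xy[, 1], xy[, 2], v$type)
    B <- make_model(vt)
    r <- match_fingerprints(A, B, p)
    expect_equal(r$matched_count, self$matched_count)
  }
})

test_that("greedy one-to-one assignment matches an independent oracle", {
  # two overlapping 6-minutia constellations sharing 3 exact positions
  common <- cbind(c(100, 140, 120), c(100, 100, 140))
  extra_a <- cbind(c(60, 180, 120), c(60, 60, 200))
  extra_b <- cbind(c(70, 190, 130), c(210, 190, 40))
  sa <- fixture_set(c(common[, 1], extra_a[, 1]), c(common[, 2], extra_a[, 2]))
  sb <- fixture_set(c(common[, 1], extra_b[, 1]), c(common[, 2], extra_b[, 2]))
  A <- make_model(sa, n = 3, r_max = 300)
  B <- make_model(sb, n = 3, r_max = 300)
  p <- match_params(tmc = 4)
  r <- match_fingerprints(A, B, p)
  # oracle: recompute candidates exhaustively and run an independent greedy
  cand <- NULL
  for (ia in A$registered) for (ib in B$registered) {
    D <- as.matrix(dist(rbind(A$descriptors[[ia]], B$descriptors[[ib]])))
    na <- nrow(A$descriptors[[ia]])
    Dx <- D[seq_len(na), -seq_len(na), drop = FALSE]
    best <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
    if (validate_pair(A$descriptors[[ia]][best[1], ],
                      B$descriptors[[ib]][best[2], ], p)) {
      cand <- rbind(cand, c(ia, ib, min(Dx)))
    }
  }
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  ua <- c(); ub <- c(); n_oracle <- 0L
  for (i in seq_len(nrow(cand))) {
    if (!(cand[i, 1] %in% ua) && !(cand[i, 2] %in% ub)) {
      ua <- c(ua, cand[i, 1]); ub <- c(ub, cand[i, 2])
      n_oracle <- n_oracle + 1L
    }
  }
  expect_equal(r$matched_count, n_oracle)
  expect_false(r$decision != (n_oracle >= 4))

  # symmetry of the count under argument swap
  r_swap <- match_fingerprints(B, A, p)
  expect_equal(r_swap$matched_count, r$matched_count)
})

test_that("thresholds act monotonically on the decision and the count", {
  s <- generate_minutia_set(synthetic_params(k = 25, extent = 300, seed = 23))
  v <- validate_minutiae(s)
  A <- make_model(v)
  sp <- synthetic_params(k = 25, extent = 300, jitter_sigma = 2,
                         rotation = 15, translation = c(10, -5), seed = 24)
  B <- make_model(validate_minutiae(perturb_minutia_set(s, sp)))
  base <- match_fingerprints(A, B, match_params(tmc = 5))
  # raising tmc never converts non-match to match
  for (tmc in c(1, base$matched_count, base$matched_count + 1, 50)) {
    r <- match_fingerprints(A, B, match_params(tmc = tmc))
    expect_equal(r$decision, r$matched_count >= tmc)
    expect_equal(r$matched_count, base$matched_count)  # tmc affects decision only
  }
  # loosening the error thresholds never decreases the count
  tighter <- match_fingerprints(A, B, match_params(th_rel = 5, th_l = 2,
                                                   th_a = 4, tmc = 5))
  looser <- match_fingerprints(A, B, match_params(th_rel = 20, th_l = 8,
                                                  th_a = 15, tmc = 5))
  expect_lte(tighter$matched_count, base$matched_count)
  expect_lte(base$matched_count, looser$matched_count)
})

test_that("degenerate matches are handled", {
  s <- fixture_set(c(10, 250), c(10, 250))
  expect_warning(empty <- build_model(s, model_params()), "no minutia")
  full <- make_model(validate_minutiae(
    generate_minutia_set(synthetic_params(seed = 3))))
  expect_warning(r <- match_fingerprints(empty, full, match_params()),
                 "empty model")
  expect_equal(r$matched_count, 0L)
  expect_false(r$decision)
  bad <- full; bad$params$n <- 6L
  expect_error(match_fingerprints(full, bad), "different polygon")
})
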