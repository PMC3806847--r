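test_that("cm_features standardises, rotates, and applies the Kaiser rule", {
  pop <- tiny_population(5, 4)
  f <- cm_features(pop, n_samples = 30)
  expect_equal(nrow(f), 20L)
  expect_equal(rownames(f), whistle_ids(pop))
  eig <- attr(f, "eigenvalues")
  expect_equal(sum(eig), 30, tolerance = 1e-8)   # correlation PCA: trace = p
  expect_equal(ncol(f), sum(eig > 1))

  # identical contours produce identical (degenerate) feature rows
  same <- contour_set(lapply(1:3, function(i)
    whistle_contour(c(0, 0.5, 1), c(5000, 6000, 5500), sprintf("w%d", i))))
  fs <- suppressWarnings(cm_features(same, n_samples = 10))
  expect_true(all(fs == fs[1, 1]))

  # rank-1 structure plus tiny noise retains a single dimension
  set.seed(5)
  base <- seq(4000, 9000, length.out = 20)
  rk1 <- contour_set(lapply(1:12, function(i) {
    scale <- 1 + i / 10
    whistle_contour(seq(0, 1, length.out = 20),
                    base * scale + rnorm(20, 0, 0.1), sprintf("w%d", i))
  }))
  f1 <- cm_features(rk1, n_samples = 20)
  expect_equal(ncol(f1), 1L)
})

test_that("cm features are invariant to a global frequency offset", {
  pop <- tiny_population(4, 3)
  shifted <- contour_set(lapply(pop$contours, function(w)
    whistle_contour(w$time, w$freq + 5000, w$whistle_id, w$individual_id)))
  f0 <- cm_features(pop, n_samples = 20)
  f1 <- cm_features(shifted, n_samples = 20)
  expect_equal(euclidean_proximity(f0), euclidean_proximity(f1), tolerance = 1e-6)
})

test_that("euclidean_proximity matches a brute-force double loop", {
  expect_equal(euclidean_proximity(rbind(a = c(0, 0), b = c(3, 4)))["a", "b"], 5)
  set.seed(6)
  X <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(sprintf("r%d", 1:15), NULL))
  D <- euclidean_proximity(X)
  for (i in 1:15) for (j in 1:15)
    expect_equal(D[i, j], sqrt(sum((X[i, ] - X[j, ])^2)), tolerance = 1e-12)
})

test_that("dtw_distance handles identity, duplication, and the two-point case", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(7, 7), c(7, 7, 7)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
})

test_that("dtw_distance matches exhaustive warping-path enumeration", {
  set.seed(7)
  for (i in 1:40) {
    a <- round(runif(sample(1:4, 1), 0, 5), 1)
    b <- round(runif(sample(1:4, 1), 0, 5), 1)
    expect_equal(dtw_distance(a, b), dtw_oracle_paths(a, b), tolerance = 1e-12)
  }
})

test_that("dtw_distance agrees with a memoised recursion on 500 random pairs", {
  set.seed(8)
  for (i in 1:500) {
    a <- runif(sample(1:6, 1), 0, 10)
    b <- runif(sample(1:6, 1), 0, 10)
    expect_equal(dtw_distance(a, b), dtw_oracle_memo(a, b), tolerance = 1e-12)
  }
})

test_that("warping can only reduce the aligned cost", {
  set.seed(9)
  for (i in 1:30) {
    a <- runif(10); b <- runif(10)
    expect_lte(dtw_distance(a, b), sum((a - b)^2) + 1e-12)
  }
})

test_that("normalized DTW divides by the optimal path length", {
  expect_equal(dtw_distance(c(0, 0), c(1, 1), normalize = TRUE), 1)
  expect_equal(dtw_distance(c(5, 5, 5), c(5, 5, 5), normalize = TRUE), 0)
})

test_that("dtw_proximity is consistent with per-pair dtw_distance", {
  pop <- tiny_population(3, 3)
  D <- dtw_proximity(pop, n_samples = 20)
  X <- resample_set(pop, 20)
  n <- nrow(X)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_equal(D[i, j], dtw_distance(X[i, ], X[j, ]), tolerance = 1e-9)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("dtw_proximity: duplicates give zero distance, permutations commute", {
  pop <- tiny_population(3, 2)
  dup <- contour_set(c(pop$contours,
                       list(whistle_contour(pop[[1]]$time, pop[[1]]$freq,
                                            "copy", "indX"))))
  D <- dtw_proximity(dup, n_samples = 15)
  expect_equal(D[whistle_ids(pop)[1], "copy"], 0)
  perm <- c(4, 2, 6, 1, 3, 5, 7)
  Dp <- dtw_proximity(dup[perm], n_samples = 15)
  expect_equal(Dp, D[perm, perm])
})

test_that("classical MDS recovers Euclidean configurations exactly", {
  set.seed(10)
  P <- matrix(rnorm(10), 5, 2)
  D <- euclidean_proximity(P)
  X <- mds_embed(D, 2)
  expect_equal(euclidean_proximity(X), D, tolerance = 1e-8)

  # rank-3 configuration embedded in 4+ dims: extra dimensions are zero
  P3 <- matrix(rnorm(24), 8, 3,
               dimnames = list(sprintf("p%d", 1:8), NULL))
  D3 <- euclidean_proximity(P3)
  X3 <- mds_embed(D3, 6)
  expect_lt(max(abs(X3[, 4:6])), 1e-6)
  expect_equal(euclidean_proximity(X3), D3, tolerance = 1e-8)

  # zero proximity puts every point at the origin
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(abs(mds_embed(Z, 2)) < 1e-10))

  expect_error(mds_embed(D, 5), "smaller")
})

test_that("classical MDS agrees with stats::cmdscale up to sign", {
  set.seed(12)
  P <- matrix(rnorm(14), 7, 2)
  D <- euclidean_proximity(P)
  ours <- mds_embed(D, 2)
  ref <- stats::cmdscale(D, k = 2)
  for (j in 1:2)
    expect_equal(unname(abs(ours[, j])), unname(abs(ref[, j])), tolerance = 1e-8)
})

test_that("random proximity control is seeded, symmetric, uniform", {
  A <- random_proximity(50, seed = 99)
  B <- random_proximity(50, seed = 99)
  expect_identical(A, B)
  expect_false(identical(A, random_proximity(50, seed = 100)))
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  big <- random_proximity(400, seed = 1)
  expect_equal(mean(big[upper.tri(big)]), 0.5, tolerance = 0.02)
})
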