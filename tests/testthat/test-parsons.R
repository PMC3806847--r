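test_that("segment means average the contour over equal time intervals", {
  expect_equal(segment_means(const_contour(5000), 7), rep(5000, 7))
  # linear ramp 0 -> 900 Hz over 1 s (freqs must be positive: use 1..901 shifted)
  ramp <- ramp_contour(f0 = 100, f1 = 1000, dur = 1, n = 2)
  expect_equal(segment_means(ramp, 3), c(250, 550, 850))
  expect_equal(segment_means(ramp, 1), 550)
})

test_that("segment means agree with dense numerical integration", {
  for (seed in 1:5) {
    w <- sine_contour(n = 17, noise_sd = 400, seed = seed)
    got <- segment_means(w, 10)
    breaks <- seq(min(w$time), max(w$time), length.out = 11)
    dense <- vapply(seq_len(10), function(i) {
      tt <- seq(breaks[i], breaks[i + 1], length.out = 20001)
      mean(stats::approx(w$time, w$freq, xout = tt)$y)
    }, numeric(1))
    expect_equal(got, dense, tolerance = 1e-4)
    # mean of segment means equals the overall contour mean (equal intervals)
    tt <- seq(min(w$time), max(w$time), length.out = 200001)
    expect_equal(mean(got), mean(stats::approx(w$time, w$freq, xout = tt)$y),
                 tolerance = 1e-4)
  }
})

test_that("alphabet fitting puts the top 10% of pooled changes in the large class", {
  a <- fit_alphabet(1:100, n_levels = 2, constant_tol = 0)
  expect_equal(length(a$magnitude_thresholds), 1L)
  expect_equal(sum(abs(1:100) > a$magnitude_thresholds), 10L)

  a1 <- fit_alphabet(rnorm(50), n_levels = 1)
  expect_identical(a1$magnitude_thresholds, numeric(0))
  expect_equal(a1$size, 3L)

  set.seed(3)
  d <- runif(10000, 0, 1000)
  a3 <- fit_alphabet(d, n_levels = 3, constant_tol = 0)
  expect_equal(a3$size, 7L)
  lev <- findInterval(abs(d), a3$magnitude_thresholds, left.open = TRUE) + 1L
  props <- tabulate(lev, 3) / length(d)
  expect_equal(props, c(0.45, 0.45, 0.10), tolerance = 0.01)

  expect_error(fit_alphabet(c(0.1, 0.2), n_levels = 2, constant_tol = 1),
               "degenerate")
})

test_that("encoding classifies direction and magnitude of each change", {
  a1 <- fit_alphabet(c(-1, 1), n_levels = 1, constant_tol = 0)
  a1$constant_tol <- 0.5
  code <- encode(c(1, 2, 3, 2, 2), a1)
  expect_equal(code$symbols, c(1L, 1L, -1L, 0L))
  expect_equal(format_parsons(code), "u1,u1,d1,c")

  mono <- encode(c(1, 3, 6, 10), a1)
  expect_true(all(mono$symbols > 0))

  # ten segment means yield a nine-symbol code
  expect_length(encode(1:10 * 100, a1)$symbols, 9L)

  # encoding depends only on differences: shift-invariant
  a3 <- fit_alphabet(runif(200, -50, 50), n_levels = 3)
  m <- c(10, 40, 35, 35.2, 90, 20)
  expect_identical(encode(m, a3)$symbols, encode(m + 1234, a3)$symbols)

  # ties on a magnitude threshold take the lower class
  at <- fit_alphabet(1:100, n_levels = 2, constant_tol = 0)
  thr <- at$magnitude_thresholds[1]
  expect_equal(encode(c(0, thr), at)$symbols, 1L)
  expect_equal(encode(c(0, thr + 1e-9), at)$symbols, 2L)
})

test_that("encode_set pools deltas over the whole set and encodes every whistle", {
  pop <- tiny_population(5, 4)
  enc <- encode_set(pop, n_segments = 10, n_levels = 3)
  expect_equal(dim(enc$codes), c(20L, 9L))
  expect_equal(enc$alphabet$size, 7L)
  # about 10% of all transitions carry the top magnitude level
  frac_large <- mean(abs(enc$codes) == 3L)
  expect_equal(frac_large, 0.10, tolerance = 0.02)
  # a supplied alphabet is honoured (frozen thresholds)
  enc2 <- encode_set(pop[1:10], alphabet = enc$alphabet, n_segments = 10)
  expect_identical(enc2$codes, enc$codes[1:10, ])
})

test_that("edit distance matches exhaustive edit-script enumeration", {
  expect_equal(edit_distance(c(1, 1, 1), c(1, 1, 1)), 0L)
  expect_equal(edit_distance(c(1, 1, 1), c(-1, -1, -1)), 3L)
  expect_equal(edit_distance(c(1, -1), c(1, -1, 1)), 1L)
  set.seed(42)
  for (i in 1:50) {
    a <- random_code(sample(0:4, 1))
    b <- random_code(sample(1:4, 1))
    expect_equal(edit_distance(a, b), ed_oracle_exhaustive(a, b))
  }
})

test_that("edit distance agrees with independent implementations on 500 random pairs", {
  set.seed(43)
  to_chr <- function(x) paste(letters[x + 4], collapse = "")
  for (i in 1:500) {
    a <- random_code(sample(1:5, 1))
    b <- random_code(sample(1:5, 1))
    expect_equal(edit_distance(a, b), ed_oracle_memo(a, b))
    expect_equal(edit_distance(a, b),
                 as.integer(utils::adist(to_chr(a), to_chr(b))))
  }
})

test_that("edit distance is a metric bounded by the longer code", {
  set.seed(44)
  for (i in 1:60) {
    a <- random_code(sample(1:8, 1)); b <- random_code(sample(1:8, 1))
    c_ <- random_code(sample(1:8, 1))
    dab <- edit_distance(a, b); dbc <- edit_distance(b, c_)
    dac <- edit_distance(a, c_)
    expect_gte(dab, 0)
    expect_equal(dab, edit_distance(b, a))
    expect_equal(edit_distance(a, a), 0L)
    expect_lte(dac, dab + dbc)
    expect_lte(dab, max(length(a), length(b)))
  }
})

test_that("pc_proximity matches pairwise edit_distance calls", {
  pop <- tiny_population(4, 3)
  enc <- encode_set(pop, n_segments = 8, n_levels = 2)
  D <- pc_proximity(enc)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  n <- nrow(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_equal(D[i, j], edit_distance(enc$codes[i, ], enc$codes[j, ]))
  # identical codes give a zero matrix
  same <- list(c(1L, 0L, -1L), c(1L, 0L, -1L), c(1L, 0L, -1L))
  expect_true(all(pc_proximity(same) == 0))
  # unequal-length codes take the plain pairwise path
  uneq <- list(c(1L, 1L), c(1L, 1L, -1L), integer(0))
  Du <- pc_proximity(uneq)
  expect_equal(Du[1, 2], 1)
  expect_equal(Du[1, 3], 2)
  expect_equal(Du[2, 3], 3)
})

test_that("capacity arithmetic reports bits of a fixed-length code", {
  expect_equal(capacity_bits(2, 8), 8)
  expect_equal(capacity_bits(128, 60), 420)
  expect_error(capacity_bits(1, 5), "alphabet_size")
})
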