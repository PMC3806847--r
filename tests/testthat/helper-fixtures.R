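# Fixture builders ------------------------------------------------------

ramp_contour <- function(f0 = 1000, f1 = 2000, dur = 1, n = 11,
                         id = "ramp", ind = "indA") {
  t <- seq(0, dur, length.out = n)
  whistle_contour(t, seq(f0, f1, length.out = n), id, ind)
}

const_contour <- function(f = 5000, dur = 1, n = 11, id = "const", ind = "indA") {
  whistle_contour(seq(0, dur, length.out = n), rep(f, n), id, ind)
}

sine_contour <- function(f0 = 8000, amp = 2000, cycles = 2, dur = 1, n = 60,
                         id = "sine", ind = "indA", noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, dur, length.out = n)
  f <- f0 + amp * sin(2 * pi * cycles * t / dur) + stats::rnorm(n, 0, noise_sd)
  whistle_contour(t, pmax(f, 1), id, ind)
}

tiny_population <- function(n_ind = 6, n_w = 5, seed = 20130423, ...) {
  generate_population(population_config(n_individuals = n_ind,
                                        whistles_per_individual = n_w,
                                        seed = seed, ...))
}

# well-separated Gaussian blobs for clusterer recovery checks
blob_features <- function(n_classes = 20, per_class = 20, dim = 8,
                          center_sd = 100, spread = 1, seed = 1) {
  set.seed(seed)
  ctr <- matrix(stats::rnorm(n_classes * dim, sd = center_sd), n_classes, dim)
  X <- ctr[rep(seq_len(n_classes), each = per_class), ] +
    matrix(stats::rnorm(n_classes * per_class * dim, sd = spread),
           n_classes * per_class, dim)
  rownames(X) <- sprintf("p%03d", seq_len(nrow(X)))
  list(X = X, truth = rep(sprintf("c%02d", seq_len(n_classes)), each = per_class))
}

random_code <- function(len, n_levels = 3) {
  sample(c(-(n_levels:1), 0, 1:n_levels), len, replace = TRUE)
}

# Independent oracles ---------------------------------------------------

# exhaustive edit-script recursion (no memoisation, no DP table)
ed_oracle_exhaustive <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  sub <- ed_oracle_exhaustive(a[-1], b[-1]) + (a[1] != b[1])
  del <- ed_oracle_exhaustive(a[-1], b) + 1
  ins <- ed_oracle_exhaustive(a, b[-1]) + 1
  min(sub, del, ins)
}

# memoised top-down recursion (independent of the package's bottom-up DP)
ed_oracle_memo <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- min(rec(i - 1, j - 1) + (a[i] != b[j]),
             rec(i - 1, j) + 1, rec(i, j - 1) + 1)
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

# explicit enumeration of all monotone boundary-anchored warping paths
dtw_oracle_paths <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (i == n && j == m) { best <<- min(best, acc); return(invisible()) }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# memoised top-down DTW recursion
dtw_oracle_memo <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- (a[i] - b[j])^2
    v <- if (i == 1 && j == 1) cost
    else if (i == 1) cost + rec(i, j - 1)
    else if (j == 1) cost + rec(i - 1, j)
    else cost + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# direct double-summation NMI over the contingency table
nmi_oracle <- function(labels, truth) {
  ks <- unique(labels); cs <- unique(truth)
  N <- length(labels)
  I <- 0
  for (k in ks) for (c in cs) {
    nkc <- sum(labels == k & truth == c)
    if (nkc == 0) next
    nk <- sum(labels == k); nc <- sum(truth == c)
    I <- I + (nkc / N) * log(N * nkc / (nk * nc))
  }
  Hk <- 0
  for (k in ks) { p <- sum(labels == k) / N; Hk <- Hk - p * log(p) }
  Hc <- 0
  for (c in cs) { p <- sum(truth == c) / N; Hc <- Hc - p * log(p) }
  if (Hk + Hc == 0) return(1)
  I / ((Hk + Hc) / 2)
}
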