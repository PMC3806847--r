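test_that("NMI endpoints and degenerate conventions", {
  truth <- rep(c("a", "b", "c"), each = 4)
  expect_equal(nmi(truth, truth), 1)
  expect_equal(nmi(as.integer(factor(truth)) + 7, truth), 1)  # relabelled
  expect_equal(nmi(rep(1, 12), truth), 0)                     # one cluster
  expect_equal(nmi(c(1, 2, 1, 2), c("A", "A", "B", "B")), 0)  # independence
  expect_equal(nmi(rep(1, 5), rep("z", 5)), 1)                # both trivial
  expect_equal(nmi(1:5, rep("z", 5)), 0)                      # one trivial
  expect_error(nmi(1:3, c("a", "b")), "length")
})

test_that("NMI matches direct contingency summation on 1000 random label pairs", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    labels <- sample(1:sample(1:6, 1), n, replace = TRUE)
    truth <- sample(letters[1:sample(1:6, 1)], n, replace = TRUE)
    got <- nmi(labels, truth)
    expect_lt(abs(got - nmi_oracle(labels, truth)), 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("NMI is invariant to relabelling of clusters and classes", {
  set.seed(32)
  labels <- sample(1:5, 40, replace = TRUE)
  truth <- sample(letters[1:4], 40, replace = TRUE)
  base <- nmi(labels, truth)
  expect_equal(nmi(6 - labels, truth), base)
  expect_equal(nmi(labels, toupper(truth)), base)
})

test_that("bootstrap re-runs the pipeline on 80% subsamples", {
  pop <- tiny_population(4, 5)
  truth_pipe <- function(set) {
    cluster_assignment(whistle_ids(set), individual_ids(set))
  }
  rep1 <- bootstrap_nmi(truth_pipe, pop, n_boot = 25, seed = 7, method = "truth")
  expect_length(rep1$nmi_boot, 25L)
  expect_true(all(rep1$nmi_boot == 1))
  expect_equal(rep1$se, 0)
  expect_equal(rep1$nmi_point, 1)
  rep2 <- bootstrap_nmi(truth_pipe, pop, n_boot = 25, seed = 7, method = "truth")
  expect_identical(rep1$nmi_boot, rep2$nmi_boot)
  # subset size: 80% of 20 = 16 whistles per draw (after the full-set point fit)
  sizes <- integer(0)
  size_pipe <- function(set) {
    sizes <<- c(sizes, length(set))
    truth_pipe(set)
  }
  invisible(bootstrap_nmi(size_pipe, pop, n_boot = 2, seed = 1))
  expect_equal(sizes, c(20L, 16L, 16L))
  expect_error(bootstrap_nmi(truth_pipe, pop[1:2], n_boot = 2, frac = 0.5),
               "fewer than 2")
})

test_that("segment sweep degrades below ten segments and is degenerate at one", {
  pop <- tiny_population(6, 5, seed = 20130423)
  sw <- sweep_segments(pop, seg_range = c(1, 2, 10), clusterer = "kmeans",
                       n_levels = 3, k = 9, seed = 1)
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$nmi[sw$n_segments == 1], 0)
  expect_gt(sw$nmi[sw$n_segments == 10], sw$nmi[sw$n_segments == 2])
})

test_that("cluster sweep covers every metric x clusterer x k cell", {
  pop <- tiny_population(5, 4, seed = 20130423)
  sw <- sweep_clusters(pop, k_range = c(5, 10, 15),
                       metrics = c("npc", "random"),
                       clusterers = c("kmeans", "hierarchical"),
                       seed = 1)
  expect_equal(nrow(sw), 2 * 2 * 3)
  expect_true(all(sw$nmi >= 0 & sw$nmi <= 1))
  # the random control never beats the n-Parsons metric at any k
  for (k in c(5, 10, 15)) {
    best <- max(sw$nmi[sw$metric == "npc" & sw$k == k])
    worst <- max(sw$nmi[sw$metric == "random" & sw$k == k])
    expect_gt(best, worst)
  }
  # k = N is well-defined: singleton clusters score below 1
  swN <- sweep_clusters(pop, k_range = 20, metrics = "npc",
                        clusterers = "hierarchical", seed = 1)
  expect_lt(swN$nmi, 1)
  expect_gt(swN$nmi, 0)
})

test_that("Parsons-n sweep has one row per (n, clusterer) and n=1 equals pc", {
  pop <- tiny_population(5, 4, seed = 20130423)
  sw <- sweep_parsons_n(pop, n_range = 1:3,
                        clusterers = c("kmeans", "hierarchical"),
                        k = 8, seed = 1)
  expect_equal(nrow(sw), 6L)
  pc_pipe <- identity_pipeline(metric = "pc", clusterer = "kmeans", k = 8,
                               seed = 1)
  expect_equal(sw$nmi[sw$n_levels == 1 & sw$clusterer == "kmeans"],
               nmi(pc_pipe(pop), individual_ids(pop)))
  sw_b <- sweep_parsons_n(pop, n_range = 2, clusterers = "hierarchical",
                          k = 8, n_boot = 5, seed = 1)
  expect_false(is.na(sw_b$se))
})

test_that("ANOVA and Tukey letters separate methods as a hand calculation does", {
  mk <- function(method, vals) {
    structure(list(method = method, nmi_point = mean(vals), nmi_boot = vals,
                   se = sd(vals) / sqrt(length(vals))), class = "nmi_report")
  }
  # identical groups: F ~ 0, one shared letter
  same <- lapply(c("m1", "m2", "m3"), function(m) mk(m, c(0.5, 0.6, 0.7, 0.55)))
  cs <- compare_methods(same)
  expect_lt(cs$f, 1e-10)
  expect_true(all(cs$letters == cs$letters[1]))

  # three clearly separated groups: distinct letters, F matches the textbook formula
  g1 <- c(0.70, 0.72, 0.71, 0.69, 0.73)
  g2 <- c(0.50, 0.52, 0.49, 0.51, 0.48)
  g3 <- c(0.90, 0.91, 0.89, 0.92, 0.88)
  cm <- compare_methods(list(mk("pc", g1), mk("cm", g2), mk("art", g3)))
  all_vals <- c(g1, g2, g3)
  grand <- mean(all_vals)
  ssb <- 5 * sum((c(mean(g1), mean(g2), mean(g3)) - grand)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(cm$f, f_hand, tolerance = 1e-10)
  expect_equal(unname(cm$df), c(2L, 12L))
  expect_lt(cm$p, 0.001)
  expect_equal(length(unique(cm$letters)), 3L)
  expect_error(compare_methods(list(mk("only", g1))), "at least 2")
})
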