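#' Construct a cluster assignment
#'
#' Pairs each whistle id with a cluster label and, when available, with the
#' true individual identity, for scoring with [nmi()].
#'
#' @param ids Character vector of whistle ids.
#' @param labels Vector of cluster labels, same length as `ids`.
#' @param truth Optional vector of true class labels (individual ids).
#' @return An object of class `"cluster_assignment"` with elements `ids`,
#'   `labels` (integer, relabelled 1..k in order of first appearance),
#'   `truth`, and `k_effective` (number of non-empty clusters).
#' @export
cluster_assignment <- function(ids, labels, truth = NULL) {
  if (length(ids) != length(labels))
    stop("'ids' and 'labels' must have the same length", call. = FALSE)
  if (!is.null(truth) && length(truth) != length(ids))
    stop("'truth' must match 'ids' in length", call. = FALSE)
  labels <- match(labels, unique(labels))
  structure(list(ids = as.character(ids), labels = as.integer(labels),
                 truth = if (is.null(truth)) NULL else as.character(truth),
                 k_effective = length(unique(labels))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d whistles in %d clusters", length(x$ids),
              x$k_effective))
  if (!is.null(x$truth))
    cat(sprintf("; NMI vs truth = %.3f", nmi(x$labels, x$truth)))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.cluster_assignment <- function(x, ...) {
  data.frame(whistle_id = x$ids,
             individual_id = if (is.null(x$truth)) NA_character_ else x$truth,
             cluster = x$labels, stringsAsFactors = FALSE)
}

kmeanspp_init <- function(X, k) {
  N <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(N, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], N, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      centers[j + 1L] <- sample.int(N, 1L)
    } else {
      centers[j + 1L] <- sample.int(N, 1L, prob = d2)
    }
    nd <- rowSums((X - matrix(X[centers[j + 1L], ], N, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' k-means clustering of a whistle feature space
#'
#' Squared-Euclidean k-means with k-means++ seeding, best of `restarts`
#' restarts by total within-cluster sum of squares. Deterministic given
#' `seed`. The default of 30 groups is 50% more than the 20 individuals of
#' the balanced study design, allowing for some within-individual whistle
#' variation without trivialising the clustering task.
#'
#' @param features Numeric matrix, one row per whistle.
#' @param k Number of clusters (default 30), `<= nrow(features)`.
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A [cluster_assignment()].
#' @export
kmeans_cluster <- function(features, k = 30, seed = 1, restarts = 10) {
  if (!is.matrix(features)) features <- as.matrix(features)
  N <- nrow(features)
  k <- as.integer(k)
  if (k > N) stop("'k' cannot exceed the number of whistles", call. = FALSE)
  if (k < 1L) stop("'k' must be positive", call. = FALSE)
  ids <- rownames(features) %||% sprintf("w%d", seq_len(N))
  if (k == N)                              # every point its own cluster
    return(cluster_assignment(ids, seq_len(N)))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- NULL
    for (attempt in 1:5) {
      ctr <- features[kmeanspp_init(features, k), , drop = FALSE]
      if (anyDuplicated(ctr)) next
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(features, centers = ctr, iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed for every restart (too few distinct points for 'k'?)",
         call. = FALSE)
  cluster_assignment(ids, best$cluster)
}

#' Complete-linkage hierarchical clustering of a proximity matrix
#'
#' Agglomerative clustering using the complete ("longest-distance") linkage
#' rule, with the tree cut to exactly `k` clusters.
#'
#' @param prox Symmetric proximity matrix with zero diagonal.
#' @param k Number of clusters to cut the tree into (default 30).
#' @return A [cluster_assignment()]; the `hclust` tree is attached as
#'   attribute `"tree"`.
#' @export
hierarchical_cluster <- function(prox, k = 30) {
  assert_proximity(prox)
  N <- nrow(prox)
  k <- as.integer(k)
  if (k > N) stop("'k' cannot exceed the number of whistles", call. = FALSE)
  tree <- stats::hclust(stats::as.dist(prox), method = "complete")
  labels <- stats::cutree(tree, k = k)
  out <- cluster_assignment(rownames(prox) %||% sprintf("w%d", seq_len(N)), labels)
  attr(out, "tree") <- tree
  out
}

#' Fuzzy ART clustering of a whistle feature space
#'
#' Unsupervised adaptive-resonance-theory network for continuous inputs.
#' Features are min-max scaled to \[0, 1\] per dimension and complement coded
#' (dimension doubled); patterns are presented in seed-shuffled order each
#' epoch. For each pattern, committed categories are ranked by the choice
#' function `T_j = |I ^ w_j| / (alpha + |w_j|)` (`^` = componentwise min) and
#' searched in that order; the first category passing the vigilance test
#' `|I ^ w_j| / |I| >= rho` resonates and learns
#' `w <- beta (I ^ w) + (1 - beta) w`. If every committed category fails
#' vigilance, a new category is committed. Presentation repeats until the
#' assignment is stable or `max_epochs` is reached. Higher vigilance demands
#' closer matches and yields more, tighter categories; `rho = 0` collapses
#' everything into the first category and `rho = 1` gives one category per
#' distinct input.
#'
#' @param features Numeric matrix of finite values, one row per whistle.
#' @param vigilance Vigilance `rho` in \[0, 1\].
#' @param learning_rate Learning fraction `beta` in (0, 1\]; 1 = fast
#'   learning.
#' @param choice_alpha Small positive choice parameter `alpha`.
#' @param max_epochs Maximum presentation epochs.
#' @param seed Integer seed for the presentation order.
#' @return A [cluster_assignment()] with the vigilance used attached as
#'   attribute `"vigilance"` and the number of epochs run as `"epochs"`.
#' @export
art_cluster <- function(features, vigilance, learning_rate = 1.0,
                        choice_alpha = 0.001, max_epochs = 50, seed = 1) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!all(is.finite(features))) stop("'features' must be finite", call. = FALSE)
  if (vigilance < 0 || vigilance > 1) stop("'vigilance' must be in [0, 1]", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1)
    stop("'learning_rate' must be in (0, 1]", call. = FALSE)
  N <- nrow(features); d <- ncol(features)
  lo <- apply(features, 2L, min); hi <- apply(features, 2L, max)
  span <- hi - lo
  X <- sweep(features, 2L, lo)
  X <- sweep(X, 2L, ifelse(span > 0, span, 1), "/")
  X[, span == 0] <- 0.5
  I <- cbind(X, 1 - X)                      # complement coding; |I| = d for all rows
  norm_I <- d
  W <- matrix(numeric(0), nrow = 0L, ncol = 2L * d)
  assign <- rep(NA_integer_, N)
  beta <- learning_rate
  eps <- 1e-12
  set.seed(seed)
  epochs_run <- 0L
  for (epoch in seq_len(max_epochs)) {
    epochs_run <- epoch
    changed <- FALSE
    for (i in sample.int(N)) {
      Ii <- I[i, ]
      if (nrow(W) == 0L) {
        W <- rbind(W, beta * Ii + (1 - beta))
        if (!identical(assign[i], 1L)) changed <- TRUE
        assign[i] <- 1L
        next
      }
      inter <- rowSums(pmin(W, matrix(Ii, nrow(W), 2L * d, byrow = TRUE)))
      Tj <- inter / (choice_alpha + rowSums(W))
      match_j <- inter / norm_I
      ord <- order(-Tj)                     # stable: ties go to the older category
      win <- 0L
      for (j in ord) {
        if (match_j[j] >= vigilance - eps) { win <- j; break }
      }
      if (win == 0L) {
        W <- rbind(W, beta * Ii + (1 - beta))
        win <- nrow(W)
      } else {
        W[win, ] <- beta * pmin(Ii, W[win, ]) + (1 - beta) * W[win, ]
      }
      if (!identical(assign[i], win)) changed <- TRUE
      assign[i] <- win
    }
    if (!changed) break
  }
  out <- cluster_assignment(rownames(features) %||% sprintf("w%d", seq_len(N)),
                            assign)
  attr(out, "vigilance") <- vigilance
  attr(out, "epochs") <- epochs_run
  out
}

#' Fuzzy ART tuned to a target number of clusters
#'
#' The vigilance parameter controls category granularity but maps to a
#' cluster count only indirectly. This wrapper bisects vigilance in \[0, 1\]
#' to bring the effective number of categories as close as possible to
#' `target_k`, so ART partitions are comparable with the fixed-`k` k-means
#' and hierarchical partitions.
#'
#' @param features Numeric feature matrix.
#' @param target_k Desired number of clusters (default 30).
#' @param max_iter Bisection iterations (default 20).
#' @param ... Passed on to [art_cluster()] (`learning_rate`, `choice_alpha`,
#'   `max_epochs`).
#' @param seed Integer seed.
#' @return The best [cluster_assignment()] found, with attributes
#'   `"vigilance"` and `"history"` (data frame of vigilance / k pairs
#'   explored). A message is emitted when `target_k` is not attained exactly.
#' @export
art_cluster_target_k <- function(features, target_k = 30, max_iter = 20,
                                 seed = 1, ...) {
  target_k <- as.integer(target_k)
  lo <- 0; hi <- 1
  best <- NULL; best_gap <- Inf
  hist_v <- numeric(0); hist_k <- integer(0)
  for (it in seq_len(max_iter)) {
    v <- (lo + hi) / 2
    a <- art_cluster(features, vigilance = v, seed = seed, ...)
    k <- a$k_effective
    hist_v <- c(hist_v, v); hist_k <- c(hist_k, k)
    gap <- abs(k - target_k)
    if (gap < best_gap) { best <- a; best_gap <- gap }
    if (k == target_k) break
    if (k < target_k) lo <- v else hi <- v
  }
  if (best_gap > 0)
    message(sprintf("art_cluster_target_k: closest attainable k is %d (target %d)",
                    best$k_effective, target_k))
  attr(best, "history") <- data.frame(vigilance = hist_v, k = hist_k)
  best
}
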