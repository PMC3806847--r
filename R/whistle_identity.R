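METRICS <- c("pc", "npc", "cm", "dtw", "random")
CLUSTERERS <- c("kmeans", "hierarchical", "art")

# proximity matrix and feature space for one metric; features are NULL until
# needed (hierarchical clustering consumes the proximity directly)
metric_matrices <- function(set, metric, n_segments = 10, n_levels = 3,
                            n_samples = 60, d = 16, seed = 1,
                            constant_tol = NULL, alphabet = NULL,
                            normalize_dtw = FALSE) {
  metric <- match.arg(metric, METRICS)
  N <- length(set)
  d <- min(d, N - 1L)
  feats <- NULL
  prox <- switch(metric,
    pc = pc_proximity(encode_set(set, n_segments = n_segments, n_levels = 1,
                                 constant_tol = constant_tol,
                                 alphabet = alphabet)),
    npc = pc_proximity(encode_set(set, n_segments = n_segments,
                                  n_levels = n_levels,
                                  constant_tol = constant_tol,
                                  alphabet = alphabet)),
    cm = {
      feats <- cm_features(set, n_samples = n_samples)
      euclidean_proximity(feats)
    },
    dtw = dtw_proximity(set, n_samples = n_samples, normalize = normalize_dtw),
    random = random_proximity(N, seed = seed, ids = whistle_ids(set))
  )
  list(metric = metric, prox = prox, features = feats, d = d, seed = seed)
}

# run one clusterer on the matrices produced by metric_matrices(); feature
# consumers (k-means, ART) fall back to a classical MDS embedding of the
# proximity when the metric has no native feature space
cluster_with <- function(mat, clusterer, k = 30, seed = 1, vigilance = NULL,
                         ...) {
  clusterer <- match.arg(clusterer, CLUSTERERS)
  N <- nrow(mat$prox)
  k <- min(k, N)
  if (max(mat$prox) == 0) {
    # degenerate metric (e.g. single-segment Parsons codes): one cluster
    return(cluster_assignment(rownames(mat$prox), rep(1L, N)))
  }
  if (clusterer == "hierarchical") return(hierarchical_cluster(mat$prox, k = k))
  feats <- mat$features
  if (is.null(feats)) feats <- mds_embed(mat$prox, d = mat$d)
  if (clusterer == "kmeans") return(kmeans_cluster(feats, k = k, seed = seed))
  if (is.null(vigilance))
    art_cluster_target_k(feats, target_k = k, seed = seed, ...)
  else
    art_cluster(feats, vigilance = vigilance, seed = seed, ...)
}

#' Build a reusable metric + clustering pipeline
#'
#' Returns a function mapping any [contour_set()] to a
#' [cluster_assignment()], running the chosen similarity metric and
#' clustering algorithm with fixed parameters. This is the unit that the
#' bootstrap and the sensitivity sweeps re-run on subsets; Parsons alphabet
#' thresholds are refit inside each subset by default (pass `alphabet` to
#' freeze them).
#'
#' @param metric One of `"pc"` (plain Parsons), `"npc"` (n-Parsons), `"cm"`
#'   (correlation metric), `"dtw"`, `"random"` (seeded control).
#' @param clusterer One of `"kmeans"`, `"hierarchical"`, `"art"`.
#' @param n_segments Parsons segments per whistle (default 10).
#' @param n_levels Magnitude levels for `"npc"` (default 3).
#' @param k Number of clusters (default 30; ART is tuned towards it by
#'   vigilance bisection unless `vigilance` is given).
#' @param n_samples Resampling length for `"cm"` and `"dtw"` (default 60).
#' @param d MDS embedding dimension for feature-space clusterers on
#'   proximity-only metrics (default 16).
#' @param seed Integer seed for all stochastic stages.
#' @param constant_tol Parsons constant-change tolerance (Hz); `NULL` uses
#'   the set's `freq_resolution`.
#' @param alphabet Optional frozen [fit_alphabet()] result.
#' @param vigilance Optional fixed ART vigilance (bypasses the target-k
#'   search).
#' @return A function of one argument (a `contour_set`) returning a
#'   `cluster_assignment`.
#' @export
identity_pipeline <- function(metric = "npc", clusterer = "kmeans",
                              n_segments = 10, n_levels = 3, k = 30,
                              n_samples = 60, d = 16, seed = 1,
                              constant_tol = NULL, alphabet = NULL,
                              vigilance = NULL) {
  metric <- match.arg(metric, METRICS)
  clusterer <- match.arg(clusterer, CLUSTERERS)
  force(n_segments); force(n_levels); force(k); force(n_samples); force(d)
  force(seed); force(constant_tol); force(alphabet); force(vigilance)
  function(set) {
    mat <- metric_matrices(set, metric, n_segments = n_segments,
                           n_levels = n_levels, n_samples = n_samples, d = d,
                           seed = seed, constant_tol = constant_tol,
                           alphabet = alphabet)
    cluster_with(mat, clusterer, k = k, seed = seed, vigilance = vigilance)
  }
}

#' Fit a whistle identity-recovery model
#'
#' The front door of the package: encodes a set of signature-whistle
#' contours under one similarity metric, partitions the whistles with one
#' clustering algorithm, and (when true individual identities are present)
#' scores how much identity information the metric preserved, by normalised
#' mutual information, optionally with a subsample bootstrap.
#'
#' Metrics: `"pc"` - plain Parsons code (up/down/constant per segment
#' transition) compared by Levenshtein edit distance; `"npc"` - n-Parsons
#' code with `n_levels` magnitude classes per direction (default 3, a
#' 7-symbol alphabet); `"cm"` - correlation metric (60-point resampling,
#' correlation-matrix PCA with Kaiser retention, Euclidean distance);
#' `"dtw"` - dynamic time warping of 60-point resampled contours;
#' `"random"` - seeded random proximity control.
#'
#' Clusterers: `"kmeans"` (k-means++ restarts on the feature space),
#' `"hierarchical"` (complete linkage on the proximity matrix), `"art"`
#' (fuzzy ART on the feature space, vigilance tuned towards `k` categories).
#' Proximity-only metrics are embedded by classical MDS (dimension `d`)
#' for the feature-space clusterers.
#'
#' @inheritParams identity_pipeline
#' @param contours A [contour_set()], e.g. from [read_contours()] or
#'   [generate_population()].
#' @param n_boot Bootstrap iterations (default 0 = none); each draws 80% of
#'   the whistles without replacement and re-runs the whole pipeline.
#' @param frac Bootstrap subsample fraction (default 0.8).
#' @return An object of class `"whistle_identity"` with components `call`,
#'   `metric`, `clusterer`, `params`, `proximity`, `features` (may be
#'   `NULL`), `assignment`, `truth`, `nmi` (`NA` without truth labels), and
#'   `bootstrap` (an `nmi_report` or `NULL`).
#' @examples
#' pop <- generate_population(population_config(n_individuals = 5,
#'                                              whistles_per_individual = 5))
#' fit <- whistle_identity(pop, metric = "npc", clusterer = "hierarchical",
#'                         k = 7)
#' print(fit)
#' @export
whistle_identity <- function(contours, metric = c("npc", "pc", "cm", "dtw", "random"),
                             clusterer = c("kmeans", "hierarchical", "art"),
                             n_segments = 10, n_levels = 3, k = 30,
                             n_samples = 60, d = 16, seed = 1,
                             constant_tol = NULL, alphabet = NULL,
                             vigilance = NULL, n_boot = 0, frac = 0.8) {
  stopifnot(inherits(contours, "contour_set"))
  metric <- match.arg(metric)
  clusterer <- match.arg(clusterer)
  mat <- metric_matrices(contours, metric, n_segments = n_segments,
                         n_levels = n_levels, n_samples = n_samples, d = d,
                         seed = seed, constant_tol = constant_tol,
                         alphabet = alphabet)
  assignment <- cluster_with(mat, clusterer, k = k, seed = seed,
                             vigilance = vigilance)
  truth <- individual_ids(contours)
  have_truth <- !all(is.na(truth))
  score <- if (have_truth) nmi(assignment, truth) else NA_real_
  boot <- NULL
  if (n_boot > 0) {
    if (!have_truth) stop("bootstrap scoring needs individual_id truth labels",
                          call. = FALSE)
    pipe <- identity_pipeline(metric = metric, clusterer = clusterer,
                              n_segments = n_segments, n_levels = n_levels,
                              k = k, n_samples = n_samples, d = d, seed = seed,
                              constant_tol = constant_tol, alphabet = alphabet,
                              vigilance = vigilance)
    boot <- bootstrap_nmi(pipe, contours, n_boot = n_boot, frac = frac,
                          seed = seed,
                          method = sprintf("%s/%s", metric, clusterer))
  }
  structure(list(call = match.call(), metric = metric, clusterer = clusterer,
                 params = list(n_segments = n_segments, n_levels = n_levels,
                               k = k, n_samples = n_samples, d = d,
                               seed = seed),
                 proximity = mat$prox, features = mat$features,
                 assignment = assignment,
                 truth = if (have_truth) truth else NULL,
                 nmi = score, bootstrap = boot),
            class = "whistle_identity")
}

#' @export
print.whistle_identity <- function(x, ...) {
  cat("Whistle identity-recovery model\n")
  cat(sprintf("  metric: %s   clusterer: %s   whistles: %d   clusters: %d\n",
              x$metric, x$clusterer, length(x$assignment$ids),
              x$assignment$k_effective))
  if (!is.na(x$nmi))
    cat(sprintf("  NMI vs individual identity: %.3f\n", x$nmi))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap (n = %d, 80%% subsamples): mean %.3f +/- %.4f SE\n",
                length(x$bootstrap$nmi_boot), mean(x$bootstrap$nmi_boot),
                x$bootstrap$se))
  invisible(x)
}

#' @export
summary.whistle_identity <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$truth)) {
    tab <- table(cluster = x$assignment$labels, individual = x$truth)
    purity <- sum(apply(tab, 1L, max)) / sum(tab)
    cat(sprintf("  cluster purity: %.3f; individuals: %d\n", purity,
                length(unique(x$truth))))
  }
  cat(sprintf("  parameters: %s\n",
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
coef.whistle_identity <- function(object, ...) {
  stats::setNames(object$assignment$labels, object$assignment$ids)
}

#' Plot a whistle identity-recovery model
#'
#' Shows the proximity matrix as an image with whistles ordered by true
#' individual (block structure on the diagonal indicates identity
#' information preserved by the metric), or the bootstrap NMI distribution
#' when one was computed.
#'
#' @param x A [whistle_identity()] fit.
#' @param which `"proximity"` or `"bootstrap"`.
#' @param ... Further graphical parameters.
#' @export
plot.whistle_identity <- function(x, which = c("proximity", "bootstrap"), ...) {
  which <- match.arg(which)
  if (which == "bootstrap") {
    if (is.null(x$bootstrap)) stop("no bootstrap stored in this fit", call. = FALSE)
    graphics::boxplot(x$bootstrap$nmi_boot, ylab = "NMI",
                      main = sprintf("%s / %s bootstrap", x$metric, x$clusterer),
                      ...)
    return(invisible(x))
  }
  ord <- if (!is.null(x$truth)) order(x$truth) else seq_len(nrow(x$proximity))
  m <- x$proximity[ord, ord]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m)[, rev(seq_len(nrow(m)))],
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "whistle (by individual)", ylab = "whistle",
                  main = sprintf("%s proximity", x$metric), axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' Export a proximity matrix to labelled square CSV
#' @param prox Symmetric proximity matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proximity <- function(prox, path) {
  assert_proximity(prox)
  utils::write.csv(as.data.frame(prox), path, row.names = TRUE)
  invisible(path)
}

#' Read a proximity matrix from labelled square CSV
#' @param path CSV written by [write_proximity()].
#' @return Symmetric matrix with id dimnames.
#' @export
read_proximity <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  m <- (m + t(m)) / 2                     # absorb CSV round-off
  diag(m) <- 0
  assert_proximity(m)
}
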