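#' Normalised mutual information between a clustering and true classes
#'
#' Measures how well a cluster partition matches the true identity classes:
#' `NMI = I(clusters; classes) / ((H(clusters) + H(classes)) / 2)`, where
#' `I` is the mutual information of the cluster-by-class contingency table
#' and `H` are the label entropies (the log base cancels in the ratio; the
#' arithmetic-mean normalisation keeps the score in \[0, 1\]). NMI is near 1
#' when each cluster contains a single class, near 0 for random clusters,
#' and invariant to relabelling of either partition. A class split over a
#' few clusters still scores high, but the score is maximal when the number
#' of clusters matches the number of classes.
#'
#' Degenerate cases: when both partitions are the same trivial single-class
#' partition the score is 1; when only one partition is trivial the mutual
#' information is 0 and so is the score.
#'
#' @param labels Cluster labels, or a [cluster_assignment()] (in which case
#'   its stored truth is used unless `truth` is given).
#' @param truth True class labels, same length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(labels, truth = NULL) {
  if (inherits(labels, "cluster_assignment")) {
    if (is.null(truth)) truth <- labels$truth
    labels <- labels$labels
  }
  if (is.null(truth)) stop("'truth' labels are required", call. = FALSE)
  if (length(labels) != length(truth))
    stop("'labels' and 'truth' must have the same length", call. = FALSE)
  if (!length(labels)) stop("empty label vectors", call. = FALSE)
  tab <- table(labels, truth)
  N <- sum(tab)
  pk <- rowSums(tab) / N
  pc <- colSums(tab) / N
  Hk <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  Hc <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  denom <- (Hk + Hc) / 2
  if (denom == 0) return(1)               # both partitions trivial
  p <- tab / N
  ex <- outer(pk, pc)
  nz <- p > 0
  I <- sum(p[nz] * log(p[nz] / ex[nz]))
  min(max(I / denom, 0), 1)
}

#' Subsample bootstrap of the clustering NMI
#'
#' Quantifies the stability of a metric + clustering pipeline: each of
#' `n_boot` iterations draws a uniform random subset of `floor(frac * N)`
#' whistles without replacement, re-runs the full pipeline (encoding /
#' proximity / clustering) on the subset, and scores the resulting partition
#' against the true identities. The default 100 draws at 80% give the NMI
#' population from which the standard error is reported.
#'
#' @param pipeline Function mapping a [contour_set()] subset to a
#'   [cluster_assignment()]; see [identity_pipeline()].
#' @param contours A [contour_set()] with `individual_id` truth labels.
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param frac Subsample fraction (default 0.8).
#' @param seed Integer seed.
#' @param method Optional label stored in the report.
#' @return An object of class `"nmi_report"`: list with `method`,
#'   `nmi_point` (pipeline on the full set), `nmi_boot` (length `n_boot`),
#'   and `se` (`sd(nmi_boot) / sqrt(n_boot)`).
#' @export
bootstrap_nmi <- function(pipeline, contours, n_boot = 100, frac = 0.8,
                          seed = 1, method = "pipeline") {
  stopifnot(inherits(contours, "contour_set"))
  N <- length(contours)
  m <- floor(frac * N)
  if (m < 2L) stop("subsample would have fewer than 2 whistles", call. = FALSE)
  truth_all <- individual_ids(contours)
  point <- nmi(pipeline(contours), truth_all)
  set.seed(seed)
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (attempt in 1:3) {
      idx <- sample.int(N, m)
      sub <- contours[idx]
      a <- tryCatch(pipeline(sub), error = function(e) e)
      if (!inherits(a, "error")) { ok <- TRUE; break }
      warning(sprintf("bootstrap iteration %d failed (%s); redrawing", b,
                      conditionMessage(a)))
    }
    if (!ok) stop(sprintf("bootstrap iteration %d failed after 3 redraws", b),
                  call. = FALSE)
    vals[b] <- nmi(a, truth_all[a$ids])
  }
  structure(list(method = method, nmi_point = point, nmi_boot = vals,
                 se = stats::sd(vals) / sqrt(n_boot)),
            class = "nmi_report")
}

#' @export
print.nmi_report <- function(x, ...) {
  cat(sprintf("<nmi_report> %s: NMI = %.3f (bootstrap mean %.3f +/- %.4f SE, n = %d)\n",
              x$method, x$nmi_point, mean(x$nmi_boot), x$se, length(x$nmi_boot)))
  invisible(x)
}

#' Sensitivity of clustering NMI to the number of Parsons segments
#'
#' Re-runs the Parsons pipeline while the number of equal time segments is
#' varied (the original design swept 1 to 25). One segment yields empty
#' codes, hence identical whistles, a single cluster and NMI 0; too many
#' segments converge on the continuous-time analysis. Ten segments is the
#' compromise used as the default elsewhere.
#'
#' @param contours A [contour_set()] with truth labels.
#' @param seg_range Integer vector of segment counts (default `1:25`).
#' @param clusterer One of `"kmeans"`, `"hierarchical"`, `"art"`.
#' @param n_levels Parsons magnitude levels (default 1).
#' @param k Cluster count (default 30, capped at the set size).
#' @param seed Integer seed.
#' @return Data frame with columns `n_segments`, `nmi`.
#' @export
sweep_segments <- function(contours, seg_range = 1:25, clusterer = "kmeans",
                           n_levels = 1, k = 30, seed = 1) {
  stopifnot(inherits(contours, "contour_set"))
  vals <- vapply(seg_range, function(s) {
    pipe <- identity_pipeline(metric = if (n_levels > 1) "npc" else "pc",
                              clusterer = clusterer, n_segments = s,
                              n_levels = n_levels, k = k, seed = seed)
    nmi(pipe(contours), individual_ids(contours))
  }, numeric(1))
  data.frame(n_segments = as.integer(seg_range), nmi = vals)
}

#' Sensitivity of clustering NMI to the number of clusters
#'
#' Sweeps the cluster count (the original design used 5 to 50) for every
#' requested metric and clustering algorithm, reporting NMI against the true
#' identities for each combination.
#'
#' @param contours A [contour_set()] with truth labels.
#' @param k_range Integer vector of cluster counts (default `seq(5, 50, 5)`).
#' @param metrics Subset of `c("pc", "npc", "cm", "dtw", "random")`.
#' @param clusterers Subset of `c("kmeans", "hierarchical", "art")`.
#' @param n_segments,n_levels,n_samples,d Pipeline parameters; see
#'   [identity_pipeline()].
#' @param seed Integer seed.
#' @return Tidy data frame with columns `metric`, `clusterer`, `k`, `nmi`.
#' @export
sweep_clusters <- function(contours, k_range = seq(5, 50, 5),
                           metrics = c("pc", "npc", "cm", "dtw", "random"),
                           clusterers = c("kmeans", "hierarchical", "art"),
                           n_segments = 10, n_levels = 3, n_samples = 60,
                           d = 16, seed = 1) {
  stopifnot(inherits(contours, "contour_set"))
  truth <- individual_ids(contours)
  N <- length(contours)
  rows <- list()
  for (metric in metrics) {
    mat <- metric_matrices(contours, metric, n_segments = n_segments,
                           n_levels = n_levels, n_samples = n_samples,
                           d = d, seed = seed)
    for (cl in clusterers) for (k in k_range) {
      if (k > N) next
      a <- cluster_with(mat, cl, k = k, seed = seed)
      rows[[length(rows) + 1L]] <-
        data.frame(metric = metric, clusterer = cl, k = as.integer(k),
                   nmi = nmi(a, truth))
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity of clustering NMI to the Parsons level n
#'
#' Sweeps the number of magnitude levels per direction (`n = 1` is the plain
#' up/down/constant Parsons code; each increment refines the magnitude
#' binning, base `2n + 1`). Identity recovery typically rises sharply at
#' `n = 2` and saturates around `n = 3` or `4`, motivating `n = 3` as the
#' default optimum.
#'
#' @param contours A [contour_set()] with truth labels.
#' @param n_range Integer vector of Parsons levels (default `1:5`).
#' @param clusterers Subset of `c("kmeans", "hierarchical", "art")`.
#' @param n_segments,k Pipeline parameters.
#' @param n_boot Bootstrap iterations per cell for a standard error (0 = no
#'   bootstrap, `se` is `NA`).
#' @param frac Bootstrap subsample fraction.
#' @param seed Integer seed.
#' @return Tidy data frame with columns `n_levels`, `clusterer`, `nmi`, `se`.
#' @export
sweep_parsons_n <- function(contours, n_range = 1:5,
                            clusterers = c("kmeans", "hierarchical", "art"),
                            n_segments = 10, k = 30, n_boot = 0, frac = 0.8,
                            seed = 1) {
  stopifnot(inherits(contours, "contour_set"))
  truth <- individual_ids(contours)
  rows <- list()
  for (n in n_range) for (cl in clusterers) {
    pipe <- identity_pipeline(metric = "npc", clusterer = cl,
                              n_segments = n_segments, n_levels = n, k = k,
                              seed = seed)
    if (n_boot > 0) {
      rep <- bootstrap_nmi(pipe, contours, n_boot = n_boot, frac = frac,
                           seed = seed, method = sprintf("%d-Parsons/%s", n, cl))
      val <- rep$nmi_point; se <- rep$se
    } else {
      val <- nmi(pipe(contours), truth); se <- NA_real_
    }
    rows[[length(rows) + 1L]] <-
      data.frame(n_levels = as.integer(n), clusterer = cl, nmi = val, se = se)
  }
  do.call(rbind, rows)
}

#' Compare bootstrap NMI populations across methods
#'
#' One-way ANOVA across the bootstrap NMI populations of several
#' metric/clusterer combinations, followed by Tukey HSD pairwise post-hoc
#' tests and a compact letter display (methods sharing a letter do not
#' differ at level `alpha`). Note the bootstrap values are resampled, not
#' independent, observations; the comparison mirrors the original analysis
#' and should be read as descriptive.
#'
#' @param reports List of [bootstrap_nmi()] reports (>= 2, each with >= 2
#'   values).
#' @param alpha Significance level for the Tukey tests (default 0.05).
#' @return An object of class `"method_comparison"`: list with `anova`
#'   (data frame), `f`, `df`, `p`, `tukey` (Tukey HSD table), `letters`
#'   (named character vector), `means`, `alpha`.
#' @export
compare_methods <- function(reports, alpha = 0.05) {
  if (inherits(reports, "nmi_report")) reports <- list(reports)
  if (length(reports) < 2L) stop("need at least 2 reports", call. = FALSE)
  ok <- vapply(reports, inherits, logical(1), what = "nmi_report")
  if (!all(ok)) stop("'reports' must be bootstrap_nmi() results", call. = FALSE)
  nm <- vapply(reports, `[[`, character(1), "method")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(method = nm[i], nmi = reports[[i]]$nmi_boot)
  }))
  if (any(table(df$method) < 2L))
    stop("each report needs at least 2 bootstrap values", call. = FALSE)
  df$method <- factor(df$method)
  fit <- stats::aov(nmi ~ method, data = df)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$method
  # pairwise p-value matrix from the Tukey table
  k <- nlevels(df$method)
  lev <- levels(df$method)
  P <- matrix(1, k, k, dimnames = list(lev, lev))
  combos <- utils::combn(lev, 2L)
  for (i in seq_len(nrow(tk))) {
    rn <- rownames(tk)[i]
    hit <- which(paste(combos[2L, ], combos[1L, ], sep = "-") == rn |
                   paste(combos[1L, ], combos[2L, ], sep = "-") == rn)[1L]
    a <- combos[1L, hit]; b <- combos[2L, hit]
    P[a, b] <- P[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(df$nmi, df$method, mean)
  letters <- letter_display(P < alpha, order(-means))
  structure(list(anova = an, f = an$`F value`[1L], df = an$Df,
                 p = an$`Pr(>F)`[1L], tukey = tk, letters = letters,
                 means = means, alpha = alpha),
            class = "method_comparison")
}

# compact letter display by insert-and-absorb on a logical "differs" matrix;
# group_order gives the display order (typically by decreasing mean)
letter_display <- function(differs, group_order = seq_len(nrow(differs))) {
  k <- nrow(differs)
  nm <- rownames(differs)
  cols <- list(seq_len(k))                 # start: one letter shared by all
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!differs[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (i %in% col && j %in% col) {
        cols[[ci]] <- setdiff(col, i)
        cols[[length(cols) + 1L]] <- setdiff(col, j)
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b)) keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letters so the first letter marks the top-ranked group
  first_rank <- vapply(cols, function(col) min(match(col, group_order)), numeric(1))
  cols <- cols[order(first_rank)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  names(out) <- nm
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> one-way ANOVA: F(%d,%d) = %.4g, p = %.3g\n",
              x$df[1L], x$df[2L], x$f, x$p))
  cat(sprintf("Tukey HSD compact letter display (alpha = %g):\n", x$alpha))
  ord <- order(-x$means)
  for (i in ord)
    cat(sprintf("  %-24s mean NMI %.3f  %s\n", names(x$means)[i], x$means[i],
                x$letters[names(x$means)[i]]))
  invisible(x)
}
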