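assert_proximity <- function(m, what = "proximity matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  if (any(abs(diag(m)) > 1e-8))
    stop(sprintf("%s must have a zero diagonal", what), call. = FALSE)
  if (any(m < -1e-8))
    stop(sprintf("%s must be non-negative", what), call. = FALSE)
  invisible(m)
}

#' Correlation-metric (CM) feature space of a whistle set
#'
#' The correlation metric of fixed-point sampling: each whistle is resampled
#' at `n_samples` equally spaced time points; the sample columns are
#' standardised to zero mean and unit variance; principal component analysis
#' of the standardised matrix (i.e. of the correlation matrix of the sampled
#' frequencies) retains the components whose eigenvalues exceed `eigen_min`
#' (the Kaiser criterion, meaningful for correlation-matrix PCA). The number
#' of retained dimensions is therefore data dependent; on the original
#' 400-whistle study design the rule retained 16 dimensions.
#'
#' @param set A [contour_set()].
#' @param n_samples Equally spaced sample points per whistle (default 60).
#' @param eigen_min Eigenvalue cut-off for retaining components (default 1.0).
#' @return Numeric score matrix, one row per whistle (rownames =
#'   `whistle_id`), one column per retained component; the full eigenvalue
#'   spectrum is attached as attribute `"eigenvalues"`.
#' @export
cm_features <- function(set, n_samples = 60, eigen_min = 1.0) {
  stopifnot(inherits(set, "contour_set"))
  if (length(set) < 2L) stop("need at least 2 contours", call. = FALSE)
  X <- resample_set(set, n_samples)
  sds <- apply(X, 2L, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance sample column(s) before standardisation",
                    sum(zero)))
    X <- X[, !zero, drop = FALSE]
  }
  if (ncol(X) < 1L) {
    # every whistle identical at this sampling: a single degenerate dimension
    out <- matrix(0, nrow = length(set), ncol = 1L,
                  dimnames = list(whistle_ids(set), NULL))
    attr(out, "eigenvalues") <- numeric(0)
    return(out)
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pca$sdev^2
  keep <- which(eig > eigen_min)
  if (!length(keep)) keep <- 1L
  scores <- pca$x[, keep, drop = FALSE]
  rownames(scores) <- whistle_ids(set)
  attr(scores, "eigenvalues") <- eig
  scores
}

#' Euclidean-distance proximity matrix of a feature space
#'
#' @param features Numeric matrix, one row per whistle (rownames taken as
#'   whistle ids).
#' @return Symmetric matrix of pairwise Euclidean distances, zero diagonal.
#' @export
euclidean_proximity <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  D <- as.matrix(stats::dist(features))
  diag(D) <- 0
  assert_proximity(D)
}

#' Dynamic time warping distance between two frequency profiles
#'
#' Minimum accumulated squared frequency difference over monotone,
#' boundary-anchored warping paths with steps (1,0), (0,1) and (1,1) and no
#' warping window, found by dynamic programming. Warping lets salient
#' features (peaks, inflections) that occur at slightly different times line
#' up, so the distance is robust to local tempo differences between
#' renditions of the same whistle.
#'
#' @param a,b Numeric frequency vectors (Hz), length >= 1, not necessarily
#'   equal length.
#' @param normalize If `TRUE` divide the accumulated cost by the length of
#'   the optimal path (off by default; the raw accumulated cost is the
#'   minimal reading of a least-squares warping distance).
#' @return Non-negative number; 0 for identical profiles (up to duplicated
#'   samples, which warping absorbs).
#' @export
dtw_distance <- function(a, b, normalize = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop("inputs must have length >= 1", call. = FALSE)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  if (normalize) {
    P <- matrix(0L, n + 1L, m + 1L)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      cost <- (a[i] - b[j])^2
      three <- c(D[i, j + 1L], D[i + 1L, j], D[i, j])
      w <- which.min(three)
      D[i + 1L, j + 1L] <- cost + three[w]
      P[i + 1L, j + 1L] <- 1L + c(P[i, j + 1L], P[i + 1L, j], P[i, j])[w]
    }
    return(D[n + 1L, m + 1L] / P[n + 1L, m + 1L])
  }
  for (i in seq_len(n)) {
    Dij <- D[i, ]
    cur <- D[i + 1L, ]
    ai <- a[i]
    for (j in seq_len(m)) {
      cur[j + 1L] <- (ai - b[j])^2 + min(Dij[j], Dij[j + 1L], cur[j])
    }
    D[i + 1L, ] <- cur
  }
  D[n + 1L, m + 1L]
}

#' Pairwise DTW proximity matrix of a whistle set
#'
#' Each contour is resampled to `n_samples` equally spaced points over its
#' own duration and every pair is compared with [dtw_distance()]. All pairs
#' share a sequence length, so the dynamic programme is run for all pairs
#' simultaneously (vectorised over pairs), which makes the full 400x400
#' matrix of the balanced study design practical in seconds.
#'
#' @param set A [contour_set()].
#' @param n_samples Resampling length (default 60, matching the CM sampling
#'   so matrices are comparable across metrics).
#' @param normalize Divide each accumulated cost by its optimal path length.
#' @return Symmetric proximity matrix with zero diagonal.
#' @export
dtw_proximity <- function(set, n_samples = 60, normalize = FALSE) {
  stopifnot(inherits(set, "contour_set"))
  if (length(set) < 2L) stop("need at least 2 contours", call. = FALSE)
  X <- resample_set(set, n_samples)
  N <- nrow(X); L <- ncol(X)
  ids <- rownames(X)
  pr <- utils::combn(N, 2L)
  A <- X[pr[1L, ], , drop = FALSE]
  B <- X[pr[2L, ], , drop = FALSE]
  np <- ncol(pr)
  prev <- matrix(Inf, np, L + 1L); prev[, 1L] <- 0
  cur <- matrix(Inf, np, L + 1L)
  plen_prev <- plen_cur <- if (normalize) matrix(0L, np, L + 1L) else NULL
  for (i in seq_len(L)) {
    cur[, 1L] <- Inf
    ai <- A[, i]
    for (j in seq_len(L)) {
      cost <- (ai - B[, j])^2
      if (normalize) {
        c1 <- prev[, j + 1L]; c2 <- cur[, j]; c3 <- prev[, j]
        best <- pmin(c1, c2, c3)
        pl <- ifelse(best == c3, plen_prev[, j],
                     ifelse(best == c1, plen_prev[, j + 1L], plen_cur[, j]))
        cur[, j + 1L] <- cost + best
        plen_cur[, j + 1L] <- pl + 1L
      } else {
        cur[, j + 1L] <- cost + pmin(prev[, j + 1L], cur[, j], prev[, j])
      }
    }
    tmp <- prev; prev <- cur; cur <- tmp
    if (normalize) { tmp <- plen_prev; plen_prev <- plen_cur; plen_cur <- tmp }
  }
  d <- prev[, L + 1L]
  if (normalize) d <- d / plen_prev[, L + 1L]
  D <- matrix(0, N, N, dimnames = list(ids, ids))
  D[cbind(pr[1L, ], pr[2L, ])] <- d
  D[cbind(pr[2L, ], pr[1L, ])] <- d
  assert_proximity(D)
}

#' Classical (Torgerson) multidimensional scaling embedding
#'
#' Embeds a proximity matrix in a `d`-dimensional Euclidean feature space:
#' the squared-distance matrix is double-centred, eigendecomposed, and the
#' points are placed on the top `d` eigenvectors scaled by the square roots
#' of their eigenvalues. Negative eigenvalues (non-Euclidean proximities) are
#' clamped to zero, giving zero-padded dimensions, so a rank-`r` Euclidean
#' configuration embedded with `d > r` reproduces its distances exactly with
#' `d - r` zero columns. Needed because k-means and ART consume feature
#' vectors while the edit-distance and DTW metrics produce proximities.
#'
#' @param prox Symmetric proximity matrix with zero diagonal.
#' @param d Embedding dimension (default 16, the dimensionality used for the
#'   CM feature space), must be `< nrow(prox)`.
#' @return Numeric `N x d` matrix with the proximity's dimnames as rownames;
#'   the centred eigenvalue spectrum is attached as attribute
#'   `"eigenvalues"`.
#' @export
mds_embed <- function(prox, d = 16) {
  assert_proximity(prox)
  N <- nrow(prox)
  d <- as.integer(d)
  if (d < 1L) stop("'d' must be positive", call. = FALSE)
  if (d >= N) stop("'d' must be smaller than the number of points", call. = FALSE)
  D2 <- prox^2
  rm <- rowMeans(D2); gm <- mean(D2)
  B <- -(D2 - outer(rm, rep(1, N)) - outer(rep(1, N), rm) + gm) / 2
  e <- eigen(B, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  X <- e$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam[seq_len(d)]), d)
  rownames(X) <- rownames(prox)
  attr(X, "eigenvalues") <- e$values
  X
}

#' Seeded random proximity matrix (negative control)
#'
#' Independent uniform(0, 1) off-diagonal entries, symmetrised, zero
#' diagonal. Serves as the chance-level control against which the whistle
#' similarity metrics are judged; its feature-space counterpart is
#' `mds_embed(random_proximity(n, seed), 16)`.
#'
#' @param n Number of whistles (>= 2).
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @param ids Optional character vector of ids for the dimnames.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
random_proximity <- function(n, seed, ids = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("w%03d", seq_len(n))
  set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- stats::runif(n * (n - 1L) / 2L)
  m <- m + t(m)
  assert_proximity(m)
}
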