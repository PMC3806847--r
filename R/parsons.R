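#' Mean frequency of equally spaced contour segments
#'
#' Splits the whistle's duration into `n_segments` equal time intervals and
#' returns the mean frequency of the (piecewise-linear) contour over each
#' interval. The mean is the exact integral of the linear interpolant divided
#' by the interval width, not a point sample, so short segments on sparse
#' contours are still well defined.
#'
#' @param contour A [whistle_contour()].
#' @param n_segments Number of equal time segments (>= 1).
#' @return Numeric vector of `n_segments` mean frequencies in Hz.
#' @export
segment_means <- function(contour, n_segments) {
  stopifnot(inherits(contour, "whistle_contour"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("'n_segments' must be at least 1", call. = FALSE)
  t0 <- min(contour$time); t1 <- max(contour$time)
  breaks <- seq(t0, t1, length.out = n_segments + 1L)
  knots <- sort(unique(c(contour$time, breaks)))
  y <- stats::approx(contour$time, contour$freq, xout = knots)$y
  # cumulative trapezoid integral of the interpolant at each knot
  cum <- c(0, cumsum(diff(knots) * (y[-1] + y[-length(y)]) / 2))
  at_breaks <- cum[match(breaks, knots)]
  diff(at_breaks) / diff(breaks)
}

#' Fit an n-Parsons alphabet from pooled frequency changes
#'
#' The n-Parsons code classifies each segment-to-segment frequency change by
#' direction (rise/fall/constant) and by one of `n_levels` magnitude classes,
#' giving a `2 * n_levels + 1`-symbol alphabet. The top magnitude class
#' ("large rise" together with "large drop") is defined to contain the
#' `large_fraction` largest absolute changes pooled over the whole data set;
#' the remaining non-constant changes are split into `n_levels - 1`
#' equal-count magnitude bins. Magnitude boundaries are shared between rising
#' and falling directions.
#'
#' @param all_deltas Numeric vector of signed frequency changes (Hz) pooled
#'   over every transition of every whistle in the data set (constants
#'   included).
#' @param n_levels Number of magnitude levels per direction (the `n` of
#'   n-Parsons; `1` gives the plain up/down/constant code).
#' @param constant_tol Absolute changes at or below this tolerance (Hz) are
#'   coded "constant". Conventionally one spectrogram frequency bin; 0 for
#'   synthetic contours.
#' @param large_fraction Proportion of pooled changes assigned to the top
#'   magnitude class (default 0.10).
#' @return An object of class `"parsons_alphabet"`: list with `n_levels`,
#'   `constant_tol`, `magnitude_thresholds` (ascending, length
#'   `n_levels - 1`), and `size` (`2 * n_levels + 1`).
#' @export
fit_alphabet <- function(all_deltas, n_levels, constant_tol = 0,
                         large_fraction = 0.10) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("'n_levels' must be at least 1", call. = FALSE)
  if (large_fraction <= 0 || large_fraction >= 1)
    stop("'large_fraction' must be in (0, 1)", call. = FALSE)
  if (constant_tol < 0) stop("'constant_tol' must be non-negative", call. = FALSE)
  a <- abs(as.numeric(all_deltas))
  a <- a[is.finite(a)]
  if (!length(a)) stop("'all_deltas' is empty", call. = FALSE)
  if (all(a <= constant_tol))
    stop("degenerate alphabet: every pooled change is within 'constant_tol'",
         call. = FALSE)
  if (n_levels == 1L) {
    thr <- numeric(0)
  } else {
    top <- stats::quantile(a, 1 - large_fraction, names = FALSE, type = 7)
    if (top <= constant_tol)
      stop("degenerate alphabet: large-change threshold falls within 'constant_tol'",
           call. = FALSE)
    if (n_levels == 2L) {
      thr <- top
    } else {
      inner_vals <- a[a > constant_tol & a <= top]
      probs <- seq_len(n_levels - 2L) / (n_levels - 1L)
      inner <- stats::quantile(inner_vals, probs, names = FALSE, type = 7)
      thr <- c(inner, top)
    }
    if (any(diff(thr) <= 0))
      stop("degenerate alphabet: magnitude thresholds are not strictly ascending",
           call. = FALSE)
  }
  structure(list(n_levels = n_levels, constant_tol = constant_tol,
                 magnitude_thresholds = thr, size = 2L * n_levels + 1L),
            class = "parsons_alphabet")
}

#' @export
print.parsons_alphabet <- function(x, ...) {
  cat(sprintf("<parsons_alphabet> n = %d (%d symbols), constant tol %.3g Hz\n",
              x$n_levels, x$size, x$constant_tol))
  if (length(x$magnitude_thresholds))
    cat("  magnitude thresholds (Hz):",
        paste(signif(x$magnitude_thresholds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Encode segment means as an n-Parsons code
#'
#' Each consecutive pair of segment means becomes one symbol: `0` when the
#' absolute change is within the alphabet's constant tolerance, otherwise a
#' signed magnitude level `sign(delta) * level` with `level` in
#' `1..n_levels`. Changes exactly on a magnitude threshold take the lower
#' class.
#'
#' @param means Numeric vector of segment mean frequencies (length >= 2), as
#'   from [segment_means()].
#' @param alphabet A [fit_alphabet()] result.
#' @param whistle_id Optional identifier stored with the code.
#' @return An object of class `"parsons_code"`: list with `whistle_id`,
#'   `symbols` (signed integer vector of length `length(means) - 1`), and
#'   `n_levels`.
#' @export
encode <- function(means, alphabet, whistle_id = NA_character_) {
  stopifnot(inherits(alphabet, "parsons_alphabet"))
  means <- as.numeric(means)
  if (length(means) < 2L)
    stop("'means' must have at least 2 values to encode", call. = FALSE)
  d <- diff(means)
  symbols <- parsons_symbols(d, alphabet)
  structure(list(whistle_id = as.character(whistle_id), symbols = symbols,
                 n_levels = alphabet$n_levels),
            class = "parsons_code")
}

parsons_symbols <- function(d, alphabet) {
  a <- abs(d)
  lev <- rep(1L, length(d))
  for (thr in alphabet$magnitude_thresholds) lev <- lev + (a > thr)
  out <- as.integer(sign(d)) * lev
  out[a <= alphabet$constant_tol] <- 0L
  out
}

#' @export
print.parsons_code <- function(x, ...) {
  cat(sprintf("<parsons_code> %s: %s\n", x$whistle_id, format_parsons(x$symbols)))
  invisible(x)
}

#' Render Parsons symbols in the u/d/c dialect
#'
#' Signed integer symbols are written `u<level>` (rise), `d<level>` (drop) and
#' `c` (constant), e.g. `u2,u1,c,d3`, for comma-free CSV export.
#'
#' @param symbols Integer vector of signed symbols, or a `parsons_code`.
#' @return Character scalar.
#' @export
format_parsons <- function(symbols) {
  if (inherits(symbols, "parsons_code")) symbols <- symbols$symbols
  if (!length(symbols)) return("")
  paste(ifelse(symbols == 0L, "c",
               paste0(ifelse(symbols > 0L, "u", "d"), abs(symbols))),
        collapse = ",")
}

#' Encode every whistle in a contour set
#'
#' Convenience wrapper: computes [segment_means()] for every whistle, pools
#' the signed changes across the whole set, fits the alphabet with
#' [fit_alphabet()] (unless one is supplied), and encodes every whistle.
#'
#' @param set A [contour_set()].
#' @param n_segments Number of equal time segments per whistle (default 10,
#'   giving nine symbols per whistle).
#' @param n_levels Magnitude levels per direction (default 1).
#' @param constant_tol Constant-change tolerance in Hz; `NULL` (default) uses
#'   the set's `freq_resolution`.
#' @param large_fraction Proportion of changes in the top magnitude class.
#' @param alphabet Optional pre-fitted [fit_alphabet()] result (e.g. from the
#'   full data set when encoding a subset).
#' @return An object of class `"parsons_encoding"`: list with `ids`, `codes`
#'   (integer matrix, one row per whistle, `n_segments - 1` columns),
#'   `alphabet`, and `n_segments`.
#' @export
encode_set <- function(set, n_segments = 10, n_levels = 1, constant_tol = NULL,
                       large_fraction = 0.10, alphabet = NULL) {
  stopifnot(inherits(set, "contour_set"))
  n_segments <- as.integer(n_segments)
  if (is.null(constant_tol)) constant_tol <- set$freq_resolution
  means <- t(vapply(set$contours, segment_means, numeric(n_segments),
                    n_segments = n_segments))
  if (n_segments == 1L) {
    # single segment: no transitions, every code is empty
    alphabet <- alphabet %||%
      structure(list(n_levels = as.integer(n_levels), constant_tol = constant_tol,
                     magnitude_thresholds = numeric(0),
                     size = 2L * as.integer(n_levels) + 1L),
                class = "parsons_alphabet")
    codes <- matrix(integer(0), nrow = length(set), ncol = 0)
  } else {
    deltas <- t(apply(means, 1L, diff))
    if (n_segments == 2L) deltas <- matrix(deltas, ncol = 1L)
    if (is.null(alphabet))
      alphabet <- fit_alphabet(as.numeric(deltas), n_levels = n_levels,
                               constant_tol = constant_tol,
                               large_fraction = large_fraction)
    codes <- matrix(parsons_symbols(as.numeric(deltas), alphabet),
                    nrow = nrow(deltas), ncol = ncol(deltas))
  }
  rownames(codes) <- whistle_ids(set)
  structure(list(ids = whistle_ids(set), codes = codes, alphabet = alphabet,
                 n_segments = n_segments),
            class = "parsons_encoding")
}

#' @export
print.parsons_encoding <- function(x, ...) {
  cat(sprintf("<parsons_encoding> %d whistles, %d segments -> %d symbols, n = %d (%d-symbol alphabet)\n",
              length(x$ids), x$n_segments, ncol(x$codes),
              x$alphabet$n_levels, x$alphabet$size))
  invisible(x)
}

#' Levenshtein edit distance between two Parsons codes
#'
#' Minimum number of single-symbol insertions, deletions and substitutions
#' transforming one code into the other, by dynamic programming. All edits
#' have unit cost; substitution cost does not depend on how far apart the two
#' symbols are. The distance is a metric on symbol strings.
#'
#' @param a,b `parsons_code` objects or plain integer/character symbol
#'   vectors.
#' @return Non-negative integer.
#' @export
edit_distance <- function(a, b) {
  if (inherits(a, "parsons_code")) a <- a$symbols
  if (inherits(b, "parsons_code")) b <- b$symbols
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  idx <- 0:m
  prev <- idx
  for (i in seq_len(n)) {
    # cand[j] = best cost of reaching column j by a diagonal or vertical step;
    # horizontal (insertion) runs are folded in with a running-minimum trick
    cand <- pmin(prev[-1L] + 1, prev[-(m + 1L)] + (a[i] != b))
    prev <- cummin(c(i, cand) - idx) + idx
  }
  as.integer(prev[m + 1L])
}

#' Pairwise edit-distance proximity matrix of Parsons codes
#'
#' @param codes A [encode_set()] result, or a list of `parsons_code`
#'   objects / symbol vectors.
#' @return Symmetric numeric matrix of pairwise edit distances with zero
#'   diagonal; dimnames are whistle ids when available.
#' @export
pc_proximity <- function(codes) {
  if (inherits(codes, "parsons_encoding")) {
    mat <- codes$codes
    ids <- codes$ids
  } else {
    if (!is.list(codes) || length(codes) < 2L)
      stop("'codes' must contain at least 2 codes", call. = FALSE)
    syms <- lapply(codes, function(x) if (inherits(x, "parsons_code")) x$symbols else x)
    ids <- vapply(seq_along(codes), function(i) {
      if (inherits(codes[[i]], "parsons_code") && !is.na(codes[[i]]$whistle_id))
        codes[[i]]$whistle_id else sprintf("w%d", i)
    }, character(1))
    lens <- lengths(syms)
    if (length(unique(lens)) == 1L && lens[1L] > 0L) {
      mat <- do.call(rbind, syms)
    } else {
      # unequal lengths: plain pairwise loop
      N <- length(syms)
      D <- matrix(0, N, N, dimnames = list(ids, ids))
      for (i in seq_len(N - 1L)) for (j in (i + 1L):N)
        D[i, j] <- D[j, i] <- edit_distance(syms[[i]], syms[[j]])
      return(D)
    }
  }
  N <- nrow(mat)
  if (N < 2L) stop("need at least 2 codes", call. = FALSE)
  L <- ncol(mat)
  D <- matrix(0, N, N, dimnames = list(ids, ids))
  if (L == 0L) return(D)
  pr <- utils::combn(N, 2L)
  A <- mat[pr[1L, ], , drop = FALSE]
  B <- mat[pr[2L, ], , drop = FALSE]
  np <- ncol(pr)
  # batched Levenshtein: one DP over all pairs at once (codes share length L)
  prev <- matrix(rep(0:L, each = np), nrow = np)
  cur <- matrix(0, np, L + 1L)
  for (i in seq_len(L)) {
    cur[, 1L] <- i
    ai <- A[, i]
    for (j in seq_len(L)) {
      cur[, j + 1L] <- pmin(prev[, j + 1L] + 1, prev[, j] + (ai != B[, j]),
                            cur[, j] + 1)
    }
    tmp <- prev; prev <- cur; cur <- tmp
  }
  d <- prev[, L + 1L]
  D[cbind(pr[1L, ], pr[2L, ])] <- d
  D[cbind(pr[2L, ], pr[1L, ])] <- d
  D
}

#' Information capacity of a fixed-length code in bits
#'
#' A length-`L` string over an alphabet of `s` symbols can distinguish
#' `s^L` combinations, i.e. `L * log2(s)` bits. Used to compare the storage
#' demanded by Parsons codes (nine base-7 digits, about 25 bits) with raw
#' 60-point frequency profiles at 128 frequency levels (420 bits) and their
#' 16-dimensional PCA reduction (112 bits).
#'
#' @param alphabet_size Number of distinguishable symbols per position.
#' @param code_length Number of positions.
#' @return Capacity in bits (not rounded).
#' @export
capacity_bits <- function(alphabet_size, code_length) {
  if (alphabet_size < 2 || code_length < 1)
    stop("need alphabet_size >= 2 and code_length >= 1", call. = FALSE)
  code_length * log2(alphabet_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
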