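#' Construct a single whistle frequency contour
#'
#' A whistle contour is the trace of the dominant (fundamental) frequency of a
#' signature whistle over time, as digitised from a spectrogram. Times must be
#' strictly increasing and frequencies strictly positive.
#'
#' @param time Numeric vector of times in seconds (non-negative, strictly
#'   increasing, length >= 2).
#' @param freq Numeric vector of frequencies in Hz (positive), same length as
#'   `time`.
#' @param whistle_id Character scalar identifying the whistle.
#' @param individual_id Character scalar identifying the animal that produced
#'   the whistle (the "truth" label for identity-recovery scoring); may be
#'   `NA` when unknown.
#' @return An object of class `"whistle_contour"`: a list with elements
#'   `whistle_id`, `individual_id`, `time`, `freq`.
#' @examples
#' w <- whistle_contour(c(0, 0.1, 0.2), c(5000, 6000, 5500), "w1", "dolphinA")
#' duration(w)
#' @export
whistle_contour <- function(time, freq, whistle_id, individual_id = NA_character_) {
  time <- as.numeric(time)
  freq <- as.numeric(freq)
  if (length(time) != length(freq))
    stop("'time' and 'freq' must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop(sprintf("contour '%s' has fewer than 2 points", whistle_id), call. = FALSE)
  if (anyNA(time) || anyNA(freq))
    stop(sprintf("contour '%s' contains missing values", whistle_id), call. = FALSE)
  if (any(time < 0))
    stop(sprintf("contour '%s' has negative times", whistle_id), call. = FALSE)
  if (any(freq <= 0))
    stop(sprintf("contour '%s' has non-positive frequencies", whistle_id), call. = FALSE)
  if (any(diff(time) <= 0))
    stop(sprintf("time not strictly increasing within whistle '%s'", whistle_id),
         call. = FALSE)
  structure(
    list(whistle_id = as.character(whistle_id),
         individual_id = as.character(individual_id),
         time = time, freq = freq),
    class = "whistle_contour"
  )
}

#' @export
print.whistle_contour <- function(x, ...) {
  cat(sprintf("<whistle_contour> %s (individual %s): %d points, %.3f s, %.0f-%.0f Hz\n",
              x$whistle_id, x$individual_id, length(x$time),
              duration(x), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Whistle duration in seconds
#' @param contour A `whistle_contour`.
#' @return Numeric scalar, `max(time) - min(time)`.
#' @export
duration <- function(contour) {
  stopifnot(inherits(contour, "whistle_contour"))
  max(contour$time) - min(contour$time)
}

#' Construct a set of whistle contours
#'
#' @param contours List of [whistle_contour()] objects with unique
#'   `whistle_id`s.
#' @param freq_resolution Spectrogram frequency-bin width in Hz (the "pixel"
#'   size used as the default constant-change tolerance when fitting a Parsons
#'   alphabet). Use 0 for synthetic contours that carry no spectrogram grain.
#' @return An object of class `"contour_set"`.
#' @export
contour_set <- function(contours, freq_resolution = 0) {
  if (!is.list(contours) || length(contours) == 0L)
    stop("'contours' must be a non-empty list of whistle_contour objects", call. = FALSE)
  ok <- vapply(contours, inherits, logical(1), what = "whistle_contour")
  if (!all(ok))
    stop("all elements of 'contours' must be whistle_contour objects", call. = FALSE)
  ids <- vapply(contours, `[[`, character(1), "whistle_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicated whistle_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  if (!is.numeric(freq_resolution) || freq_resolution < 0)
    stop("'freq_resolution' must be a non-negative number", call. = FALSE)
  names(contours) <- ids
  structure(list(contours = contours, freq_resolution = freq_resolution),
            class = "contour_set")
}

#' @export
length.contour_set <- function(x) length(x$contours)

#' @export
`[.contour_set` <- function(x, i) {
  contour_set(x$contours[i], freq_resolution = x$freq_resolution)
}

#' @export
`[[.contour_set` <- function(x, i) x$contours[[i]]

#' @export
print.contour_set <- function(x, ...) {
  ind <- individual_ids(x)
  cat(sprintf("<contour_set> %d whistles from %d individuals\n",
              length(x), length(unique(ind[!is.na(ind)]))))
  invisible(x)
}

#' Whistle identifiers of a contour set
#' @param set A `contour_set`.
#' @return Character vector of `whistle_id`s, in set order.
#' @export
whistle_ids <- function(set) {
  stopifnot(inherits(set, "contour_set"))
  unname(vapply(set$contours, `[[`, character(1), "whistle_id"))
}

#' Individual (truth) labels of a contour set
#' @param set A `contour_set`.
#' @return Character vector of `individual_id`s named by `whistle_id`.
#' @export
individual_ids <- function(set) {
  stopifnot(inherits(set, "contour_set"))
  ids <- vapply(set$contours, `[[`, character(1), "individual_id")
  names(ids) <- whistle_ids(set)
  ids
}

#' Read whistle contours from a long-format CSV file
#'
#' The file must have columns `whistle_id,individual_id,time_s,freq_hz`, one
#' row per time-frequency point. Rows are grouped by whistle (in order of
#' first appearance) and sorted by time within each whistle; duplicated or
#' non-increasing times within a whistle are a validation error.
#'
#' @param path Path to a CSV file.
#' @param freq_resolution Spectrogram frequency-bin width in Hz; see
#'   [contour_set()].
#' @return A [contour_set()].
#' @export
read_contours <- function(path, freq_resolution = 0) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("whistle_id", "individual_id", "time_s", "freq_hz")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("missing column(s) in %s: %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  ord <- unique(df$whistle_id)
  contours <- lapply(ord, function(id) {
    rows <- df[df$whistle_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    whistle_contour(rows$time_s, rows$freq_hz, id, rows$individual_id[1L])
  })
  contour_set(contours, freq_resolution = freq_resolution)
}

#' Write whistle contours to a long-format CSV file
#'
#' Inverse of [read_contours()]; emits the same
#' `whistle_id,individual_id,time_s,freq_hz` schema.
#'
#' @param set A `contour_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(set, path) {
  stopifnot(inherits(set, "contour_set"))
  df <- as.data.frame(set)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.contour_set <- function(x, ...) {
  do.call(rbind, lapply(x$contours, function(w) {
    data.frame(whistle_id = w$whistle_id, individual_id = w$individual_id,
               time_s = w$time, freq_hz = w$freq, stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Smooth a contour with a cubic smoothing spline
#'
#' Fits a cubic smoothing spline to the hand-traced time-frequency points and
#' evaluates it on a uniform time grid, capturing the essential shape of the
#' whistle while suppressing tracing jitter.
#'
#' @param contour A `whistle_contour`.
#' @param smoothing Non-negative smoothing penalty (`lambda` of
#'   [stats::smooth.spline()]). `NULL` (default) selects the penalty by
#'   generalized cross-validation; `0` gives an exact cubic interpolating
#'   spline through the input points.
#' @param n_out Number of output points on the uniform grid (>= 2); defaults
#'   to the number of input points.
#' @return A `whistle_contour` with `n_out` points spanning the original
#'   duration. Contours with fewer than 4 points fall back to linear
#'   interpolation with a warning.
#' @export
smooth_contour <- function(contour, smoothing = NULL, n_out = NULL) {
  stopifnot(inherits(contour, "whistle_contour"))
  if (is.null(n_out)) n_out <- length(contour$time)
  n_out <- as.integer(n_out)
  if (n_out < 2L) stop("'n_out' must be at least 2", call. = FALSE)
  grid <- seq(min(contour$time), max(contour$time), length.out = n_out)
  n_in <- length(contour$time)
  if (n_in < 4L) {
    warning(sprintf("contour '%s' has %d points; falling back to linear interpolation",
                    contour$whistle_id, n_in))
    f <- stats::approx(contour$time, contour$freq, xout = grid)$y
  } else if (!is.null(smoothing) && smoothing == 0) {
    f <- stats::spline(contour$time, contour$freq, xout = grid, method = "natural")$y
  } else if (is.null(smoothing)) {
    fit <- stats::smooth.spline(contour$time, contour$freq, cv = FALSE)
    f <- stats::predict(fit, grid)$y
  } else {
    if (smoothing < 0) stop("'smoothing' must be non-negative", call. = FALSE)
    fit <- stats::smooth.spline(contour$time, contour$freq, lambda = smoothing)
    f <- stats::predict(fit, grid)$y
  }
  # splines can undershoot 0 on pathological input; frequencies must stay positive
  f <- pmax(f, .Machine$double.eps)
  whistle_contour(grid, f, contour$whistle_id, contour$individual_id)
}

#' Resample a contour at equally spaced time points
#'
#' Linearly interpolates the contour at `n_points` equally spaced times over
#' the whistle's own duration, so that whistles of different durations map to
#' comparable fixed-length frequency vectors (per-whistle time normalisation).
#'
#' @param contour A `whistle_contour`.
#' @param n_points Number of sample points (>= 2).
#' @return Numeric vector of `n_points` frequencies in Hz.
#' @export
resample_uniform <- function(contour, n_points) {
  stopifnot(inherits(contour, "whistle_contour"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("'n_points' must be at least 2", call. = FALSE)
  grid <- seq(min(contour$time), max(contour$time), length.out = n_points)
  stats::approx(contour$time, contour$freq, xout = grid)$y
}

#' Resample every contour in a set to a fixed-length frequency matrix
#'
#' @param set A `contour_set`.
#' @param n_points Number of sample points per whistle.
#' @return Numeric matrix, one row per whistle (rownames = `whistle_id`),
#'   `n_points` columns.
#' @export
resample_set <- function(set, n_points) {
  stopifnot(inherits(set, "contour_set"))
  m <- t(vapply(set$contours, resample_uniform, numeric(n_points),
                n_points = n_points))
  rownames(m) <- whistle_ids(set)
  m
}

#' @export
plot.whistle_contour <- function(x, ...) {
  graphics::plot(x$time, x$freq / 1000, type = "l", xlab = "Time (s)",
                 ylab = "Frequency (kHz)", main = x$whistle_id, ...)
  graphics::points(x$time, x$freq / 1000, pch = 16, cex = 0.4)
  invisible(x)
}

#' @export
plot.contour_set <- function(x, n = 9, ...) {
  n <- min(n, length(x))
  op <- graphics::par(mfrow = grDevices::n2mfrow(n), mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    w <- x$contours[[i]]
    graphics::plot(w$time, w$freq / 1000, type = "l", xlab = "", ylab = "",
                   main = w$whistle_id, cex.main = 0.8, ...)
  }
  invisible(x)
}
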