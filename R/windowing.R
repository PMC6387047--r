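#' Construct a tri-axial accelerometer record
#'
#' Container for a regularly sampled tri-axial acceleration time series.
#' Sample `i` (1-based) carries time `(i - 1) / sampling_rate_hz` seconds;
#' supplied timestamps are validated against that grid.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param ax,ay,az Per-axis acceleration in m/s^2.
#' @param sampling_rate_hz Sampling rate in Hz. If `NULL`, inferred from
#'   the median time step.
#' @return An object of class `accel_record`.
#' @export
accel_record <- function(times, ax, ay, az, sampling_rate_hz = NULL) {
  n <- length(times)
  if (n == 0L) stop("record has no samples")
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("times, ax, ay, az must have equal lengths")
  }
  vals <- c(times, ax, ay, az)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("record contains missing or non-finite values")
  }
  if (n > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (is.null(sampling_rate_hz)) sampling_rate_hz <- 1 / stats::median(dt)
    # reject irregular series instead of silently interpolating
    if (any(abs(dt - 1 / sampling_rate_hz) > 1e-6)) {
      stop("sample spacing inconsistent with sampling_rate_hz (tolerance 1e-6 s)")
    }
  } else if (is.null(sampling_rate_hz)) {
    stop("sampling_rate_hz required for a single-sample record")
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  structure(
    list(
      times = as.numeric(times), ax = as.numeric(ax), ay = as.numeric(ay),
      az = as.numeric(az), sampling_rate_hz = sampling_rate_hz
    ),
    class = "accel_record"
  )
}

#' @export
print.accel_record <- function(x, ...) {
  cat(sprintf(
    "<accel_record> %d samples @ %g Hz, %.3f s\n",
    length(x$times), x$sampling_rate_hz, length(x$times) / x$sampling_rate_hz
  ))
  invisible(x)
}

#' Tri-axial acceleration magnitude
#'
#' Element-wise Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` of the three
#' axes; the quantity all downstream analysis operates on. Invariant
#' under axis permutation and sign flips.
#'
#' @param record An `accel_record`.
#' @return An object of class `magnitude_series`: list with `times`,
#'   `values` (non-negative, m/s^2) and `sampling_rate_hz`.
#' @export
magnitude <- function(record) {
  stopifnot(inherits(record, "accel_record"))
  structure(
    list(
      times = record$times,
      values = sqrt(record$ax^2 + record$ay^2 + record$az^2),
      sampling_rate_hz = record$sampling_rate_hz
    ),
    class = "magnitude_series"
  )
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf(
    "<magnitude_series> %d samples @ %g Hz, mean %.3f m/s^2\n",
    length(x$values), x$sampling_rate_hz, mean(x$values)
  ))
  invisible(x)
}

#' Sliding FIFO windows over a magnitude series
#'
#' Emulates the on-device FIFO buffer: the first window is emitted once
#' `window_size` samples have arrived (warm-up), then one window per
#' `stride` new samples, each holding the most recent `window_size`
#' magnitudes. At the default 8 Hz / stride 8 this is one window per
#' second. A window's decision time is the time of its last sample.
#'
#' @param series A `magnitude_series` (or plain numeric vector, in which
#'   case times are taken as `(i-1)/sampling_rate_hz`).
#' @param window_size Window length in samples (default 256).
#' @param stride Advance between windows in samples (default 8).
#' @param sampling_rate_hz Used only when `series` is a bare vector.
#' @return A list with `end_times` (numeric vector, seconds) and
#'   `windows` (a `length(end_times)` x `window_size` numeric matrix, one
#'   window per row). Series shorter than `window_size` yield zero
#'   windows.
#' @export
sliding_windows <- function(series, window_size = 256L, stride = 8L,
                            sampling_rate_hz = 8) {
  if (inherits(series, "magnitude_series")) {
    values <- series$values
    times <- series$times
  } else {
    values <- as.numeric(series)
    times <- (seq_along(values) - 1) / sampling_rate_hz
  }
  window_size <- as.integer(window_size)
  stride <- as.integer(stride)
  if (window_size < 1L || stride < 1L || stride > window_size) {
    stop("require 1 <= stride <= window_size")
  }
  n <- length(values)
  if (n < window_size) {
    return(list(
      end_times = numeric(0),
      windows = matrix(numeric(0), nrow = 0, ncol = window_size)
    ))
  }
  ends <- seq.int(window_size, n, by = stride)
  win <- matrix(0, nrow = length(ends), ncol = window_size)
  for (i in seq_along(ends)) {
    win[i, ] <- values[(ends[i] - window_size + 1L):ends[i]]
  }
  list(end_times = times[ends], windows = win)
}

#' Normalised cross-correlation of two series
#'
#' Brute-force normalised (mean-removed, unit-scaled) cross-correlation
#' over all integer lags `-(n-1) .. (n-1)`; used to compare the two
#' lower extremities' signals, whose near-unity peak at lag 0 justifies
#' instrumenting a single leg. Positive lag means `b` trails `a`.
#'
#' @param a,b Equal-length numeric vectors or `magnitude_series`, length
#'   >= 2, non-constant.
#' @return List with `peak` (maximum coefficient, in `[-1, 1]`),
#'   `lag_samples` (lag of the maximum), and `coefficients` (named by
#'   lag).
#' @export
cross_correlation <- function(a, b) {
  if (inherits(a, "magnitude_series")) a <- a$values
  if (inherits(b, "magnitude_series")) b <- b$values
  n <- length(a)
  if (length(b) != n || n < 2L) stop("series must have equal length >= 2")
  da <- a - mean(a)
  db <- b - mean(b)
  denom <- sqrt(sum(da^2)) * sqrt(sum(db^2))
  if (denom == 0) stop("correlation undefined for a constant series")
  lags <- -(n - 1L):(n - 1L)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(da[1:(n - l)] * db[(1 + l):n]) else
      sum(da[(1 - l):n] * db[1:(n + l)])
  }, numeric(1)) / denom
  names(cc) <- lags
  i <- which.max(cc)
  list(peak = cc[[i]], lag_samples = lags[i], coefficients = cc)
}
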