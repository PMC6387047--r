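#' Detector configuration
#'
#' Parameters of the windowed freeze detector. Defaults mirror the
#' on-device pipeline: 8 Hz sampling, a 256-sample (32 s) analysis
#' window advanced by 8 samples so a decision is made once per second,
#' five-level Haar decomposition, and a 2% activation threshold on the
#' freeze-indicator statistic. A decision is FOG-positive when the
#' statistic is less than or equal to the threshold (low first-band
#' energy means a near-stationary limb); the same predicate releases the
#' stimulation, so it stays on exactly while decisions are positive.
#'
#' @param threshold_pct Activation threshold in percent (default 2).
#' @param window_size Analysis window in samples (default 256).
#' @param stride New samples per decision (default 8).
#' @param statistic_variant `"dc1_fraction"` (default) or
#'   `"eq13_verbatim"`; see [fog_statistic()].
#' @param sampling_rate_hz Expected sampling rate (default 8).
#' @param levels Wavelet decomposition depth (default 5).
#' @param min_episode_s Optional minimum episode duration filter applied
#'   after extraction (default 0: off, the single-threshold rule only).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(threshold_pct = 2.0, window_size = 256L,
                            stride = 8L,
                            statistic_variant = c("dc1_fraction", "eq13_verbatim"),
                            sampling_rate_hz = 8, levels = 5L,
                            min_episode_s = 0) {
  statistic_variant <- match.arg(statistic_variant)
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    stop("threshold_pct must lie in (0, 100)")
  }
  window_size <- as.integer(window_size)
  stride <- as.integer(stride)
  if (stride < 1L || stride > window_size) stop("require 1 <= stride <= window_size")
  if (window_size %% 2L^as.integer(levels) != 0L) {
    stop("window_size must be divisible by 2^levels")
  }
  structure(
    list(
      threshold_pct = threshold_pct, window_size = window_size,
      stride = stride, statistic_variant = statistic_variant,
      sampling_rate_hz = sampling_rate_hz, levels = as.integer(levels),
      min_episode_s = min_episode_s
    ),
    class = "detector_config"
  )
}

#' Single-window FOG decision
#'
#' @param window Numeric window of `config$window_size` values.
#' @param config A [detector_config()].
#' @return List with `statistic_pct` and logical `fog` (`TRUE` iff
#'   `statistic_pct <= threshold_pct`).
#' @export
decide <- function(window, config = detector_config()) {
  if (length(window) != config$window_size) {
    stop(sprintf(
      "window has %d values; config expects %d",
      length(window), config$window_size
    ))
  }
  s <- fog_statistic(window,
    variant = config$statistic_variant,
    levels = config$levels
  )
  list(statistic_pct = s, fog = s <= config$threshold_pct)
}

#' Run the freeze detector over a magnitude series
#'
#' Applies [decide()] to every FIFO window of the series (one decision
#' per `stride` samples after warm-up), derives the stimulation channel
#' (on exactly while decisions are FOG-positive, released at the first
#' decision whose statistic exceeds the threshold), and extracts
#' episodes as maximal runs of consecutive positive decisions. Because a
#' decision summarises the trailing window, each episode's start is
#' backdated by one decision interval (`stride / sampling_rate_hz`, 1 s
#' at the defaults); its end is the last positive decision time.
#'
#' @param series A `magnitude_series` (or numeric vector of magnitudes).
#' @param config A [detector_config()].
#' @return An object of class `detection_timeline`: list with
#'   `decision_times`, `statistic_values`, `fog_flags`,
#'   `stimulation_flags`, `episodes` (data frame `start_s`, `end_s`),
#'   and `config`. A series shorter than the window yields an empty
#'   timeline with a warning.
#' @export
detect_fog <- function(series, config = detector_config()) {
  if (inherits(series, "magnitude_series") &&
    abs(series$sampling_rate_hz - config$sampling_rate_hz) /
      config$sampling_rate_hz > 1e-3) {
    stop(sprintf(
      "series sampled at %g Hz but detector configured for %g Hz",
      series$sampling_rate_hz, config$sampling_rate_hz
    ))
  }
  sw <- sliding_windows(series,
    window_size = config$window_size, stride = config$stride,
    sampling_rate_hz = config$sampling_rate_hz
  )
  if (length(sw$end_times) == 0L) {
    warning("series shorter than one analysis window; no decisions emitted")
    return(new_timeline(numeric(0), numeric(0), logical(0), config))
  }
  stats_pct <- apply(sw$windows, 1L, fog_statistic,
    variant = config$statistic_variant, levels = config$levels
  )
  flags <- stats_pct <= config$threshold_pct
  new_timeline(sw$end_times, stats_pct, flags, config)
}

new_timeline <- function(times, stats_pct, flags, config) {
  structure(
    list(
      decision_times = times, statistic_values = as.numeric(stats_pct),
      fog_flags = flags,
      # stimulation follows the decision flag one-for-one: turned on by a
      # positive decision, held while positive, released when the
      # statistic exceeds the threshold
      stimulation_flags = flags,
      episodes = extract_episodes(times, flags, config),
      config = config
    ),
    class = "detection_timeline"
  )
}

extract_episodes <- function(times, flags, config) {
  if (length(flags) == 0L || !any(flags)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  interval_s <- config$stride / config$sampling_rate_hz
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ep <- data.frame(
    start_s = times[starts[keep]] - interval_s,
    end_s = times[ends[keep]]
  )
  ep[ep$end_s - ep$start_s >= config$min_episode_s, , drop = FALSE]
}

#' @export
print.detection_timeline <- function(x, ...) {
  cat(sprintf(
    "<detection_timeline> %d decisions, %d positive, %d episode(s)\n",
    length(x$fog_flags), sum(x$fog_flags), nrow(x$episodes)
  ))
  invisible(x)
}

#' Create streaming detector state
#'
#' Incremental counterpart of [detect_fog()]: holds the FIFO buffer and
#' emits decisions as samples arrive, in any chunking, with output
#' identical to the batch run on the concatenated series.
#'
#' @param config A [detector_config()].
#' @return An object of class `fog_stream_state`.
#' @seealso [stream_feed()], [stream_timeline()]
#' @export
stream_new <- function(config = detector_config()) {
  structure(
    list(
      config = config, buffer = numeric(0), n_seen = 0L,
      times = numeric(0), stats = numeric(0), flags = logical(0)
    ),
    class = "fog_stream_state"
  )
}

#' Feed samples to a streaming detector
#'
#' @param state A `fog_stream_state`.
#' @param new_samples Numeric vector of new magnitude values (any
#'   length, including 0 or 1).
#' @return Updated state. Decisions accumulated so far are available via
#'   [stream_timeline()]; those added by this call are in
#'   `attr(, "new_decisions")` (data frame `time_s`, `statistic_pct`,
#'   `fog`).
#' @export
stream_feed <- function(state, new_samples) {
  stopifnot(inherits(state, "fog_stream_state"))
  cfg <- state$config
  buf <- c(state$buffer, as.numeric(new_samples))
  n_seen <- state$n_seen + length(new_samples)
  times <- state$times
  stats_pct <- state$stats
  flags <- state$flags
  added <- 0L
  # a decision is due whenever total samples seen reaches
  # window_size + k * stride; buffer retains at most window_size values
  repeat {
    n_decided <- length(times)
    due_at <- cfg$window_size + n_decided * cfg$stride
    if (n_seen < due_at) break
    # window ending at absolute sample index due_at
    start_in_buf <- length(buf) - (n_seen - due_at) - cfg$window_size + 1L
    w <- buf[start_in_buf:(start_in_buf + cfg$window_size - 1L)]
    d <- decide(w, cfg)
    times <- c(times, (due_at - 1L) / cfg$sampling_rate_hz)
    stats_pct <- c(stats_pct, d$statistic_pct)
    flags <- c(flags, d$fog)
    added <- added + 1L
  }
  if (length(buf) > cfg$window_size) {
    buf <- buf[(length(buf) - cfg$window_size + 1L):length(buf)]
  }
  out <- structure(
    list(
      config = cfg, buffer = buf, n_seen = n_seen,
      times = times, stats = stats_pct, flags = flags
    ),
    class = "fog_stream_state"
  )
  nd <- length(times)
  attr(out, "new_decisions") <- data.frame(
    time_s = times[seq_len(added) + nd - added],
    statistic_pct = stats_pct[seq_len(added) + nd - added],
    fog = flags[seq_len(added) + nd - added]
  )
  out
}

#' Timeline of all decisions a stream has made so far
#'
#' @param state A `fog_stream_state`.
#' @return A `detection_timeline` identical to [detect_fog()] run on the
#'   full series fed so far.
#' @export
stream_timeline <- function(state) {
  stopifnot(inherits(state, "fog_stream_state"))
  new_timeline(state$times, state$stats, state$flags, state$config)
}
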