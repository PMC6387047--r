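#' Write an accelerometer record to CSV
#'
#' Writes the dialect used throughout the package: comma-separated,
#' header `time_s,ax,ay,az`, decimal point, UTF-8, values at full double
#' precision (round-trips through [read_accel_csv()] to well below
#' 1e-9). For a `labeled_record` a sidecar annotation file
#' (`<path basename>_episodes.csv`, header `start_s,end_s`) is written
#' unless `annotations_path` says otherwise; an empty episode list gives
#' a header-only sidecar.
#'
#' @param x An `accel_record` or `labeled_record`.
#' @param path Output CSV path.
#' @param annotations_path Sidecar path for episode annotations; `NULL`
#'   (default) derives it from `path`; `NA` suppresses the sidecar.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(x, path, annotations_path = NULL) {
  rec <- if (inherits(x, "labeled_record")) x$record else x
  stopifnot(inherits(rec, "accel_record"))
  df <- data.frame(
    time_s = fmt_num(rec$times), ax = fmt_num(rec$ax),
    ay = fmt_num(rec$ay), az = fmt_num(rec$az)
  )
  utils::write.table(df, path,
    sep = ",", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  if (inherits(x, "labeled_record")) {
    if (is.null(annotations_path)) {
      annotations_path <- default_sidecar_path(path)
    }
    if (!is.na(annotations_path)) write_episodes_csv(x$episodes, annotations_path)
  }
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

default_sidecar_path <- function(path) {
  sub("(\\.[Cc][Ss][Vv])?$", "_episodes.csv", path)
}

#' Read an accelerometer record from CSV
#'
#' Parses the `time_s,ax,ay,az` dialect, validating every cell (a
#' non-numeric or missing cell is reported with its data-row number) and
#' the time base (strictly increasing, regular). The sampling rate is
#' inferred from the timestamps and, when `sampling_rate_hz` is supplied,
#' cross-checked against it (relative mismatch above 1e-3 is an error,
#' since the band-to-level mapping depends on the rate).
#'
#' @param path CSV file path.
#' @param sampling_rate_hz Optional expected sampling rate in Hz.
#' @return An [accel_record()].
#' @export
read_accel_csv <- function(path, sampling_rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    fileEncoding = "UTF-8"
  )
  need <- c("time_s", "ax", "ay", "az")
  if (!identical(names(raw)[seq_along(need)], need)) {
    stop("header must be 'time_s,ax,ay,az'; got: ", paste(names(raw), collapse = ","))
  }
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  cols <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric value in column '%s' at data row %d of %s",
        cn, bad[1L], path
      ))
    }
    v
  })
  names(cols) <- need
  inferred <- if (length(cols$time_s) > 1L) {
    1 / stats::median(diff(cols$time_s))
  } else {
    sampling_rate_hz
  }
  if (!is.null(sampling_rate_hz) && !is.null(inferred) &&
    abs(inferred - sampling_rate_hz) / sampling_rate_hz > 1e-3) {
    stop(sprintf(
      "timestamps imply %.4f Hz but %.4f Hz was declared",
      inferred, sampling_rate_hz
    ))
  }
  accel_record(cols$time_s, cols$ax, cols$ay, cols$az,
    sampling_rate_hz = inferred
  )
}

#' Write episode intervals to CSV
#'
#' @param episodes Data frame (or coercible) with `start_s`, `end_s`.
#' @param path Output path; header `start_s,end_s`.
#' @return `path`, invisibly.
#' @export
write_episodes_csv <- function(episodes, path) {
  ep <- normalize_episodes(episodes)
  df <- data.frame(start_s = fmt_num(ep$start_s), end_s = fmt_num(ep$end_s))
  utils::write.table(df, path,
    sep = ",", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read episode intervals from CSV
#'
#' @param path CSV with header `start_s,end_s`; may contain zero rows.
#' @return Data frame with numeric `start_s`, `end_s`.
#' @export
read_episodes_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("start_s", "end_s") %in% names(raw))) {
    stop("episode file header must contain start_s,end_s")
  }
  normalize_episodes(data.frame(
    start_s = as.numeric(raw$start_s),
    end_s = as.numeric(raw$end_s)
  ))
}

#' Write a detection timeline and its episodes to CSV
#'
#' Per-decision rows `time_s,statistic_pct,fog,stim` plus an episodes
#' file `start_s,end_s`.
#'
#' @param timeline A `detection_timeline`.
#' @param path Output CSV for decisions.
#' @param episodes_path Output CSV for extracted episodes; `NULL` derives
#'   `<path basename>_episodes.csv`, `NA` suppresses it.
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(timeline, path, episodes_path = NULL) {
  stopifnot(inherits(timeline, "detection_timeline"))
  df <- data.frame(
    time_s = fmt_num(timeline$decision_times),
    statistic_pct = fmt_num(timeline$statistic_values),
    fog = as.integer(timeline$fog_flags),
    stim = as.integer(timeline$stimulation_flags)
  )
  utils::write.table(df, path,
    sep = ",", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  if (is.null(episodes_path)) episodes_path <- default_sidecar_path(path)
  if (!is.na(episodes_path)) write_episodes_csv(timeline$episodes, episodes_path)
  invisible(path)
}
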