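#' Match detected episodes against annotated ones
#'
#' Greedy chronological matching of detected FOG episodes to expert
#' annotations. An annotated episode counts as a true positive when some
#' not-yet-used detected episode overlaps it by at least `min_overlap_s`
#' seconds, else as a false negative; each detected episode matches at
#' most one annotation. The default minimum overlap of 1 s is one
#' decision interval, the finest granularity the 1 Hz decision cadence
#' supports.
#'
#' @param annotated,detected Data frames with `start_s`, `end_s` (or
#'   anything [read_episodes_csv()] would return).
#' @param min_overlap_s Minimum overlap to accept a match (default 1).
#' @return List with `tp`, `fn`, `unmatched_detections` (count of
#'   detected episodes matching no annotation), and `matches` (data
#'   frame of matched index pairs).
#' @export
match_episodes <- function(annotated, detected, min_overlap_s = 1) {
  ann <- normalize_episodes(annotated)
  det <- normalize_episodes(detected)
  used <- rep(FALSE, nrow(det))
  pairs <- list()
  tp <- 0L
  for (i in seq_len(nrow(ann))) {
    for (j in seq_len(nrow(det))) {
      if (used[j]) next
      ov <- min(ann$end_s[i], det$end_s[j]) - max(ann$start_s[i], det$start_s[j])
      if (ov >= min_overlap_s) {
        used[j] <- TRUE
        tp <- tp + 1L
        pairs[[length(pairs) + 1L]] <- c(annotated = i, detected = j)
        break
      }
    }
  }
  list(
    tp = tp, fn = nrow(ann) - tp,
    unmatched_detections = sum(!used),
    matches = if (length(pairs)) {
      as.data.frame(do.call(rbind, pairs))
    } else {
      data.frame(annotated = integer(0), detected = integer(0))
    }
  )
}

#' Classify FOG-free records as true negatives or false positives
#'
#' Record-level accounting for signals annotated FOG-free: a record
#' whose timeline contains no positive decision is a true negative, any
#' positive decision makes it a false positive (one count per record, as
#' in a 15-signals-per-patient tally).
#'
#' @param timelines List of `detection_timeline` objects, one per
#'   FOG-free record.
#' @return List with counts `tn` and `fp`.
#' @export
classify_negative_records <- function(timelines) {
  if (length(timelines) == 0L) return(list(tn = 0L, fp = 0L))
  pos <- vapply(timelines, function(tl) {
    stopifnot(inherits(tl, "detection_timeline"))
    any(tl$fog_flags)
  }, logical(1))
  list(tn = sum(!pos), fp = sum(pos))
}

#' Diagnostic sensitivity
#'
#' `100 * TP / (TP + FN)`: the share of expert-annotated FOG episodes
#' the system detected.
#'
#' @param tp,fn Non-negative counts with `tp + fn > 0`.
#' @return Percentage.
#' @export
sensitivity <- function(tp, fn) {
  check_counts(tp = tp, fn = fn)
  if (tp + fn == 0) stop("sensitivity undefined: tp + fn = 0")
  100 * tp / (tp + fn)
}

#' Diagnostic specificity
#'
#' `100 * TN / (TN + FP)`: the share of FOG-free records the system left
#' untouched.
#'
#' @param tn,fp Non-negative counts with `tn + fp > 0`.
#' @return Percentage.
#' @export
specificity <- function(tn, fp) {
  check_counts(tn = tn, fp = fp)
  if (tn + fp == 0) stop("specificity undefined: tn + fp = 0")
  100 * tn / (tn + fp)
}

#' Stimulation effectiveness
#'
#' `100 * resumptions / TP`: among detected episodes, the share in which
#' the vibratory cue triggered resumption of gait. Resumption is an
#' annotated input (an observer's judgement), not something the detector
#' measures.
#'
#' @param resumptions Count of gait resumptions, `<= tp`.
#' @param tp True-positive count, `> 0`.
#' @return Percentage.
#' @export
effectiveness <- function(resumptions, tp) {
  check_counts(resumptions = resumptions, tp = tp)
  if (tp == 0) stop("effectiveness undefined: tp = 0")
  if (resumptions > tp) stop("resumptions cannot exceed tp")
  100 * resumptions / tp
}

#' Relative reduction of mean FOG duration under stimulation
#'
#' `100 * (t_without - t_with) / t_without`, the improvement percentage
#' comparing mean episode duration with and without vibratory cueing.
#'
#' @param t_without_s Mean episode duration without stimulation,
#'   seconds, `> 0`.
#' @param t_with_s Mean episode duration with stimulation, seconds.
#' @return Percentage (negative if stimulation lengthened episodes).
#' @export
improvement_pct <- function(t_without_s, t_with_s) {
  if (!is.numeric(t_without_s) || !is.numeric(t_with_s)) {
    stop("durations must be numeric")
  }
  if (any(t_without_s <= 0)) stop("t_without_s must be positive")
  100 * (t_without_s - t_with_s) / t_without_s
}

check_counts <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
      v != round(v)) {
      stop(nm, " must be a single non-negative integer count")
    }
  }
  invisible(TRUE)
}

#' Full validation report from counts
#'
#' Bundles the three diagnostic metrics from a set of tallies, the way a
#' study report would print them.
#'
#' @param tp,fn,tn,fp,resumptions Non-negative counts.
#' @return An object of class `validation_report`: the counts plus
#'   `sensitivity_pct`, `specificity_pct`, `effectiveness_pct` (the
#'   latter `NA` when `tp = 0`).
#' @export
validation_report <- function(tp, fn, tn, fp, resumptions = 0L) {
  structure(
    list(
      tp = tp, fn = fn, tn = tn, fp = fp, resumptions = resumptions,
      sensitivity_pct = sensitivity(tp, fn),
      specificity_pct = specificity(tn, fp),
      effectiveness_pct = if (tp > 0) effectiveness(resumptions, tp) else NA_real_
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<validation_report> TP %d, FN %d, TN %d, FP %d, resumptions %d\n",
      "  sensitivity %.2f%%  specificity %.2f%%  effectiveness %s\n"
    ),
    x$tp, x$fn, x$tn, x$fp, x$resumptions,
    x$sensitivity_pct, x$specificity_pct,
    if (is.na(x$effectiveness_pct)) "NA" else sprintf("%.2f%%", x$effectiveness_pct)
  ))
  invisible(x)
}

#' Published per-patient validation tables
#'
#' Returns the per-patient tallies of the clinical evaluation shipped
#' with the package (`inst/extdata/`): `fog` — episodes diagnosed per
#' patient with TP/FN and gait-resumption counts, including the printed
#' totals row; `no_fog` — record-level TN/FP for the two FOG-free
#' patients; `durations` — mean FOG duration with/without stimulation
#' and the printed improvement percentages. Note the published totals
#' row of the `fog` table (TP 20, FN 13) does not equal its column sums
#' (17, 12); the totals row is what the published metrics derive from,
#' so both are preserved verbatim.
#'
#' @param which One of `"fog"`, `"no_fog"`, `"durations"`.
#' @return A data frame.
#' @export
reference_table <- function(which = c("fog", "no_fog", "durations")) {
  which <- match.arg(which)
  fn <- c(
    fog = "table_fog_patients.csv",
    no_fog = "table_no_fog_patients.csv",
    durations = "table_episode_durations.csv"
  )[[which]]
  path <- system.file("extdata", fn, package = "fogdetect", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
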