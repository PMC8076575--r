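#' Detect cry sequences from a per-epoch label series
#'
#' Post-processes binary 5-s epoch labels into cry sequences — periods during
#' which an infant cries continuously or intermittently. A sequence starts
#' when at least `start_min_cry` cry epochs fall within any sliding window of
#' `start_window` epochs (1 min at the defaults), anchored at the first cry
#' epoch of the earliest such window; it stops at the last cry epoch before
#' `stop_gap` consecutive non-cry epochs (5 min at the defaults) or the end
#' of the series. Sequences never overlap, and sub-threshold crying between
#' sequences belongs to no sequence.
#'
#' @param labels Binary vector (1 = cry) or a tibble with a `label` column,
#'   on the 5-s epoch grid.
#' @param start_min_cry Minimum cry epochs required to open a sequence.
#'   Default 6.
#' @param start_window Window length in epochs over which `start_min_cry` is
#'   counted. Default 12 (= 1 min).
#' @param stop_gap Consecutive non-cry epochs that close a sequence.
#'   Default 60 (= 5 min).
#' @param epoch_seconds Epoch length in seconds, for durations. Default 5.
#' @return A tibble with one row per sequence: `start_epoch`, `end_epoch`
#'   (0-based, inclusive), `duration_min`, and `cry_epochs` (cry count inside
#'   the sequence).
#' @examples
#' detect_sequences(c(rep(0, 10), rep(1, 6), rep(0, 70), 1, rep(0, 5)))
#' @export
detect_sequences <- function(labels, start_min_cry = 6, start_window = 12,
                             stop_gap = 60, epoch_seconds = 5) {
  labels <- label_vector(labels)
  if (start_min_cry < 1 || start_window < start_min_cry || stop_gap < 1) {
    stop("require 1 <= start_min_cry <= start_window and stop_gap >= 1",
         call. = FALSE)
  }
  m <- .seq_scan_cpp(labels, as.integer(start_min_cry),
                     as.integer(start_window), as.integer(stop_gap))
  cum <- cumsum(labels)
  n_seq <- nrow(m)
  tibble::new_tibble(list(
    start_epoch = m[, 1L],
    end_epoch = m[, 2L],
    duration_min = (m[, 2L] - m[, 1L] + 1) * epoch_seconds / 60,
    cry_epochs = if (n_seq) cum[m[, 2L] + 1L] - cum[m[, 1L] + 1L] + labels[m[, 1L] + 1L] else integer()
  ), nrow = n_seq)
}

#' Summarise the cry sequences of one label series
#'
#' @param labels As in [detect_sequences()].
#' @param subject Subject identifier carried into the summary.
#' @param ... Passed to [detect_sequences()].
#' @return A one-row tibble: `subject`, `n_sequences`, `total_duration_min`,
#'   `total_cry_epochs`, and the per-sequence table in list-column
#'   `sequences`.
#' @export
sequence_summary <- function(labels, subject = NA_character_, ...) {
  seqs <- detect_sequences(labels, ...)
  tibble::tibble(
    subject = subject,
    n_sequences = nrow(seqs),
    total_duration_min = sum(seqs$duration_min),
    total_cry_epochs = sum(label_vector(labels)),
    sequences = list(seqs)
  )
}

#' Compare annotated and predicted cry-sequence timelines
#'
#' Runs [detect_sequences()] on both label series and reports the per-subject
#' deltas used to judge the biomarker: absolute difference in sequence count
#' and in total sequence duration.
#'
#' @param annotated,predicted Binary label series on the same epoch grid.
#' @param subject Subject identifier.
#' @param ... Sequence parameters passed to [detect_sequences()].
#' @return A one-row tibble: `subject`, `annotated_count`, `predicted_count`,
#'   `annotated_duration_min`, `predicted_duration_min`,
#'   `annotated_cry_epochs`, `delta_count`, `delta_duration_min`, plus the
#'   two sequence tables as list-columns.
#' @export
compare_timelines <- function(annotated, predicted, subject = NA_character_, ...) {
  a <- label_vector(annotated)
  p <- label_vector(predicted)
  if (length(a) != length(p)) {
    stop("annotated and predicted series differ in length", call. = FALSE)
  }
  sa <- detect_sequences(a, ...)
  sp <- detect_sequences(p, ...)
  timeline_comparison(
    annotated_count = nrow(sa),
    predicted_count = nrow(sp),
    annotated_duration_min = sum(sa$duration_min),
    predicted_duration_min = sum(sp$duration_min),
    annotated_cry_epochs = sum(a),
    subject = subject,
    annotated_sequences = list(sa),
    predicted_sequences = list(sp)
  )
}

#' Assemble a timeline comparison from summary numbers
#'
#' Builds the same row as [compare_timelines()] from already-summarised
#' counts and durations — the form in which published per-subject results are
#' reported — so cohort statistics can be recomputed from printed tables.
#'
#' @param annotated_count,predicted_count Sequence counts.
#' @param annotated_duration_min,predicted_duration_min Total sequence
#'   durations (minutes).
#' @param annotated_cry_epochs Total annotated cry epochs (optional).
#' @param subject Subject identifier.
#' @param group Optional group label (e.g. `"hospital"`, `"home"`).
#' @param annotated_sequences,predicted_sequences Optional per-sequence
#'   tables (list of tibbles).
#' @return A one-row tibble; see [compare_timelines()].
#' @export
timeline_comparison <- function(annotated_count, predicted_count,
                                annotated_duration_min, predicted_duration_min,
                                annotated_cry_epochs = NA_real_,
                                subject = NA_character_, group = NA_character_,
                                annotated_sequences = NULL,
                                predicted_sequences = NULL) {
  out <- tibble::tibble(
    subject = subject,
    group = group,
    annotated_count = annotated_count,
    predicted_count = predicted_count,
    annotated_duration_min = annotated_duration_min,
    predicted_duration_min = predicted_duration_min,
    annotated_cry_epochs = annotated_cry_epochs,
    delta_count = abs(predicted_count - annotated_count),
    delta_duration_min = abs(predicted_duration_min - annotated_duration_min)
  )
  if (!is.null(annotated_sequences)) out$annotated_sequences <- annotated_sequences
  if (!is.null(predicted_sequences)) out$predicted_sequences <- predicted_sequences
  out
}

#' Cohort statistics over per-subject timeline comparisons
#'
#' Computes the cohort-level biomarker summaries: median and IQR (type-7
#' quantiles) of the annotated sequence count over all subjects, the total
#' annotated sequence count, median/IQR of the absolute count and duration
#' deltas restricted to subjects with at least one annotated sequence, and —
#' when `annotated_cry_epochs` and `group` are available — the median and IQR
#' of per-subject cry duration (epochs x 5 s) by group.
#'
#' @param comparisons A tibble of rows from [compare_timelines()] /
#'   [timeline_comparison()] (bind rows for the cohort).
#' @param epoch_seconds Epoch length used to convert cry epochs to minutes.
#'   Default 5.
#' @return A one-row tibble of cohort statistics, with per-group cry-duration
#'   medians nested in list-column `cry_duration_by_group`.
#' @export
summarize_cohort <- function(comparisons, epoch_seconds = 5) {
  stopifnot(is.data.frame(comparisons))
  if (nrow(comparisons) == 0L) stop("empty cohort", call. = FALSE)
  q <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))

  counts <- comparisons$annotated_count
  has_seq <- comparisons$annotated_count >= 1
  d_count <- comparisons$delta_count[has_seq]
  d_dur <- comparisons$delta_duration_min[has_seq]

  by_group <- NULL
  if (all(c("group", "annotated_cry_epochs") %in% names(comparisons)) &&
      any(!is.na(comparisons$annotated_cry_epochs))) {
    by_group <- comparisons |>
      dplyr::filter(!is.na(.data$annotated_cry_epochs)) |>
      dplyr::mutate(cry_min = .data$annotated_cry_epochs * epoch_seconds / 60) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        median_cry_duration_min = stats::median(.data$cry_min),
        q25_cry_duration_min = q(.data$cry_min, 0.25),
        q75_cry_duration_min = q(.data$cry_min, 0.75),
        .groups = "drop"
      )
  }

  out <- tibble::tibble(
    n_subjects = nrow(comparisons),
    total_annotated_sequences = sum(counts),
    median_annotated_count = stats::median(counts),
    q25_annotated_count = q(counts, 0.25),
    q75_annotated_count = q(counts, 0.75),
    median_abs_delta_count = stats::median(d_count),
    q25_abs_delta_count = q(d_count, 0.25),
    q75_abs_delta_count = q(d_count, 0.75),
    median_abs_delta_duration_min = stats::median(d_dur),
    q25_abs_delta_duration_min = q(d_dur, 0.25),
    q75_abs_delta_duration_min = q(d_dur, 0.75)
  )
  if (!is.null(by_group)) out$cry_duration_by_group <- list(by_group)
  out
}

#' Published 15-infant validation cohort summaries
#'
#' Per-subject results of a smartphone cry-detection validation study in 11
#' hospital-admitted and 4 at-home infants: recording duration, annotated and
#' algorithm-detected cry-epoch counts, per-subject classification rates, and
#' annotated vs. algorithm cry-sequence counts and durations. These published
#' summary numbers serve as reference inputs for the cohort statistics in
#' [summarize_cohort()].
#'
#' @return A tibble with one row per subject.
#' @examples
#' vc <- validation_cohort()
#' sum(vc$annotated_seq_count) # 39 annotated cry sequences in the cohort
#' @export
validation_cohort <- function() {
  tibble::tribble(
    ~subject, ~group, ~recording_min, ~annotated_cry_epochs, ~predicted_cry_epochs,
    ~sensitivity_pct, ~specificity_pct, ~ppv_pct, ~npv_pct,
    ~annotated_seq_count, ~predicted_seq_count,
    ~annotated_seq_duration_min, ~predicted_seq_duration_min,
    "1", "hospital", 764, 145, 120, 80, 99.5, 66.2, 99.7, 3, 5, 37, 59,
    "2", "hospital", 610, 65, 43, 90.7, 99.6, 60, 99.9, 3, 3, 19, 21,
    "3", "hospital", 245, 12, 11, 90.9, 99.9, 83.3, 99.9, 1, 1, 5, 6,
    "4", "hospital", 648, 52, 20, 80, 99.5, 30.7, 99.5, 3, 3, 17, 25,
    "5", "hospital", 540, 17, 12, 91.7, 99.9, 64.7, 99.9, 1, 1, 7, 8,
    "6", "hospital", 317, 721, 711, 82.3, 95.6, 81.1, 95.9, 7, 7, 117, 122,
    "7", "hospital", 16.5, 26, 24, 87.5, 97.1, 80.7, 98.2, 1, 1, 6, 8,
    "8", "hospital", 441, 200, 158, 66.5, 98.2, 52.5, 98.9, 7, 8, 55, 72,
    "9", "hospital", 77.5, 70, 80, 75, 98.8, 85.7, 97.7, 3, 3, 18.5, 26,
    "10", "hospital", 356, 99, 79, 62, 98.8, 49.5, 99.3, 3, 3, 22, 36,
    "11", "hospital", 452, 320, 290, 87.9, 98.7, 79.7, 99.3, 6, 7, 64, 80,
    "12", "home", 36, 38, 40, 95, 100, 100, 99.5, 1, 1, 2.8, 2.4,
    "13", "home", 13, 7, 7, 100, 100, 100, 100, 0, 0, 0, 0,
    "14", "home", 2, 25, 25, 100, 100, 100, 100, 0, 0, 0, 0,
    "15", "home", 1, 8, 8, 100, 100, 100, 100, 0, 0, 0, 0
  )
}

#' Cohort comparisons implied by the published validation summaries
#'
#' Reshapes [validation_cohort()] into the [timeline_comparison()] rows that
#' [summarize_cohort()] consumes.
#'
#' @return A tibble with one comparison row per subject.
#' @export
validation_comparisons <- function() {
  vc <- validation_cohort()
  dplyr::bind_rows(lapply(seq_len(nrow(vc)), function(i) {
    timeline_comparison(
      annotated_count = vc$annotated_seq_count[i],
      predicted_count = vc$predicted_seq_count[i],
      annotated_duration_min = vc$annotated_seq_duration_min[i],
      predicted_duration_min = vc$predicted_seq_duration_min[i],
      annotated_cry_epochs = vc$annotated_cry_epochs[i],
      subject = vc$subject[i],
      group = vc$group[i]
    )
  }))
}
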