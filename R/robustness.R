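#' Cumulative cry-count curve of a label series
#'
#' The running total of cry-labelled epochs over time — the repeatability
#' diagnostic used to compare repeated or perturbed runs of the detector
#' against the reference annotation.
#'
#' @param labels Binary label series (vector or tibble with `label`).
#' @param run Text label identifying the run/condition.
#' @return A `cry_curve` tibble: `run`, `epoch_index`, `cumulative`; the
#'   final count is `max(cumulative)`.
#' @export
cumulative_curve <- function(labels, run = "run") {
  l <- label_vector(labels)
  out <- tibble::tibble(
    run = run,
    epoch_index = seq_along(l) - 1L,
    cumulative = cumsum(l)
  )
  class(out) <- c("cry_curve", class(out))
  out
}

#' Compare cumulative cry-count curves against a reference
#'
#' @param reference A `cry_curve` (typically from ground-truth labels).
#' @param runs A `cry_curve`, a list of them, or several curves row-bound
#'   (distinguished by `run`).
#' @return A tibble with one row per run: `run`, `final_count`,
#'   `reference_count`, `final_delta`, `final_delta_pct` (relative to the
#'   reference final count), `max_abs_deviation`, and
#'   `epoch_max_deviation` (first epoch attaining it).
#' @export
compare_runs <- function(reference, runs) {
  stopifnot(inherits(reference, "cry_curve"))
  if (inherits(runs, "cry_curve")) runs <- list(runs)
  if (is.data.frame(runs)) runs <- split(runs, runs$run)
  ref_final <- max(reference$cumulative)
  dplyr::bind_rows(lapply(runs, function(r) {
    if (nrow(r) != nrow(reference)) {
      stop("curve '", r$run[1], "' has ", nrow(r), " epochs; reference has ",
           nrow(reference), call. = FALSE)
    }
    dev <- abs(r$cumulative - reference$cumulative)
    tibble::tibble(
      run = r$run[1],
      final_count = max(r$cumulative),
      reference_count = ref_final,
      final_delta = max(r$cumulative) - ref_final,
      final_delta_pct = if (ref_final > 0) 100 * (max(r$cumulative) - ref_final) / ref_final else NA_real_,
      max_abs_deviation = max(dev),
      epoch_max_deviation = which.max(dev) - 1L
    )
  }))
}

#' Run the detector over perturbed versions of a session
#'
#' The software analogue of re-recording robustness tests: for each
#' condition, perturb the session audio, re-extract features, predict with
#' the trained model, and build the cumulative cry-count curve. The reference
#' curve from the ground-truth labels is always included (run
#' `"reference"`), and the unperturbed detector run as `"original"`.
#'
#' @param audio Session audio ([cry_audio()] or WAV path).
#' @param truth Ground-truth label series for the session.
#' @param model A `cry_model`.
#' @param conditions Named list of perturbation argument lists for
#'   [perturb()], e.g.
#'   `list(att6 = list(attenuate_db = 6), tv = list(background = "babble", snr_db = 5))`.
#' @param screen Optional `cry_screen` report applied to extracted features.
#' @param registry Feature registry. Default [feature_registry()].
#' @return A list: `curves` (row-bound `cry_curve`s) and `report` (the
#'   [compare_runs()] table for all detector runs).
#' @export
run_conditions <- function(audio, truth, model, conditions = list(),
                           screen = NULL, registry = feature_registry()) {
  if (is.character(audio)) audio <- read_wav(audio)
  stopifnot(inherits(audio, "cry_audio"), inherits(model, "cry_model"))

  predict_curve <- function(a, run) {
    f <- extract_features(a, registry = registry)
    if (!is.null(screen)) f <- apply_screen(f, screen)
    cumulative_curve(predict_epochs(model, f)$label, run)
  }

  curves <- list(cumulative_curve(truth, "reference"),
                 predict_curve(audio, "original"))
  for (cn in names(conditions)) {
    pa <- do.call(perturb, c(list(audio), conditions[[cn]]))
    curves[[length(curves) + 1L]] <- predict_curve(pa, cn)
  }
  all_curves <- dplyr::bind_rows(curves)
  class(all_curves) <- c("cry_curve", class(all_curves))
  report <- compare_runs(curves[[1L]], curves[-1L])
  list(curves = all_curves, report = report)
}

#' Plot cumulative cry-count curves
#'
#' One line per run; the reference annotation is drawn first. Mirrors the
#' cumulative-count panels used to report detector repeatability.
#'
#' @param object A `cry_curve` tibble (possibly several runs row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cry_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$epoch_index * 5 / 60, y = .data$cumulative, colour = .data$run
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "cumulative cry epochs", colour = "run") +
    ggplot2::theme_minimal()
}

#' Plot annotated vs. predicted cry-sequence timelines
#'
#' Per-subject strips of annotated and predicted sequences on a common time
#' axis.
#'
#' @param comparisons Rows from [compare_timelines()] carrying
#'   `annotated_sequences` / `predicted_sequences` list-columns.
#' @return A ggplot object.
#' @export
plot_timelines <- function(comparisons) {
  stopifnot(all(c("annotated_sequences", "predicted_sequences") %in% names(comparisons)))
  bands <- dplyr::bind_rows(lapply(seq_len(nrow(comparisons)), function(i) {
    dplyr::bind_rows(
      dplyr::mutate(comparisons$annotated_sequences[[i]], source = "annotated"),
      dplyr::mutate(comparisons$predicted_sequences[[i]], source = "predicted")
    ) |>
      dplyr::mutate(subject = comparisons$subject[i])
  }))
  ggplot2::ggplot(bands) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_epoch * 5 / 60, xmax = (.data$end_epoch + 1) * 5 / 60,
      ymin = as.integer(factor(.data$source)) - 0.45,
      ymax = as.integer(factor(.data$source)) + 0.45,
      fill = .data$source
    )) +
    ggplot2::facet_wrap(~subject, ncol = 1, strip.position = "left") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
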