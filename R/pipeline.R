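#' Pipeline configuration defaults
#'
#' Collects every tunable parameter of the detection pipeline in one list:
#' the canonical sample rate and epoch grid, framing, screening thresholds,
#' cross-validation settings, the decision threshold, and the cry-sequence
#' start/stop criteria (at the defaults: at least 6 cry epochs within 1 min
#' to start, 5 min without crying to stop).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list with a `config_hash` attribute for provenance.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_rate = 16000,
    epoch_seconds = 5,
    frame_ms = 25,
    hop_ms = 10,
    n_mfcc = 12,
    n_mel = 26,
    smd_threshold = 0.5,
    sd_ratio_bounds = c(0.5, 2),
    k_folds = 5,
    decision_threshold = 0.5,
    start_min_cry = 6,
    start_window = 12,
    stop_gap = 60,
    seed = 7
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","), ""),
             sep = "=", collapse = ";")
  # polynomial rolling hash, hex — a stable dependency-free fingerprint
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default re-recording conditions for feature screening
#'
#' Software analogues of re-recording the reference audio under changed
#' ambient conditions: greater distance (6 dB attenuation), a physical
#' barrier (4 kHz low-pass), and ambient TV-like noise (babble mixed at
#' 15 dB SNR).
#'
#' @return Named list of [perturb()] argument lists.
#' @export
default_screen_conditions <- function() {
  list(
    distance = list(attenuate_db = 6),
    barrier = list(lowpass_hz = 4000),
    tv_noise = list(background = "babble", snr_db = 15)
  )
}

#' Screen features using perturbed re-recordings of reference clips
#'
#' Re-records each reference clip under every condition via [perturb()],
#' extracts features, and hands the condition feature sets to
#' [screen_features()].
#'
#' @param clips Tibble of reference clips (`epoch_index`, `samples`), e.g.
#'   a subset of [synth_corpus()].
#' @param conditions Named list of [perturb()] argument lists.
#'   Default [default_screen_conditions()].
#' @param registry Feature registry.
#' @param sample_rate Sampling rate of the clips. Default 16000.
#' @param seed Integer seed for stochastic perturbations.
#' @param ... Thresholds passed on to [screen_features()].
#' @return A `cry_screen` report.
#' @export
screen_from_conditions <- function(clips, conditions = default_screen_conditions(),
                                   registry = feature_registry(),
                                   sample_rate = 16000, seed = 1, ...) {
  ref <- extract_features(clips, sample_rate, registry)
  cond_feats <- lapply(seq_along(conditions), function(ci) {
    perturbed <- clips
    perturbed$samples <- lapply(seq_len(nrow(clips)), function(i) {
      do.call(perturb, c(list(cry_audio(clips$samples[[i]], sample_rate)),
                         conditions[[ci]], list(seed = seed + ci * 1000L + i)))$samples
    })
    extract_features(perturbed, sample_rate, registry)
  })
  names(cond_feats) <- names(conditions)
  screen_features(ref, cond_feats, ...)
}

#' End-to-end training benchmark on synthetic audio
#'
#' The package's standing substitute for a real training corpus: generate a
#' labelled clip corpus ([synth_corpus()]), extract features, screen them
#' against perturbed re-recordings of a clip subset, run the cross-validated
#' grid search for each classifier family, and select the final model by
#' MCC. Deterministic given the seed.
#'
#' @param n_cry,n_noncry Corpus composition. Defaults 300 / 400.
#' @param seed Integer seed for the whole benchmark. Default 7.
#' @param families Families to search. Default all three.
#' @param n_screen_clips Clips re-recorded for screening (taken evenly from
#'   both classes). Default 60.
#' @param config Pipeline configuration from [pipeline_config()].
#' @return A list of class `cry_benchmark`: `features` (with labels),
#'   `screen`, `screened_features`, `cv_results`, `model`, and `summary`
#'   (per-family CV means/SDs).
#' @export
run_benchmark <- function(n_cry = 300, n_noncry = 400, seed = 7,
                          families = model_families(),
                          n_screen_clips = 60,
                          config = pipeline_config(seed = seed)) {
  registry <- feature_registry(config$n_mfcc, config$n_mel)
  corpus <- synth_corpus(n_cry, n_noncry, epoch_seconds = config$epoch_seconds,
                         sample_rate = config$sample_rate, seed = seed)
  features <- extract_features(corpus, config$sample_rate, registry)
  features$label <- corpus$label

  # screening clips: alternate classes so both contribute to stability checks
  half <- n_screen_clips %/% 2L
  pick <- c(seq_len(min(half, n_cry)),
            n_cry + seq_len(min(n_screen_clips - half, n_noncry)))
  screen <- screen_from_conditions(
    corpus[pick, ], registry = registry, sample_rate = config$sample_rate,
    seed = seed,
    smd_threshold = config$smd_threshold,
    sd_ratio_bounds = config$sd_ratio_bounds
  )
  screened <- apply_screen(features, screen)

  cv_results <- lapply(families, function(fam) {
    grid_search_cv(screened, family = fam, k = config$k_folds, seed = seed,
                   threshold = config$decision_threshold)
  })
  model <- select_final_model(cv_results, screened, seed = seed)

  structure(
    list(
      features = features,
      screen = screen,
      screened_features = screened,
      cv_results = cv_results,
      model = model,
      summary = dplyr::bind_rows(lapply(cv_results, glance)),
      config = config
    ),
    class = "cry_benchmark"
  )
}

#' @export
print.cry_benchmark <- function(x, ...) {
  cat("<cry_benchmark>\n")
  cat("  features:", nrow(x$features), "epochs x",
      length(feature_columns(x$features)), "features;",
      sum(x$screen$retained), "retained after screening\n")
  print(as.data.frame(x$summary[, c("family", "mean_mcc", "mean_sensitivity",
                                    "mean_accuracy")]), row.names = FALSE)
  cat("  final model:", x$model$family, "\n")
  invisible(x)
}

#' Detect crying in a session and post-process into sequences
#'
#' The full inference path: segment the audio, extract and screen features,
#' predict per-epoch labels, and detect cry sequences.
#'
#' @param audio A [cry_audio()] or WAV path.
#' @param model A `cry_model`.
#' @param screen Optional `cry_screen` applied before prediction.
#' @param registry Feature registry matching the model's training features.
#' @param config Pipeline configuration (sequence criteria, epoch length).
#' @return A list: `predictions` (per-epoch tibble), `sequences`
#'   (from [detect_sequences()]).
#' @export
detect_cries <- function(audio, model, screen = NULL,
                         registry = feature_registry(),
                         config = pipeline_config()) {
  if (is.character(audio)) audio <- read_wav(audio, config$sample_rate)
  f <- extract_features(audio, registry = registry)
  if (!is.null(screen)) f <- apply_screen(f, screen)
  pred <- predict_epochs(model, f)
  seqs <- detect_sequences(pred$label,
                           start_min_cry = config$start_min_cry,
                           start_window = config$start_window,
                           stop_gap = config$stop_gap,
                           epoch_seconds = config$epoch_seconds)
  list(predictions = pred, sequences = seqs)
}
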