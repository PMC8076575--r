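#' Feature registry: low-level descriptors x statistical functionals
#'
#' Defines the fixed, ordered feature set computed per 5-s epoch. Each of the
#' 42 frame-level low-level descriptors (LLDs) — 12 MFCCs, 26 log mel-band
#' energies, RMS energy, zero-crossing rate, fundamental frequency, and
#' voicing probability — is summarised by 13 statistical functionals (mean,
#' population SD, min, max, range, percentiles 1/25/50/75/99, IQR, skewness,
#' excess kurtosis), for 546 named features of the form `<lld>_<functional>`
#' (e.g. `mfcc3_p99`).
#'
#' @param n_mfcc Number of cepstral coefficients (coefficients 1..n, the 0th
#'   is excluded). Default 12.
#' @param n_mel Number of triangular mel filters spanning 20-8000 Hz.
#'   Default 26.
#' @return An object of class `cry_registry`: a list with `llds`,
#'   `functionals`, `names` (the full ordered feature-name vector), and the
#'   framing parameters.
#' @export
feature_registry <- function(n_mfcc = 12, n_mel = 26) {
  llds <- c(
    paste0("mfcc", seq_len(n_mfcc)),
    sprintf("mel%02d", seq_len(n_mel)),
    "rms", "zcr", "f0", "voicing"
  )
  functionals <- c(
    "mean", "sd", "min", "max", "range",
    "p1", "p25", "p50", "p75", "p99",
    "iqr", "skew", "kurt"
  )
  nm <- as.vector(t(outer(llds, functionals, paste, sep = "_")))
  stopifnot(!anyDuplicated(nm))
  structure(
    list(
      llds = llds, functionals = functionals, names = nm,
      n_mfcc = n_mfcc, n_mel = n_mel,
      frame_ms = 25, hop_ms = 10,
      fmin = 20, fmax = 8000,
      f0_min = 75, f0_max = 600, voicing_threshold = 0.45
    ),
    class = "cry_registry"
  )
}

#' @export
print.cry_registry <- function(x, ...) {
  cat(sprintf(
    "<cry_registry> %d LLDs x %d functionals = %d features (%g ms frames, %g ms hop)\n",
    length(x$llds), length(x$functionals), length(x$names), x$frame_ms, x$hop_ms
  ))
  invisible(x)
}

#' Serialize / read a feature registry as JSON (provenance record)
#'
#' @param registry A [feature_registry()] object.
#' @param path JSON file path.
#' @return `path` invisibly for write; a `cry_registry` for read.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "cry_registry"))
  jsonlite::write_json(unclass(registry), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "cry_registry")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mel x n_bins matrix over an FFT of size nfft.
mel_filterbank <- function(n_mel, nfft, sample_rate, fmin, fmax) {
  n_bins <- nfft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sample_rate / nfft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mel + 2L))
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix rows 1..n_mfcc (0th coefficient excluded).
dct_matrix <- function(n_mfcc, n_mel) {
  i <- seq_len(n_mfcc)
  j <- seq_len(n_mel) - 1L
  sqrt(2 / n_mel) * cos(outer(i, j + 0.5) * pi / n_mel)
}

#' Compute frame-level low-level descriptors for one epoch
#'
#' Frames the waveform (25 ms Hamming windows, 10 ms hop) and computes, per
#' frame: MFCC 1-12, log mel-band energies for 26 triangular filters spanning
#' 20-8000 Hz (floored at `log(1e-10)` for silence safety), RMS energy,
#' zero-crossing rate (crossings/s), fundamental frequency F0 (Hz; 0 when
#' unvoiced), and voicing probability — the peak of the normalized
#' cross-correlation over pitch lags 75-600 Hz, clamped to `[0, 1]`.
#'
#' @param samples Numeric vector, one epoch of audio at `sample_rate`.
#' @param sample_rate Sampling rate in Hz. Default 16000.
#' @param registry A [feature_registry()] supplying LLD parameters.
#' @return A tibble with one row per frame and one column per LLD, plus
#'   `frame` (0-based index).
#' @export
compute_llds <- function(samples, sample_rate = 16000, registry = feature_registry()) {
  stopifnot(inherits(registry, "cry_registry"))
  x <- as.numeric(samples)
  flen <- as.integer(round(registry$frame_ms / 1000 * sample_rate))
  hop <- as.integer(round(registry$hop_ms / 1000 * sample_rate))
  if (length(x) < flen) stop("epoch shorter than one frame", call. = FALSE)
  n_frames <- (length(x) - flen) %/% hop + 1L

  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- x[idx]
  dim(frames) <- dim(idx) # flen x n_frames

  # --- spectral LLDs on Hamming-windowed frames ---
  nfft <- stats::nextn(flen, c(2, 3, 5))
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1L) / (flen - 1L))
  padded <- matrix(0, nfft, n_frames)
  padded[seq_len(flen), ] <- frames * win
  spec <- stats::mvfft(padded)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  pow <- Re(spec)^2 + Im(spec)^2

  fb <- mel_filterbank(registry$n_mel, nfft, sample_rate, registry$fmin, registry$fmax)
  mel <- fb %*% pow                       # n_mel x n_frames
  log_mel <- log(pmax(mel, 1e-10))
  mfcc <- dct_matrix(registry$n_mfcc, registry$n_mel) %*% log_mel

  # --- time-domain LLDs on raw frames ---
  rms <- sqrt(colMeans(frames^2))
  pos <- frames >= 0
  zcr <- colSums(pos[-1L, , drop = FALSE] != pos[-flen, , drop = FALSE]) *
    sample_rate / flen

  # --- pitch & voicing: normalized cross-correlation over the pitch lag band ---
  lmin <- max(2L, floor(sample_rate / registry$f0_max))
  lmax <- min(flen - 1L, ceiling(sample_rate / registry$f0_min))
  nfft2 <- stats::nextn(flen + lmax + 1L, c(2, 3, 5))
  padded2 <- matrix(0, nfft2, n_frames)
  padded2[seq_len(flen), ] <- frames
  sp2 <- stats::mvfft(padded2)
  ac <- Re(stats::mvfft(Re(sp2)^2 + Im(sp2)^2, inverse = TRUE)) / nfft2 # row l+1 = autocorr at lag l
  lags <- lmin:lmax
  cs <- matrix(0, flen + 1L, n_frames) # (flen+1) x n_frames cumulative energy
  cs[-1L, ] <- apply(frames^2, 2L, cumsum)
  e_total <- cs[flen + 1L, ]
  # E1(tau) = sum_{t<=flen-tau} x_t^2 ; E2(tau) = sum_{t>tau} x_t^2
  e1 <- cs[flen - lags + 1L, , drop = FALSE]
  e2 <- matrix(e_total, length(lags), n_frames, byrow = TRUE) -
    cs[lags + 1L, , drop = FALSE]
  ncc <- ac[lags + 1L, , drop = FALSE] / sqrt(pmax(e1 * e2, 1e-20))
  ncc[!is.finite(ncc)] <- 0
  voicing <- pmin(pmax(suppressWarnings(apply(ncc, 2L, max)), 0), 1)
  # pick the earliest local maximum within 90% of the peak to avoid octave
  # (period-multiple) errors that a bare argmax commits on periodic signals
  nl <- length(lags)
  local_max <- rbind(ncc[1L, , drop = FALSE] >= ncc[2L, , drop = FALSE],
                     ncc[-c(1L, nl), , drop = FALSE] >= ncc[-c(nl - 1L, nl), , drop = FALSE] &
                       ncc[-c(1L, nl), , drop = FALSE] >= ncc[-c(1L, 2L), , drop = FALSE],
                     ncc[nl, , drop = FALSE] >= ncc[nl - 1L, , drop = FALSE])
  qualify <- local_max & ncc >= rep(0.9 * voicing, each = nl)
  first_q <- max.col(t(qualify), ties.method = "first") # first TRUE per frame
  best_lag <- lags[first_q]
  f0 <- ifelse(voicing >= registry$voicing_threshold, sample_rate / best_lag, 0)

  out <- cbind(t(mfcc), t(log_mel), rms, zcr, f0, voicing)
  colnames(out) <- registry$llds
  tibble::as_tibble(out) |>
    tibble::add_column(frame = seq_len(n_frames) - 1L, .before = 1L)
}

#' Summarise frame-level descriptors into a fixed-length feature vector
#'
#' Applies the registry's 13 statistical functionals to each LLD's frame
#' series. Percentiles use type-7 linear interpolation; SD, skewness and
#' kurtosis use population moments, and zero-variance series get skewness and
#' kurtosis 0 rather than NaN.
#'
#' @param frames A tibble from [compute_llds()].
#' @param registry The [feature_registry()] the frames were computed under.
#' @return A named numeric vector of length `length(registry$names)`, ordered
#'   per the registry.
#' @export
apply_functionals <- function(frames, registry = feature_registry()) {
  stopifnot(inherits(registry, "cry_registry"))
  m <- as.matrix(frames[, registry$llds, drop = FALSE])
  if (nrow(m) == 0L) stop("empty frame series", call. = FALSE)

  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  m2 <- colMeans(ctr^2)
  m3 <- colMeans(ctr^3)
  m4 <- colMeans(ctr^4)
  sdv <- sqrt(m2)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  qs <- apply(m, 2L, stats::quantile, probs = c(0.01, 0.25, 0.5, 0.75, 0.99),
              names = FALSE, type = 7)
  mins <- apply(m, 2L, min)
  maxs <- apply(m, 2L, max)

  per_lld <- rbind(
    mean = mu, sd = sdv, min = mins, max = maxs, range = maxs - mins,
    p1 = qs[1L, ], p25 = qs[2L, ], p50 = qs[3L, ], p75 = qs[4L, ], p99 = qs[5L, ],
    iqr = qs[4L, ] - qs[2L, ], skew = skew, kurt = kurt
  )
  out <- as.vector(per_lld[registry$functionals, registry$llds])
  names(out) <- registry$names
  out
}

#' Extract the per-epoch feature matrix from segmented audio
#'
#' Runs [compute_llds()] and [apply_functionals()] on every epoch, yielding
#' the feature matrix that feeds screening and classification.
#'
#' @param epochs A tibble from [segment_epochs()] (columns `epoch_index`,
#'   `start_time_s`, `samples`), or a [cry_audio()] object (segmented
#'   internally).
#' @param sample_rate Sampling rate of the epoch samples (ignored when
#'   `epochs` is a `cry_audio`). Default 16000.
#' @param registry A [feature_registry()].
#' @return A tibble: `epoch_index`, `start_time_s`, then one column per
#'   registry feature. Carries the registry in attribute `registry`.
#' @examples
#' a <- synth_cry(10, seed = 1)
#' feats <- extract_features(a)
#' dim(feats)
#' @export
extract_features <- function(epochs, sample_rate = 16000, registry = feature_registry()) {
  if (inherits(epochs, "cry_audio")) {
    sample_rate <- epochs$sample_rate
    epochs <- segment_epochs(epochs)
  }
  stopifnot(is.data.frame(epochs), all(c("epoch_index", "samples") %in% names(epochs)))
  vecs <- lapply(epochs$samples, function(s) {
    apply_functionals(compute_llds(s, sample_rate, registry), registry)
  })
  fm <- do.call(rbind, vecs)
  out <- dplyr::bind_cols(
    tibble::tibble(
      epoch_index = epochs$epoch_index,
      start_time_s = if ("start_time_s" %in% names(epochs)) epochs$start_time_s else epochs$epoch_index * 5
    ),
    tibble::as_tibble(fm)
  )
  attr(out, "registry") <- registry
  out
}

# Feature columns of a feature tibble (everything except the epoch grid ids
# and any label/provenance columns).
feature_columns <- function(features) {
  setdiff(names(features),
          c("epoch_index", "start_time_s", "label", "clip", "subject",
            "kind", "group", "probability"))
}
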