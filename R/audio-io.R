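#' Audio signal container
#'
#' Constructs the canonical in-memory audio representation used throughout the
#' package: a mono waveform with amplitudes in `[-1, 1]` and a sample rate in
#' Hz. All pipeline stages operate on this container.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @return An object of class `cry_audio`: a list with elements `samples`,
#'   `sample_rate`, and derived `duration` (seconds).
#' @examples
#' a <- cry_audio(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' a$duration
#' @export
cry_audio <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("empty audio: zero samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("audio samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  structure(
    list(
      samples = samples,
      sample_rate = sample_rate,
      duration = length(samples) / sample_rate
    ),
    class = "cry_audio"
  )
}

#' @export
print.cry_audio <- function(x, ...) {
  cat(sprintf(
    "<cry_audio> %.2f s @ %d Hz (%d samples, peak %.3f)\n",
    x$duration, as.integer(x$sample_rate), length(x$samples), max(abs(x$samples))
  ))
  invisible(x)
}

#' Read a WAV file into a canonical mono audio signal
#'
#' Parses a RIFF/WAVE file (PCM 8/16/24/32-bit or IEEE float 32/64-bit),
#' mixes stereo down to mono by channel averaging, resamples to the target
#' rate, and peak-normalizes only when any sample exceeds full scale.
#'
#' @param path Path to a WAV file.
#' @param target_rate Canonical sample rate in Hz. Default 16000.
#' @return A [cry_audio()] object at `target_rate`.
#' @seealso [write_wav()], [segment_epochs()]
#' @export
read_wav <- function(path, target_rate = 16000) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAV file: ", path, call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels     = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV: missing fmt or data chunk in ", path, call. = FALSE)
  }
  if (length(data_raw) == 0L) {
    stop("empty audio: WAV data chunk has zero length", call. = FALSE)
  }

  x <- decode_wav_samples(data_raw, fmt)
  if (fmt$channels > 1L) {
    # mix down: average across channels (samples are interleaved)
    n <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels, byrow = TRUE))
  }
  if (length(x) == 0L) stop("empty audio: no samples decoded", call. = FALSE)

  x <- resample_to(x, fmt$sample_rate, target_rate)
  cry_audio(x, target_rate)
}

decode_wav_samples <- function(raw, fmt) {
  n_bytes <- fmt$bits %/% 8L
  n <- floor(length(raw) / n_bytes)
  if (fmt$audio_format == 1L) { # integer PCM
    if (fmt$bits == 8L) {
      as.integer(raw[seq_len(n)]) / 127.5 - 1
    } else if (fmt$bits == 16L) {
      readBin(raw, "integer", n, size = 2, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      b <- as.integer(raw[seq_len(n * 3L)])
      v <- b[seq(1, by = 3, length.out = n)] +
        b[seq(2, by = 3, length.out = n)] * 256L +
        b[seq(3, by = 3, length.out = n)] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(raw, "integer", n, size = 4, endian = "little") / 2147483648
    } else {
      stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    }
  } else if (fmt$audio_format == 3L) { # IEEE float
    readBin(raw, "numeric", n, size = n_bytes, endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")", call. = FALSE)
  }
}

# Polyphase rational resampling via signal::resample; identity when rates match.
resample_to <- function(x, from_rate, to_rate) {
  if (from_rate == to_rate) {
    return(x)
  }
  pq <- rational_approx(to_rate / from_rate)
  signal::resample(x, pq[1], pq[2])
}

# Continued-fraction rational approximation p/q of a positive ratio.
rational_approx <- function(r, max_den = 1000L, tol = 1e-9) {
  h <- c(1, floor(r)); k <- c(0, 1)
  x <- r - floor(r)
  while (abs(h[2] / k[2] - r) > tol * r && k[2] <= max_den && x > tol) {
    x <- 1 / x
    a <- floor(x)
    h <- c(h[2], a * h[2] + h[1])
    k <- c(k[2], a * k[2] + k[1])
    x <- x - a
  }
  as.integer(c(h[2], k[2]))
}

#' Write an audio signal to a 16-bit PCM WAV file
#'
#' @param audio A [cry_audio()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "cry_audio"))
  x <- pmin(pmax(audio$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  sr <- as.integer(audio$sample_rate)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Segment an audio signal into non-overlapping 5-second epochs
#'
#' Epochs tile the signal from time zero; a trailing remainder shorter than
#' `epoch_seconds` is discarded. Epochs are the unit of annotation,
#' classification, and all downstream biomarkers.
#'
#' @param audio A [cry_audio()] object.
#' @param epoch_seconds Epoch length in seconds. Default 5.
#' @return A tibble with one row per epoch: `epoch_index` (0-based),
#'   `start_time_s`, and `samples` (list-column of numeric vectors, each
#'   exactly `epoch_seconds * sample_rate` samples).
#' @examples
#' a <- synth_noncry("white_noise", duration = 12.4, seed = 1)
#' segment_epochs(a) # 2 epochs; the trailing 2.4 s is dropped
#' @export
segment_epochs <- function(audio, epoch_seconds = 5) {
  stopifnot(inherits(audio, "cry_audio"))
  spe <- as.integer(round(epoch_seconds * audio$sample_rate))
  n_epochs <- floor(length(audio$samples) / spe)
  if (n_epochs == 0L) {
    warning("signal shorter than one epoch (", epoch_seconds, " s); no epochs produced")
    return(tibble::tibble(
      epoch_index = integer(), start_time_s = numeric(), samples = list()
    ))
  }
  idx <- seq_len(n_epochs) - 1L
  tibble::tibble(
    epoch_index = idx,
    start_time_s = idx * epoch_seconds,
    samples = lapply(idx, function(i) audio$samples[(i * spe + 1L):((i + 1L) * spe)])
  )
}
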