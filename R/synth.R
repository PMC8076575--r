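#' Synthesize a stylized infant-cry signal
#'
#' Generates voiced harmonic cry phrases with a rising-falling F0 contour,
#' separated by unvoiced pauses — a source model of the gross
#' spectro-temporal structure of infant crying (F0 roughly 300-600 Hz,
#' ~1 s expiratory phrases), not a perceptual resynthesis. Deterministic
#' given the seed.
#'
#' @param duration Total duration in seconds (> 0).
#' @param f0_base Centre fundamental frequency in Hz. Default 450.
#' @param f0_excursion Contour excursion in Hz (rise-fall peak above base at
#'   mid-phrase, with a small random per-phrase offset). Default 100.
#' @param phrase_seconds Mean voiced phrase length in seconds. Default 1.
#' @param pause_seconds Mean unvoiced pause length in seconds. Default 0.4.
#' @param harmonics Number of harmonics, amplitude decaying as 1/k. Default 8.
#' @param jitter Relative cycle-to-cycle F0 noise (slow modulation).
#'   Default 0.02.
#' @param sample_rate Sampling rate in Hz. Default 16000.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A [cry_audio()] object.
#' @examples
#' cry <- synth_cry(5, seed = 42)
#' @export
synth_cry <- function(duration, f0_base = 450, f0_excursion = 100,
                      phrase_seconds = 1, pause_seconds = 0.4,
                      harmonics = 8, jitter = 0.02,
                      sample_rate = 16000, seed = 1) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (f0_base - f0_excursion <= 0) {
    stop("`f0_base - f0_excursion` must stay positive", call. = FALSE)
  }
  n <- as.integer(round(duration * sample_rate))
  withr::with_seed(seed, {
    x <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      plen <- as.integer(round(stats::runif(1, 0.85, 1.15) * phrase_seconds * sample_rate))
      plen <- min(plen, n - pos + 1L)
      if (plen > sample_rate * 0.1) { # skip fragments shorter than 100 ms
        u <- seq_len(plen) / plen
        offset <- stats::rnorm(1, 0, f0_excursion / 4)
        f0 <- f0_base + offset + f0_excursion * sin(pi * u)
        f0 <- f0 * (1 + jitter * slow_noise(plen, sample_rate, cutoff_hz = 8))
        phase <- 2 * pi * cumsum(f0) / sample_rate
        tone <- numeric(plen)
        for (k in seq_len(harmonics)) tone <- tone + sin(k * phase) / k
        env <- sin(pi * u)^0.5 # rise-fall amplitude envelope
        x[pos:(pos + plen - 1L)] <- 0.35 * env * tone / harmonics_norm(harmonics)
      }
      gap <- as.integer(round(stats::runif(1, 0.75, 1.25) * pause_seconds * sample_rate))
      pos <- pos + plen + gap
    }
    cry_audio(x, sample_rate)
  })
}

harmonics_norm <- function(k) sum(1 / seq_len(k))

# Smooth unit-variance noise: white noise low-passed below cutoff_hz.
slow_noise <- function(n, sample_rate, cutoff_hz) {
  w <- stats::rnorm(n)
  b <- signal::butter(2, min(0.99, cutoff_hz / (sample_rate / 2)))
  s <- signal::filtfilt(b, w)
  s / max(stats::sd(s), 1e-12)
}

#' Synthesize non-cry domestic sounds
#'
#' Deterministic generators for the non-cry sound classes used to train and
#' test the detector: broadband noise, a steady tone, speech-like babble
#' (low-pitched multi-voice harmonic murmur), and impulsive knocks.
#'
#' @param kind One of `"white_noise"`, `"pink_noise"`, `"tone"`, `"babble"`,
#'   `"knock"`.
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate in Hz. Default 16000.
#' @param tone_hz Tone frequency when `kind = "tone"`. Default 200.
#' @return A [cry_audio()] object.
#' @export
synth_noncry <- function(kind, duration, seed = 1, sample_rate = 16000, tone_hz = 200) {
  kinds <- c("white_noise", "pink_noise", "tone", "babble", "knock")
  if (!kind %in% kinds) {
    stop("unknown non-cry kind: ", kind, " (expected one of ",
         paste(kinds, collapse = ", "), ")", call. = FALSE)
  }
  n <- as.integer(round(duration * sample_rate))
  withr::with_seed(seed, {
    x <- switch(kind,
      white_noise = 0.1 * stats::rnorm(n),
      pink_noise = {
        w <- stats::rnorm(n)
        sp <- stats::fft(w)
        f <- pmax(1, seq_len(n) - 1)
        f <- pmin(f, n - f + 1) # mirror for negative frequencies
        y <- Re(stats::fft(sp / sqrt(f), inverse = TRUE)) / n
        0.1 * y / stats::sd(y)
      },
      tone = 0.5 * sin(2 * pi * tone_hz * seq_len(n) / sample_rate),
      babble = synth_babble(n, sample_rate),
      knock = synth_knock(n, sample_rate)
    )
    cry_audio(x, sample_rate)
  })
}

# Multi-voice low-pitch murmur: overlapping harmonic voices with wandering F0
# and on/off syllabic envelopes, over a mild noise floor.
synth_babble <- function(n, sample_rate) {
  x <- 0.02 * stats::rnorm(n)
  for (v in 1:3) {
    f0 <- 120 + 60 * stats::runif(1) +
      30 * slow_noise(n, sample_rate, cutoff_hz = 3)
    f0 <- pmax(f0, 60)
    phase <- 2 * pi * cumsum(f0) / sample_rate
    tone <- numeric(n)
    for (k in 1:6) tone <- tone + sin(k * phase) / k
    gate <- slow_noise(n, sample_rate, cutoff_hz = 4) > 0 # syllabic on/off
    env <- signal::filtfilt(signal::butter(2, 8 / (sample_rate / 2)), as.numeric(gate))
    x <- x + 0.12 * env * tone / harmonics_norm(6)
  }
  x
}

# Sparse exponentially-decaying broadband bursts (door knocks, footsteps).
synth_knock <- function(n, sample_rate) {
  x <- 0.005 * stats::rnorm(n)
  n_hits <- max(1L, as.integer(round(n / sample_rate * 2)))
  at <- sort(sample.int(max(1L, n - sample_rate %/% 5L), n_hits))
  dur <- as.integer(sample_rate * 0.15)
  decay <- exp(-seq_len(dur) / (sample_rate * 0.02))
  for (t0 in at) {
    seg <- t0:min(n, t0 + dur - 1L)
    x[seg] <- x[seg] + 0.6 * decay[seq_along(seg)] * stats::rnorm(length(seg))
  }
  x
}

#' Generate a labelled recording session on the 5-s epoch grid
#'
#' Builds a continuous background soundscape with cry bouts mixed in at a
#' stated signal-to-noise ratio, together with the ground-truth per-epoch
#' label series. The default 3% cry prevalence mirrors the class imbalance of
#' real-world validation recordings.
#'
#' @param total_epochs Session length in 5-s epochs.
#' @param bouts A data frame with columns `start_epoch` (0-based) and
#'   `length` (epochs), non-overlapping and within range; or `NULL` to place
#'   bouts randomly via `cry_fraction`.
#' @param cry_fraction Fraction of epochs carrying crying when `bouts` is
#'   `NULL`. Default 0.03.
#' @param background Non-cry kind for the soundscape. Default `"white_noise"`.
#' @param snr_db Cry-to-background SNR in dB within bouts. Default 10.
#' @param epoch_seconds Epoch length in seconds. Default 5.
#' @param sample_rate Sampling rate in Hz. Default 16000.
#' @param seed Integer seed.
#' @return A list: `audio` ([cry_audio()], exactly
#'   `total_epochs * epoch_seconds` seconds), `labels` (tibble
#'   `epoch_index`, `label` with 1 = cry), and `bouts`.
#' @export
synth_session <- function(total_epochs, bouts = NULL, cry_fraction = 0.03,
                          background = "white_noise", snr_db = 10,
                          epoch_seconds = 5, sample_rate = 16000, seed = 1) {
  stopifnot(total_epochs >= 1)
  if (is.null(bouts)) {
    bouts <- withr::with_seed(seed + 1L, sample_bouts(total_epochs, cry_fraction))
  }
  bouts <- dplyr::arrange(tibble::as_tibble(bouts), .data$start_epoch)
  ends <- bouts$start_epoch + bouts$length
  if (nrow(bouts) > 0) {
    if (any(bouts$start_epoch < 0) || any(ends > total_epochs)) {
      stop("cry bouts fall outside the session", call. = FALSE)
    }
    if (nrow(bouts) > 1 && any(bouts$start_epoch[-1] < ends[-nrow(bouts)])) {
      stop("cry bouts overlap", call. = FALSE)
    }
  }

  spe <- as.integer(epoch_seconds * sample_rate)
  n <- total_epochs * spe
  bg <- synth_noncry(background, n / sample_rate, seed = seed, sample_rate = sample_rate)
  x <- bg$samples[seq_len(n)]
  p_bg <- mean(x^2)

  labels <- integer(total_epochs)
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    cry <- synth_cry(b$length * epoch_seconds, sample_rate = sample_rate,
                     seed = seed + 100L + i)
    g <- sqrt(p_bg * 10^(snr_db / 10) / max(mean(cry$samples^2), 1e-12))
    seg <- (b$start_epoch * spe + 1L):((b$start_epoch + b$length) * spe)
    x[seg] <- x[seg] + g * cry$samples
    labels[(b$start_epoch + 1L):(b$start_epoch + b$length)] <- 1L
  }
  list(
    audio = cry_audio(x, sample_rate),
    labels = tibble::tibble(epoch_index = seq_len(total_epochs) - 1L, label = labels),
    bouts = bouts
  )
}

# Random non-overlapping bouts totalling ~fraction of the session.
sample_bouts <- function(total_epochs, cry_fraction, mean_bout = 6L) {
  target <- round(total_epochs * cry_fraction)
  bouts <- list()
  placed <- 0L
  occupied <- rep(FALSE, total_epochs)
  tries <- 0L
  while (placed < target && tries < 200L) {
    tries <- tries + 1L
    len <- max(1L, min(target - placed, stats::rpois(1, mean_bout)))
    if (len >= total_epochs) len <- max(1L, total_epochs %/% 2L)
    s <- sample.int(total_epochs - len + 1L, 1L) - 1L
    span <- (s + 1L):(s + len)
    pad <- max(1L, s):min(total_epochs, s + len + 1L) # keep bouts separated
    if (!any(occupied[pad])) {
      occupied[span] <- TRUE
      bouts[[length(bouts) + 1L]] <- tibble::tibble(start_epoch = s, length = len)
      placed <- placed + len
    }
  }
  if (length(bouts) == 0L) {
    return(tibble::tibble(start_epoch = integer(), length = integer()))
  }
  dplyr::bind_rows(bouts)
}

#' Apply a re-recording perturbation to an audio signal
#'
#' Emulates the degradations of re-recording the same audio under changed
#' conditions: gain attenuation (distance), low-pass filtering (physical
#' barrier), and additive background noise at a stated SNR (ambient TV or
#' room noise). Conditions compose in the order attenuate, low-pass,
#' background. Duration and sample rate are preserved.
#'
#' @param audio A [cry_audio()] object.
#' @param attenuate_db Gain reduction in dB (amplitude scaled by
#'   `10^(-dB/20)`); 0 is the identity.
#' @param lowpass_hz Zero-phase Butterworth low-pass cutoff in Hz.
#' @param background Non-cry kind mixed in at `snr_db`.
#' @param snr_db Signal-to-background SNR in dB (required with `background`).
#' @param seed Integer seed for the background generator.
#' @return A [cry_audio()] of identical length and rate.
#' @export
perturb <- function(audio, attenuate_db = NULL, lowpass_hz = NULL,
                    background = NULL, snr_db = NULL, seed = 1) {
  stopifnot(inherits(audio, "cry_audio"))
  x <- audio$samples
  sr <- audio$sample_rate
  if (!is.null(attenuate_db)) {
    x <- x * 10^(-attenuate_db / 20)
  }
  if (!is.null(lowpass_hz)) {
    if (lowpass_hz <= 0 || lowpass_hz >= sr / 2) {
      stop("`lowpass_hz` must lie in (0, sample_rate/2)", call. = FALSE)
    }
    b <- signal::butter(6, lowpass_hz / (sr / 2))
    x <- signal::filtfilt(b, x)
  }
  if (!is.null(background)) {
    if (is.null(snr_db)) stop("`snr_db` required with `background`", call. = FALSE)
    bg <- synth_noncry(background, length(x) / sr, seed = seed, sample_rate = sr)
    b <- bg$samples[seq_along(x)]
    g <- sqrt(mean(x^2) / (10^(snr_db / 10) * max(mean(b^2), 1e-12)))
    x <- x + g * b
  }
  out <- cry_audio(x, sr)
  out
}

#' Generate the labelled clip corpus used for training benchmarks
#'
#' Produces `n_cry` stylized cry clips (per-clip randomized F0 base and
#' phrase timing) and `n_noncry` non-cry clips cycling over the non-cry
#' kinds, each one epoch long, with binary labels.
#'
#' @param n_cry,n_noncry Clip counts per class.
#' @param epoch_seconds Clip length in seconds. Default 5.
#' @param sample_rate Sampling rate in Hz. Default 16000.
#' @param seed Integer seed.
#' @return A tibble: `epoch_index`, `start_time_s`, `samples` (list-column),
#'   `label` (1 = cry), `kind`.
#' @export
synth_corpus <- function(n_cry = 300, n_noncry = 400, epoch_seconds = 5,
                         sample_rate = 16000, seed = 1) {
  n <- n_cry + n_noncry
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n + n_cry * 2L))
  kinds <- rep(c("white_noise", "pink_noise", "tone", "babble", "knock"),
               length.out = n_noncry)
  cry_f0 <- withr::with_seed(seed + 1L, stats::runif(n_cry, 350, 550))
  cry_snr <- withr::with_seed(seed + 2L, stats::runif(n_cry, 10, 25))

  clips <- vector("list", n)
  for (i in seq_len(n_cry)) {
    cry <- synth_cry(epoch_seconds, f0_base = cry_f0[i], sample_rate = sample_rate,
                     seed = seeds[i])
    # light room-noise floor so cries are not recorded in digital silence
    clips[[i]] <- perturb(cry, background = "white_noise", snr_db = cry_snr[i],
                          seed = seeds[n + i])$samples
  }
  for (j in seq_len(n_noncry)) {
    clips[[n_cry + j]] <- synth_noncry(kinds[j], epoch_seconds,
                                       seed = seeds[n_cry + j],
                                       sample_rate = sample_rate)$samples
  }
  tibble::tibble(
    epoch_index = seq_len(n) - 1L,
    start_time_s = (seq_len(n) - 1L) * epoch_seconds,
    samples = clips,
    label = rep(c(1L, 0L), c(n_cry, n_noncry)),
    kind = c(rep("cry", n_cry), kinds)
  )
}
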