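test_that("the registry enumerates 42 LLDs x 13 functionals = 546 features", {
  reg <- feature_registry()
  expect_length(reg$llds, 42)
  expect_length(reg$functionals, 13)
  expect_length(reg$names, 546)
  expect_false(anyDuplicated(reg$names) > 0)
  expect_true(all(grepl("^[a-z0-9]+_[a-z0-9]+$", reg$names)))
})

test_that("digital silence yields zero energy, voicing and F0", {
  ll <- compute_llds(numeric(5 * 16000))
  expect_true(all(ll$rms == 0))
  expect_true(all(ll$voicing == 0))
  expect_true(all(ll$f0 == 0))
  # log mel energies are floored, not -Inf
  expect_true(all(is.finite(as.matrix(ll[, grep("^mel", names(ll))]))))
  fv <- apply_functionals(ll)
  expect_true(all(is.finite(fv)))
})

test_that("a pure sine is fully voiced with the right pitch and crossing rate", {
  s <- 0.5 * sin(2 * pi * 440 * (0:(5 * 16000 - 1)) / 16000)
  ll <- compute_llds(s)
  expect_true(all(ll$voicing > 0.9))
  # 440 Hz sine crosses zero 880 times per second
  expect_equal(mean(ll$zcr), 880, tolerance = 0.02)
  expect_equal(median(ll$f0), 440, tolerance = 0.02)
})

test_that("white noise is mostly unvoiced", {
  # Monte-Carlo over seeded noise epochs
  vp <- vapply(1:20, function(s) {
    mean(compute_llds(synth_noncry("white_noise", 5, seed = s)$samples)$voicing)
  }, 0)
  expect_true(all(vp < 0.5))
})

test_that("functionals match their definitions on closed-form cases", {
  reg <- feature_registry()
  # constant series: moments collapse, skew/kurt are defined as 0
  frames <- compute_llds(numeric(5 * 16000), registry = reg)
  frames[] <- lapply(frames, function(col) rep(4.2, length(col)))
  fv <- apply_functionals(frames, reg)
  expect_equal(unname(fv["rms_mean"]), 4.2)
  expect_equal(unname(fv["rms_sd"]), 0)
  expect_equal(unname(fv["rms_range"]), 0)
  expect_equal(unname(fv["rms_p99"]), 4.2)
  expect_equal(unname(fv["rms_skew"]), 0)
  expect_equal(unname(fv["rms_kurt"]), 0)

  # tiny series with known population statistics
  x <- c(1, 2, 3, 4, 5)
  nf <- naive_functionals(x)
  expect_equal(unname(nf["mean"]), 3)
  expect_equal(unname(nf["sd"]), sqrt(2))
  expect_equal(unname(nf["p50"]), 3)
})

test_that("functionals agree with a naive re-implementation on random series", {
  reg <- feature_registry()
  set.seed(42)
  base <- compute_llds(synth_cry(5, seed = 9)$samples, registry = reg)
  fv <- apply_functionals(base, reg)
  for (lld in c("mfcc1", "mel07", "rms", "zcr", "f0", "voicing")) {
    nf <- naive_functionals(base[[lld]])
    for (fun in names(nf)) {
      expect_equal(unname(fv[paste0(lld, "_", fun)]), unname(nf[fun]),
                   tolerance = 1e-9,
                   label = paste0(lld, "_", fun))
    }
  }
})

test_that("percentile functionals are monotone", {
  reg <- feature_registry()
  f <- extract_features(synth_corpus(3, 3, seed = 21), registry = reg)
  for (lld in reg$llds) {
    p <- as.matrix(f[, paste0(lld, "_", c("p1", "p25", "p50", "p75", "p99"))])
    expect_true(all(diff(t(p)) >= -1e-12), label = lld)
  }
})

test_that("gain-invariant LLD functionals ignore amplitude scaling", {
  reg <- feature_registry()
  s <- synth_cry(5, seed = 5)$samples
  f1 <- apply_functionals(compute_llds(s, registry = reg), reg)
  f2 <- apply_functionals(compute_llds(0.5 * s, registry = reg), reg)
  inv <- grep("^(zcr|voicing|f0)_", names(f1), value = TRUE)
  expect_equal(f1[inv], f2[inv], tolerance = 1e-6)

  # log mel means shift by the constant log(0.25) under halving; checked on a
  # noise epoch whose band energies sit everywhere above the silence floor
  n <- synth_noncry("white_noise", 5, seed = 5)$samples
  g1 <- apply_functionals(compute_llds(n, registry = reg), reg)
  g2 <- apply_functionals(compute_llds(0.5 * n, registry = reg), reg)
  mel_means <- grep("^mel\\d+_mean$", names(g1), value = TRUE)
  shifts <- g2[mel_means] - g1[mel_means]
  expect_equal(unname(shifts), rep(log(0.25), length(shifts)), tolerance = 1e-6)
})

test_that("feature extraction is deterministic and carries the epoch grid", {
  ep <- synth_corpus(2, 2, seed = 13)
  f1 <- extract_features(ep)
  f2 <- extract_features(ep)
  expect_identical(f1, f2)
  expect_equal(f1$epoch_index, 0:3)
  expect_equal(ncol(f1), 548) # grid columns + 546 features
})

test_that("the registry serializes to JSON and back", {
  reg <- feature_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, path)
  reg2 <- read_registry(path)
  expect_equal(reg2$names, reg$names)
  expect_equal(reg2$frame_ms, reg$frame_ms)
})
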