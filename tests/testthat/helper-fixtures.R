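# Expensive fixtures are built once per test run and cached here. Everything
# is generated in code from fixed seeds; nothing is read from disk.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Small end-to-end benchmark for module-level pipeline/robustness tests.
small_benchmark <- function() {
  memo("small_benchmark",
       run_benchmark(n_cry = 30, n_noncry = 40, seed = 11, n_screen_clips = 16))
}

# The full-scale seeded training benchmark: 300 cry / 400 non-cry clips.
full_benchmark <- function() {
  memo("full_benchmark", run_benchmark(n_cry = 300, n_noncry = 400, seed = 7))
}

# Benchmark session shaped like the 29-min robustness clip: 348 epochs of
# which 200 carry crying.
benchmark_session <- function() {
  memo("benchmark_session", {
    bouts <- tibble::tibble(
      start_epoch = c(10L, 70L, 140L, 200L, 270L),
      length = c(40L, 50L, 30L, 40L, 40L)
    )
    synth_session(348, bouts = bouts, snr_db = 10, seed = 7)
  })
}
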