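# Synthetic feature tibbles for screening tests: n epochs x p features.
fake_features <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- sprintf("f%03d_mean", seq_len(p))
    tibble::as_tibble(m) |>
      tibble::add_column(epoch_index = seq_len(n) - 1L, .before = 1L)
  })
}

test_that("conditions identical to the reference retain every feature", {
  ref <- fake_features(50, 30)
  rep <- screen_features(ref, list(same = ref, again = ref))
  expect_true(all(rep$retained))
  expect_true(all(rep$reason == ""))
})

test_that("a single shifted feature is the only exclusion", {
  ref <- fake_features(100, 30, seed = 2)
  cond <- ref
  cond$f010_mean <- cond$f010_mean + 3 * sd(cond$f010_mean)
  rep <- screen_features(ref, list(shifted = cond))
  expect_identical(rep$feature[!rep$retained], "f010_mean")
  expect_match(rep$reason[!rep$retained], "SMD")
})

test_that("SD inflation triggers the ratio rule", {
  ref <- fake_features(200, 10, seed = 3)
  cond <- ref
  cond$f003_mean <- cond$f003_mean * 3
  rep <- screen_features(ref, list(noisy = cond))
  expect_false(rep$retained[rep$feature == "f003_mean"])
  expect_match(rep$reason[!rep$retained], "SD ratio|SMD")
})

test_that("zero-variance features follow the equal-means convention", {
  ref <- fake_features(20, 3)
  ref$f001_mean <- 1 # constant
  same <- ref
  moved <- ref
  moved$f001_mean <- 2
  expect_true(screen_features(ref, list(c = same))$retained[1])
  expect_false(screen_features(ref, list(c = moved))$retained[1])
})

test_that("planted unstable features are excluded with few false exclusions", {
  # 100 features, 20 planted unstable (mean shift 1 SD or SD ratio 3)
  for (seed in 1:3) {
    ref <- fake_features(120, 100, seed = seed)
    cond <- fake_features(120, 100, seed = seed + 500)
    planted <- sprintf("f%03d_mean", 1:20)
    for (j in 1:10) cond[[planted[j]]] <- cond[[planted[j]]] + 1
    for (j in 11:20) cond[[planted[j]]] <- cond[[planted[j]]] * 3
    rep <- screen_features(ref, list(perturbed = cond))
    expect_true(all(!rep$retained[rep$feature %in% planted]))
    stable <- setdiff(rep$feature, planted)
    false_excl <- mean(!rep$retained[rep$feature %in% stable])
    expect_lte(false_excl, 0.10)
  }
})

test_that("screening rejects mismatched registries and epoch counts", {
  ref <- fake_features(30, 10)
  other <- fake_features(30, 11)
  expect_error(screen_features(ref, list(c = other)), "registry")
  fewer <- fake_features(20, 10)
  expect_error(screen_features(ref, list(c = fewer)), "epochs")
})

test_that("loosening the SMD threshold never excludes more features", {
  ref <- fake_features(60, 40, seed = 8)
  cond <- fake_features(60, 40, seed = 9)
  strict <- screen_features(ref, list(c = cond), smd_threshold = 0.3)
  loose <- screen_features(ref, list(c = cond), smd_threshold = 0.6)
  expect_true(all(loose$retained[strict$retained]))
})

test_that("apply_screen restricts columns and refuses an empty set", {
  ref <- fake_features(30, 10)
  rep_all <- screen_features(ref, list(c = ref))
  expect_identical(apply_screen(ref, rep_all), ref)

  rep_none <- rep_all
  rep_none$retained <- FALSE
  expect_error(apply_screen(ref, rep_none), "empty feature set")

  rep_some <- rep_all
  rep_some$retained[6:10] <- FALSE
  out <- apply_screen(ref, rep_some)
  expect_identical(setdiff(names(ref), names(out)), sprintf("f%03d_mean", 6:10))

  stranger <- fake_features(30, 12)
  expect_error(apply_screen(stranger, rep_all), "absent from the screen")
})

test_that("screen reports serialize to JSON and back", {
  ref <- fake_features(30, 10)
  cond <- fake_features(30, 10, seed = 99)
  rep <- screen_features(ref, list(c = cond))
  path <- withr::local_tempfile(fileext = ".json")
  write_screen(rep, path)
  rep2 <- read_screen(path)
  expect_equal(rep2$retained, rep$retained)
  expect_equal(attr(rep2, "smd_threshold"), attr(rep, "smd_threshold"))
})

test_that("attenuation-only re-recording keeps gain-invariant features", {
  clips <- synth_corpus(6, 6, seed = 31)
  rep <- screen_from_conditions(clips, conditions = list(att = list(attenuate_db = 6)))
  inv <- grepl("^(zcr|voicing)_", rep$feature)
  expect_true(all(rep$retained[inv]))
})
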