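test_that("start and stop criteria behave on constructed series", {
  # all-silence: no sequences
  expect_equal(nrow(detect_sequences(rep(0, 500))), 0)

  # exactly six consecutive cry epochs: one sequence of 0.5 min
  s <- c(rep(0, 20), rep(1, 6), rep(0, 100))
  seqs <- detect_sequences(s)
  expect_equal(nrow(seqs), 1)
  expect_equal(seqs$start_epoch, 20)
  expect_equal(seqs$end_epoch, 25)
  expect_equal(seqs$duration_min, 0.5)
  expect_equal(seqs$cry_epochs, 6)

  # 5 cries then 8 silences, repeated: never 6 cries in any 12-epoch window
  s2 <- rep(c(rep(1, 5), rep(0, 8)), 10)
  expect_equal(nrow(detect_sequences(s2)), 0)

  # a sub-5-min pause stays inside one sequence; a 5-min pause splits
  joined <- c(rep(1, 6), rep(0, 59), rep(1, 6), rep(0, 70))
  expect_equal(nrow(detect_sequences(joined)), 1)
  split <- c(rep(1, 6), rep(0, 60), rep(1, 6), rep(0, 70))
  expect_equal(nrow(detect_sequences(split)), 2)
})

test_that("sequences start and end on cry epochs and never overlap", {
  withr::with_seed(5, {
    for (i in 1:50) {
      l <- as.integer(runif(400) < 0.2)
      seqs <- detect_sequences(l)
      if (nrow(seqs) == 0) next
      expect_true(all(l[seqs$start_epoch + 1] == 1))
      expect_true(all(l[seqs$end_epoch + 1] == 1))
      expect_true(all(diff(seqs$start_epoch) > 0))
      expect_true(all(seqs$start_epoch[-1] > seqs$end_epoch[-nrow(seqs)]))
    }
  })
})

test_that("the scanner matches the naive R implementation on random series", {
  withr::with_seed(21, {
    for (i in 1:200) {
      l <- as.integer(runif(sample(10:120, 1)) < runif(1, 0.1, 0.6))
      got <- sequences_as_matrix(detect_sequences(l, 2, 4, 5))
      want <- brute_sequences_r(l, 2L, 4L, 5L)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  })
})

test_that("adding cry epochs never shrinks total sequence duration", {
  withr::with_seed(33, {
    for (i in 1:30) {
      l <- as.integer(runif(300) < 0.15)
      extra <- l
      extra[sample(which(extra == 0), 10)] <- 1L
      d0 <- sum(detect_sequences(l)$duration_min)
      d1 <- sum(detect_sequences(extra)$duration_min)
      expect_gte(d1, d0)
    }
  })
})

test_that("default parameters encode the 1-min window and 5-min gap", {
  # 12 epochs x 5 s = 1 min; 60 epochs x 5 s = 5 min
  expect_equal(formals(detect_sequences)$start_window * 5 / 60, 1)
  expect_equal(formals(detect_sequences)$stop_gap * 5 / 60, 5)
  expect_equal(formals(detect_sequences)$start_min_cry, 6)
})

test_that("invalid label series and parameters are contract errors", {
  expect_error(detect_sequences(c(0, 1, 2)), "binary")
  expect_error(detect_sequences(c(0, 1), start_min_cry = 0), "start_min_cry")
  expect_error(detect_sequences(c(0, 1), start_min_cry = 6, start_window = 3),
               "start_min_cry")
})

test_that("timeline comparison reports zero deltas for identical series", {
  withr::with_seed(9, l <- as.integer(runif(600) < 0.1))
  cmp <- compare_timelines(l, l, subject = "x")
  expect_equal(cmp$delta_count, 0)
  expect_equal(cmp$delta_duration_min, 0)
})

test_that("sparse label flips outside sequences leave the count unchanged", {
  l <- rep(0L, 720)
  l[100:140] <- 1L # one solid 41-epoch sequence
  base <- compare_timelines(l, l)
  flipped <- l
  # flip isolated epochs far from the sequence and from each other: too
  # sparse for any 12-epoch window to collect 6 cries
  flipped[c(300, 350, 400, 450, 500, 550, 600)] <- 1L
  cmp <- compare_timelines(l, flipped)
  expect_equal(cmp$predicted_count, base$annotated_count)
  expect_equal(cmp$delta_count, 0)
})

test_that("published per-subject summaries give the reported deltas", {
  vc <- validation_comparisons()
  s1 <- vc[vc$subject == "1", ]
  expect_equal(s1$annotated_count, 3)
  expect_equal(s1$predicted_count, 5)
  expect_equal(s1$delta_count, 2)
  expect_equal(s1$delta_duration_min, 22)
})

test_that("cohort statistics reproduce the published summaries", {
  cs <- summarize_cohort(validation_comparisons())
  expect_equal(cs$total_annotated_sequences, 39)
  expect_equal(cs$median_annotated_count, 3)
  expect_equal(cs$q25_annotated_count, 1)
  expect_equal(cs$q75_annotated_count, 3)
  by_group <- cs$cry_duration_by_group[[1]]
  expect_equal(by_group$median_cry_duration_min[by_group$group == "hospital"],
               5.8, tolerance = 0.01)
  expect_equal(by_group$median_cry_duration_min[by_group$group == "home"],
               1.4, tolerance = 0.02)
  # duration mismatch between annotation and detector: median ~6 min
  expect_equal(cs$median_abs_delta_duration_min, 6.25)

  single <- summarize_cohort(validation_comparisons()[3, ])
  expect_equal(single$median_annotated_count, 1)
  expect_equal(single$q75_annotated_count - single$q25_annotated_count, 0)
  expect_error(summarize_cohort(validation_comparisons()[0, ]), "empty")
})
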