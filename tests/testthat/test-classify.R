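# Quick synthetic tabular datasets (no audio) for classifier-level tests.
separable_data <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    # classes sit on opposite sides of a margin: linearly separable by design
    tibble::tibble(
      epoch_index = seq_len(n) - 1L,
      fa_mean = runif(n, 0, 1) + 2 * y,
      fb_mean = -(runif(n, 0, 1) + 2 * y) + 0.2 * runif(n),
      label = y
    )
  })
}

test_that("all families reach perfect sensitivity on separable data", {
  d <- separable_data(200, seed = 1)
  for (fam in c("random_forest", "logistic_regression", "naive_bayes")) {
    cv <- grid_search_cv(d, family = fam, k = 5, seed = 3)
    expect_equal(mean(cv$fold_metrics$sensitivity), 1.0, label = fam)
  }
})

test_that("shuffled labels give chance-level cross-validated MCC", {
  # permutation null: the mean MCC over shuffles must sit near 0
  d <- separable_data(400, seed = 2)
  mccs <- vapply(1:10, function(s) {
    d$label <- withr::with_seed(s, sample(d$label))
    cv <- grid_search_cv(d, family = "naive_bayes", k = 5, seed = 3)
    mean(cv$fold_metrics$mcc)
  }, 0)
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("hyperparameter choice maximises sensitivity with MCC tie-break", {
  d <- separable_data(200, seed = 4)
  cv <- grid_search_cv(d, family = "naive_bayes", k = 5, seed = 5)
  g <- cv$grid
  best_sens <- max(g$mean_sensitivity)
  tied <- g[g$mean_sensitivity == best_sens, ]
  expect_equal(cv$best_params$var_smoothing,
               tied$var_smoothing[which.max(tied$mean_mcc)])
})

test_that("grid search is deterministic given the seed", {
  d <- separable_data(120, seed = 6)
  cv1 <- grid_search_cv(d, family = "random_forest", k = 5, seed = 7,
                        grid = tibble::tibble(num_trees = 100, max_depth = 0, min_node = 1))
  cv2 <- grid_search_cv(d, family = "random_forest", k = 5, seed = 7,
                        grid = tibble::tibble(num_trees = 100, max_depth = 0, min_node = 1))
  expect_equal(cv1$fold_metrics, cv2$fold_metrics)
})

test_that("degenerate training inputs are contract errors", {
  d <- separable_data(40, seed = 8)
  d$label <- 1L
  expect_error(grid_search_cv(d, family = "naive_bayes"), "both classes")
  d2 <- separable_data(40, seed = 8)
  expect_error(grid_search_cv(d2[c(1:3, 21:38), ], family = "naive_bayes", k = 5),
               "at least k")
})

test_that("the final model is the family with the highest mean CV MCC", {
  d <- separable_data(200, seed = 9)
  cvs <- lapply(c("random_forest", "logistic_regression", "naive_bayes"),
                function(f) grid_search_cv(d, family = f, k = 5, seed = 10))
  model <- select_final_model(cvs, d, seed = 10)
  mccs <- vapply(cvs, function(cv) mean(cv$fold_metrics$mcc), 0)
  expect_equal(model$family, cvs[[order(-mccs)[1]]]$family)

  # refit sanity: training-set MCC at least near the CV ceiling on separable data
  pred <- predict_epochs(model, d)
  m <- compute_metrics(confusion_matrix(d$label, pred$label))
  expect_gte(m$mcc, max(mccs) - 0.05)
})

test_that("models serialize and reload to identical predictions", {
  d <- separable_data(200, seed = 11)
  cv <- grid_search_cv(d, family = "logistic_regression", k = 5, seed = 12)
  model <- select_final_model(list(cv), d, seed = 12)
  held <- separable_data(100, seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  model2 <- read_model(path)
  expect_identical(predict_epochs(model, held), predict_epochs(model2, held))
})

test_that("prediction enforces the registry and handles edge cases", {
  d <- separable_data(80, seed = 14)
  cv <- grid_search_cv(d, family = "naive_bayes", k = 5, seed = 15)
  model <- select_final_model(list(cv), d, seed = 15)

  renamed <- dplyr::rename(d, fc_mean = fb_mean)
  expect_error(predict_epochs(model, renamed), "registry mismatch")

  empty <- d[0, ]
  out <- predict_epochs(model, empty)
  expect_equal(nrow(out), 0)
  expect_named(out, c("epoch_index", "probability", "label"))

  # boundary convention: probability exactly at the threshold labels cry
  pred <- predict_epochs(model, d)
  model$threshold <- pred$probability[1]
  pred2 <- predict_epochs(model, d)
  expect_equal(pred2$label[1], 1L)
})

test_that("tidy and glance expose CV folds and model summaries", {
  d <- separable_data(100, seed = 16)
  cv <- grid_search_cv(d, family = "random_forest", k = 5, seed = 17,
                       grid = tibble::tibble(num_trees = 100, max_depth = 0, min_node = 1))
  expect_equal(nrow(tidy(cv)), 5)
  g <- glance(cv)
  expect_equal(g$mean_mcc, mean(tidy(cv)$mcc))

  model <- select_final_model(list(cv), d, seed = 17)
  imp <- tidy(model)
  expect_setequal(imp$feature, c("fa_mean", "fb_mean"))
  expect_equal(glance(model)$n_features, 2)
})
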