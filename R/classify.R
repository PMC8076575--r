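#' Default hyperparameter grids for the three classifier families
#'
#' Random forest: number of trees, maximum depth (0 = unlimited), minimum
#' node size. Ridge logistic regression: four log-spaced L2 penalties.
#' Gaussian naive Bayes: two variance-smoothing values. Small, documented
#' grids — override by passing your own tibble of the same columns.
#'
#' @return Named list of grids (tibbles), one per family.
#' @export
default_grids <- function() {
  list(
    random_forest = tidyr::expand_grid(
      num_trees = c(100, 300, 500),
      max_depth = c(0, 10, 20),
      min_node = c(1, 5)
    ),
    logistic_regression = tibble::tibble(lambda = 10^seq(1, -2, length.out = 4)),
    naive_bayes = tibble::tibble(var_smoothing = c(1e-9, 1e-6))
  )
}

model_families <- function() c("random_forest", "logistic_regression", "naive_bayes")

# Split a labelled feature tibble into the design matrix and label vector.
design_matrix <- function(features, labels = NULL) {
  if (is.null(labels) && "label" %in% names(features)) labels <- features$label
  x <- as.matrix(features[, feature_columns(features), drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = if (is.null(labels)) NULL else label_vector(labels))
}

# Fit one (family, hyperparameters) combination. Logistic regression and
# naive Bayes see z-scored features (training statistics); the forest sees
# raw features.
fit_model <- function(family, params, x, y, seed = 1) {
  scaler <- NULL
  if (family %in% c("logistic_regression", "naive_bayes")) {
    mu <- colMeans(x)
    sdv <- pmax(apply(x, 2L, stats::sd), 1e-12)
    scaler <- list(mu = mu, sd = sdv)
    x <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  }
  fit <- switch(family,
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      num.trees = params$num_trees,
      max.depth = params$max_depth,
      min.node.size = params$min_node,
      probability = TRUE, seed = seed, num.threads = 1,
      importance = "impurity"
    ),
    logistic_regression = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0,
      lambda = sort(unique(c(params$lambda, 10^seq(1, -2, length.out = 4))),
                    decreasing = TRUE)
    ),
    naive_bayes = fit_gaussian_nb(x, y, params$var_smoothing),
    stop("unknown model family: ", family, call. = FALSE)
  )
  structure(
    list(family = family, params = params, fit = fit, scaler = scaler,
         features = colnames(x)),
    class = "cry_fit"
  )
}

predict_prob <- function(object, x) {
  stopifnot(inherits(object, "cry_fit"))
  if (!is.null(object$scaler)) {
    x <- sweep(sweep(x, 2L, object$scaler$mu), 2L, object$scaler$sd, "/")
  }
  switch(object$family,
    random_forest = {
      p <- stats::predict(object$fit, data = x, num.threads = 1)$predictions
      unname(p[, "1"])
    },
    logistic_regression = as.numeric(
      stats::predict(object$fit, newx = x, s = object$params$lambda, type = "response")
    ),
    naive_bayes = predict_gaussian_nb(object$fit, x)
  )
}

# Gaussian naive Bayes with additive variance smoothing
# (eps = var_smoothing * max feature variance), on standardized features.
fit_gaussian_nb <- function(x, y, var_smoothing) {
  classes <- c(0L, 1L)
  stats_by_class <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    v <- colMeans(sweep(xc, 2L, mu)^2)
    list(mu = mu, var = v, prior = nrow(xc) / nrow(x))
  })
  all_var <- c(stats_by_class[[1]]$var, stats_by_class[[2]]$var)
  eps <- var_smoothing * max(all_var, 1e-12)
  for (i in 1:2) stats_by_class[[i]]$var <- stats_by_class[[i]]$var + eps
  structure(list(classes = classes, stats = stats_by_class), class = "gaussian_nb")
}

predict_gaussian_nb <- function(fit, x) {
  loglik <- vapply(fit$stats, function(s) {
    rowSums(sweep(sweep(x, 2L, s$mu)^2, 2L, -2 * s$var, "/")) -
      sum(0.5 * log(2 * pi * s$var)) + log(s$prior)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) loglik <- matrix(loglik, nrow = 1L)
  m <- pmax(loglik[, 1L], loglik[, 2L])
  e0 <- exp(loglik[, 1L] - m)
  e1 <- exp(loglik[, 2L] - m)
  e1 / (e0 + e1)
}

# Stratified k-fold assignment, deterministic per seed.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  fold
}

#' Cross-validated grid search for one classifier family
#'
#' Runs stratified k-fold cross-validation over the family's hyperparameter
#' grid. Because the detector's primary purpose is to find crying,
#' hyperparameters are chosen to maximise mean cross-validated sensitivity;
#' ties are broken by mean MCC, then by grid order (first row wins).
#'
#' @param features Feature tibble (screened), optionally carrying a `label`
#'   column.
#' @param labels Binary labels (1 = cry); omit if `features` has `label`.
#' @param family One of `"random_forest"`, `"logistic_regression"`,
#'   `"naive_bayes"`.
#' @param k Number of folds. Default 5.
#' @param seed Integer seed controlling fold assignment and forest
#'   randomness.
#' @param grid Hyperparameter tibble; default from [default_grids()].
#' @param threshold Decision threshold on the cry probability. Default 0.5.
#' @return A `cry_cv` object: chosen hyperparameters, per-fold metrics of the
#'   chosen setting, mean/SD summaries, and the full grid table.
#' @export
grid_search_cv <- function(features, labels = NULL, family = "random_forest",
                           k = 5, seed = 1, grid = NULL, threshold = 0.5) {
  family <- match.arg(family, model_families())
  d <- design_matrix(features, labels)
  if (is.null(d$y)) stop("no labels supplied", call. = FALSE)
  tab <- table(factor(d$y, levels = c(0, 1)))
  if (any(tab == 0)) stop("training data must contain both classes", call. = FALSE)
  if (any(tab < k)) {
    stop("need at least k = ", k, " examples of each class for stratified ",
         k, "-fold CV", call. = FALSE)
  }
  if (is.null(grid)) grid <- default_grids()[[family]]
  fold <- stratified_folds(d$y, k, seed)

  metric_names <- c("accuracy", "mcc", "sensitivity", "specificity", "ppv", "npv")
  grid_rows <- vector("list", nrow(grid))
  fold_metrics <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    per_fold <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- fit_model(family, params, d$x[tr, , drop = FALSE], d$y[tr],
                       seed = seed + f)
      prob <- predict_prob(fit, d$x[!tr, , drop = FALSE])
      pred <- as.integer(prob >= threshold)
      compute_metrics(confusion_matrix(d$y[!tr], pred)) |>
        tibble::add_column(fold = f, .before = 1L)
    }))
    fold_metrics[[g]] <- per_fold
    summ <- as.list(colMeans(per_fold[metric_names]))
    names(summ) <- paste0("mean_", metric_names)
    sds <- as.list(vapply(per_fold[metric_names], stats::sd, 0))
    names(sds) <- paste0("sd_", metric_names)
    grid_rows[[g]] <- dplyr::bind_cols(grid[g, , drop = FALSE],
                                       tibble::as_tibble(summ),
                                       tibble::as_tibble(sds))
  }
  grid_tbl <- dplyr::bind_rows(grid_rows)
  best <- order(-grid_tbl$mean_sensitivity, -grid_tbl$mean_mcc,
                seq_len(nrow(grid_tbl)))[1L]

  structure(
    list(
      family = family,
      best_params = as.list(grid[best, , drop = FALSE]),
      fold_metrics = fold_metrics[[best]],
      grid = grid_tbl,
      k = k, seed = seed, threshold = threshold,
      feature_names = colnames(d$x)
    ),
    class = "cry_cv"
  )
}

#' @export
print.cry_cv <- function(x, ...) {
  cat(sprintf("<cry_cv> %s, %d-fold CV over %d settings\n",
              x$family, x$k, nrow(x$grid)))
  cat("  chosen:", paste(names(x$best_params),
                         unlist(x$best_params), sep = "=", collapse = ", "), "\n")
  s <- colMeans(x$fold_metrics[c("sensitivity", "mcc", "accuracy")])
  cat(sprintf("  mean CV sensitivity %.3f, MCC %.3f, accuracy %.3f\n",
              s[1], s[2], s[3]))
  invisible(x)
}

#' Select the final model across families and refit on all data
#'
#' The family with the highest mean cross-validated MCC (at its chosen
#' hyperparameters) wins; ties fall back to the fixed family order random
#' forest, logistic regression, naive Bayes. The winner is refit on every
#' training row.
#'
#' @param results List of `cry_cv` objects (one or more families).
#' @param features,labels The training data the results were computed on.
#' @param seed Integer seed for the refit.
#' @return A `cry_model`: family, hyperparameters, fitted state, training
#'   feature registry, decision threshold, and the winning `cry_cv`.
#' @export
select_final_model <- function(results, features, labels = NULL, seed = 1) {
  if (inherits(results, "cry_cv")) results <- list(results)
  stopifnot(length(results) >= 1, all(vapply(results, inherits, TRUE, "cry_cv")))
  fam_order <- match(vapply(results, `[[`, "", "family"), model_families())
  mcc <- vapply(results, function(r) mean(r$fold_metrics$mcc), 0)
  win <- order(-mcc, fam_order)[1L]
  cv <- results[[win]]

  d <- design_matrix(features, labels)
  if (!identical(colnames(d$x), cv$feature_names)) {
    stop("features do not match the registry the CV was run on", call. = FALSE)
  }
  fit <- fit_model(cv$family, cv$best_params, d$x, d$y, seed = seed)
  structure(
    list(
      family = cv$family,
      params = cv$best_params,
      fit = fit,
      feature_names = cv$feature_names,
      threshold = cv$threshold,
      cv = cv,
      seed = seed
    ),
    class = "cry_model"
  )
}

#' @export
print.cry_model <- function(x, ...) {
  cat(sprintf("<cry_model> %s (%d features, threshold %.2f)\n",
              x$family, length(x$feature_names), x$threshold))
  invisible(x)
}

#' Predict per-epoch cry labels with a trained model
#'
#' @param model A `cry_model` from [select_final_model()].
#' @param features Feature tibble whose feature columns exactly match the
#'   model's training registry.
#' @return A tibble: `epoch_index`, `probability` (cry probability in
#'   `[0, 1]`), `label` (1 when `probability >= threshold`).
#' @export
predict_epochs <- function(model, features) {
  stopifnot(inherits(model, "cry_model"))
  feats <- feature_columns(features)
  missing <- setdiff(model$feature_names, feats)
  extra <- setdiff(feats, model$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature registry mismatch; missing: [",
         paste(utils::head(missing, 5), collapse = ", "), "], unexpected: [",
         paste(utils::head(extra, 5), collapse = ", "), "]", call. = FALSE)
  }
  idx <- if ("epoch_index" %in% names(features)) {
    features$epoch_index
  } else {
    seq_len(nrow(features)) - 1L
  }
  if (nrow(features) == 0L) {
    return(tibble::tibble(epoch_index = integer(), probability = numeric(),
                          label = integer()))
  }
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  prob <- predict_prob(model$fit, x)
  tibble::tibble(
    epoch_index = idx,
    probability = prob,
    label = as.integer(prob >= model$threshold)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cross-validation results
#'
#' @param x A `cry_cv` object.
#' @param ... Unused.
#' @return Per-fold metrics of the chosen hyperparameters, one row per fold.
#' @export
tidy.cry_cv <- function(x, ...) x$fold_metrics

#' @rdname tidy.cry_cv
#' @export
glance.cry_cv <- function(x, ...) {
  m <- x$fold_metrics
  tibble::tibble(
    family = x$family,
    k = x$k,
    mean_accuracy = mean(m$accuracy), sd_accuracy = stats::sd(m$accuracy),
    mean_mcc = mean(m$mcc), sd_mcc = stats::sd(m$mcc),
    mean_sensitivity = mean(m$sensitivity), sd_sensitivity = stats::sd(m$sensitivity),
    mean_specificity = mean(m$specificity), sd_specificity = stats::sd(m$specificity)
  )
}

#' Tidy a trained model: feature importance / coefficients
#'
#' For a random forest, impurity importance; for logistic regression, the
#' standardized coefficients at the chosen penalty; for naive Bayes, the
#' between-class mean gap per feature.
#'
#' @param x A `cry_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`, sorted decreasing.
#' @export
tidy.cry_model <- function(x, ...) {
  imp <- switch(x$family,
    random_forest = ranger::importance(x$fit$fit),
    logistic_regression = {
      co <- as.numeric(stats::coef(x$fit$fit, s = x$params$lambda))[-1]
      stats::setNames(abs(co), x$feature_names)
    },
    naive_bayes = {
      s <- x$fit$fit$stats
      stats::setNames(abs(s[[2]]$mu - s[[1]]$mu), x$feature_names)
    }
  )
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.cry_model
#' @export
glance.cry_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_features = length(x$feature_names), threshold = x$threshold),
    glance(x$cv)
  )
}

#' Save / load a trained model
#'
#' @param model A `cry_model`.
#' @param path File path (RDS).
#' @return `path` invisibly for write; the model for read.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cry_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cry_model"))
  m
}
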