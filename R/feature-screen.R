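#' Screen features for robustness across re-recording conditions
#'
#' Quantitative replacement for judging feature-distribution plots by eye:
#' for re-recordings of the same audio under changed conditions, every
#' feature's distribution should match the reference. A feature is excluded
#' when, for any condition, the standardized mean difference
#' `|mean_c - mean_ref| / pooled_SD` (pooled SD = `sqrt((SD_ref^2 + SD_c^2)/2)`)
#' exceeds `smd_threshold`, or the SD ratio `SD_c / SD_ref` leaves
#' `sd_ratio_bounds`. Exclusion is worst-case over conditions. Features with
#' zero pooled SD are excluded when their means differ and retained when
#' equal.
#'
#' @param reference Feature tibble (from [extract_features()]) of the
#'   reference recording.
#' @param conditions Named list of feature tibbles, one per re-recording
#'   condition, with the same registry columns and epoch count as
#'   `reference`.
#' @param smd_threshold Standardized-mean-difference cutoff. Default 0.5.
#' @param sd_ratio_bounds Allowed `SD_c / SD_ref` interval.
#'   Default `c(0.5, 2)`.
#' @return A `cry_screen` tibble with one row per feature: `feature`,
#'   `retained`, `worst_smd`, `worst_sd_ratio`, `reason` (empty when
#'   retained). Thresholds are carried as attributes.
#' @export
screen_features <- function(reference, conditions, smd_threshold = 0.5,
                            sd_ratio_bounds = c(0.5, 2)) {
  stopifnot(is.data.frame(reference), is.list(conditions), length(conditions) >= 1)
  feats <- feature_columns(reference)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    names(conditions) <- paste0("condition_", seq_along(conditions))
  }
  ref <- as.matrix(reference[, feats, drop = FALSE])
  if (nrow(ref) < 10L) {
    warning("fewer than 10 epochs per condition set; screening will be noisy")
  }
  mu_ref <- colMeans(ref)
  sd_ref <- pop_sd(ref)

  worst_smd <- rep(0, length(feats))
  worst_ratio <- rep(1, length(feats))
  reason <- rep("", length(feats))
  excluded <- rep(FALSE, length(feats))

  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    if (!identical(feature_columns(cond), feats)) {
      stop("condition '", cn, "' does not share the reference feature registry",
           call. = FALSE)
    }
    cm <- as.matrix(cond[, feats, drop = FALSE])
    if (nrow(cm) != nrow(ref)) {
      stop("condition '", cn, "' has ", nrow(cm), " epochs; reference has ",
           nrow(ref), call. = FALSE)
    }
    mu_c <- colMeans(cm)
    sd_c <- pop_sd(cm)
    pooled <- sqrt((sd_ref^2 + sd_c^2) / 2)

    zero_pool <- pooled == 0
    smd <- ifelse(zero_pool,
                  ifelse(mu_c == mu_ref, 0, Inf),
                  abs(mu_c - mu_ref) / pooled)
    ratio <- ifelse(sd_ref > 0, sd_c / sd_ref, ifelse(sd_c == 0, 1, Inf))

    hit_smd <- smd > smd_threshold
    hit_ratio <- ratio < sd_ratio_bounds[1] | ratio > sd_ratio_bounds[2]
    newly <- (hit_smd | hit_ratio) & reason == ""
    reason[newly] <- paste0(
      cn, ": ",
      ifelse(hit_smd[newly], sprintf("SMD %.2f", smd[newly]),
             sprintf("SD ratio %.2f", ratio[newly]))
    )
    excluded <- excluded | hit_smd | hit_ratio
    worst_smd <- pmax(worst_smd, smd)
    worst_ratio <- ifelse(abs(log(pmax(ratio, 1e-300))) > abs(log(pmax(worst_ratio, 1e-300))),
                          ratio, worst_ratio)
  }

  out <- tibble::tibble(
    feature = feats,
    retained = unname(!excluded),
    worst_smd = unname(worst_smd),
    worst_sd_ratio = unname(worst_ratio),
    reason = unname(reason)
  )
  attr(out, "smd_threshold") <- smd_threshold
  attr(out, "sd_ratio_bounds") <- sd_ratio_bounds
  attr(out, "conditions") <- names(conditions)
  class(out) <- c("cry_screen", class(out))
  out
}

pop_sd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2L, mu)^2))
}

#' Restrict a feature matrix to the screened (retained) features
#'
#' @param features Feature tibble using the report's registry.
#' @param report A `cry_screen` report from [screen_features()].
#' @return The feature tibble with excluded feature columns dropped; column
#'   order and non-feature columns (`epoch_index`, `start_time_s`, `label`)
#'   are preserved.
#' @export
apply_screen <- function(features, report) {
  stopifnot(is.data.frame(features), inherits(report, "cry_screen"))
  feats <- feature_columns(features)
  unknown <- setdiff(feats, report$feature)
  if (length(unknown) > 0) {
    stop("features absent from the screen report: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keep <- report$feature[report$retained]
  if (length(keep) == 0L) {
    stop("screen report retains no features; refusing an empty feature set",
         call. = FALSE)
  }
  drop <- setdiff(feats, keep)
  features[, setdiff(names(features), drop), drop = FALSE]
}

#' Write / read a screening report as JSON
#'
#' @param report A `cry_screen` report.
#' @param path JSON file path.
#' @return `path` invisibly for write; a `cry_screen` tibble for read.
#' @export
write_screen <- function(report, path) {
  stopifnot(inherits(report, "cry_screen"))
  payload <- list(
    smd_threshold = attr(report, "smd_threshold"),
    sd_ratio_bounds = attr(report, "sd_ratio_bounds"),
    conditions = attr(report, "conditions"),
    features = as.data.frame(report)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screen
#' @export
read_screen <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(payload$features)
  attr(out, "smd_threshold") <- payload$smd_threshold
  attr(out, "sd_ratio_bounds") <- unlist(payload$sd_ratio_bounds)
  attr(out, "conditions") <- payload$conditions
  class(out) <- c("cry_screen", class(out))
  out
}
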