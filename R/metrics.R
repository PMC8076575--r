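#' Confusion matrix between annotated and predicted epoch labels
#'
#' @param truth,predicted Binary label vectors (or tibbles with a `label`
#'   column) on the same epoch grid; 1 = cry.
#' @return A `cry_confusion` object with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- label_vector(truth)
  predicted <- label_vector(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted label series differ in length (",
         length(truth), " vs ", length(predicted), ")", call. = FALSE)
  }
  new_confusion(
    tp = sum(truth == 1L & predicted == 1L),
    fp = sum(truth == 0L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fn = sum(truth == 1L & predicted == 0L)
  )
}

#' Construct a confusion matrix from counts
#'
#' Counts may be non-integer: rate-based reconstruction
#' ([metrics_from_rates()]) produces real-valued cells.
#'
#' @param tp,fp,tn,fn Non-negative cell counts.
#' @return A `cry_confusion` object.
#' @export
new_confusion <- function(tp, fp, tn, fn) {
  cells <- c(tp = as.numeric(tp), fp = as.numeric(fp),
             tn = as.numeric(tn), fn = as.numeric(fn))
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("confusion cells must be finite and non-negative", call. = FALSE)
  }
  structure(as.list(cells), class = "cry_confusion")
}

#' @export
print.cry_confusion <- function(x, ...) {
  cat(sprintf("<cry_confusion> tp=%g fp=%g tn=%g fn=%g\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

label_vector <- function(x) {
  if (is.data.frame(x)) x <- x$label
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("labels must be binary (0 = non-cry, 1 = cry)", call. = FALSE)
  }
  x
}

#' Classification metric suite from a confusion matrix
#'
#' Computes accuracy, Matthews correlation coefficient (MCC), sensitivity,
#' specificity, positive predictive value (PPV) and negative predictive value
#' (NPV). Any metric whose denominator is zero is defined as 0 and listed in
#' the `degenerate` attribute rather than returned as NaN, so that
#' single-class stretches of a recording do not crash a pipeline.
#'
#' @param cm A `cry_confusion` object.
#' @return A one-row tibble with columns `accuracy`, `mcc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`; attribute `degenerate` names zero-denominator
#'   metrics.
#' @examples
#' compute_metrics(new_confusion(tp = 10, fp = 2, tn = 85, fn = 3))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "cry_confusion"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)

  degenerate <- character()
  safe_div <- function(num, den, name) {
    if (den > 0) return(num / den)
    degenerate <<- c(degenerate, name)
    0
  }
  # multiply the marginals in sorted order: the set of factors is invariant
  # under class swap, so MCC symmetry holds exactly in floating point
  marg <- sort(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc_den <- sqrt(marg[1]) * sqrt(marg[2]) * sqrt(marg[3]) * sqrt(marg[4])
  out <- tibble::tibble(
    accuracy = (tp + tn) / total,
    mcc = safe_div(tp * tn - fp * fn, mcc_den, "mcc"),
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    ppv = safe_div(tp, tp + fp, "ppv"),
    npv = safe_div(tn, tn + fn, "npv")
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Reconstruct the metric suite from printed rates and class totals
#'
#' Published reports often print only sensitivity, specificity and the class
#' sizes. This rebuilds the implied (real-valued) confusion matrix —
#' `tp = sensitivity * n_pos`, `tn = specificity * n_neg`, complements in
#' `fn`/`fp` — and delegates to [compute_metrics()], recovering pooled
#' accuracy, MCC, PPV and NPV.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_pos,n_neg Positive / negative class totals (> 0).
#' @return A one-row tibble as from [compute_metrics()].
#' @examples
#' # pooled accuracy implied by sens 83.2%, spec 99.2% over 1805/52464 epochs
#' metrics_from_rates(0.832, 0.992, 1805, 52464)$accuracy
#' @export
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_pos <= 0 || n_neg <= 0) stop("class totals must be positive", call. = FALSE)
  cm <- new_confusion(
    tp = sensitivity * n_pos,
    fn = (1 - sensitivity) * n_pos,
    tn = specificity * n_neg,
    fp = (1 - specificity) * n_neg
  )
  compute_metrics(cm)
}

#' Evaluate predictions against annotations, optionally per group
#'
#' @param truth,predicted Tibbles with `label` columns (and optionally a
#'   grouping column such as `subject`), or bare binary vectors.
#' @param group Optional name of a grouping column present in both tibbles;
#'   metrics are then computed overall and per group.
#' @return A tibble of metric rows; column `scope` is `"overall"` or the
#'   group value.
#' @export
evaluate_predictions <- function(truth, predicted, group = NULL) {
  overall <- compute_metrics(confusion_matrix(truth, predicted)) |>
    tibble::add_column(scope = "overall", .before = 1L)
  if (is.null(group)) {
    return(overall)
  }
  stopifnot(is.data.frame(truth), is.data.frame(predicted),
            group %in% names(truth), group %in% names(predicted))
  per <- dplyr::bind_rows(lapply(split(seq_len(nrow(truth)), truth[[group]]), function(i) {
    compute_metrics(confusion_matrix(truth$label[i], predicted$label[i]))
  }), .id = "scope")
  dplyr::bind_rows(overall, per)
}

#' Format a proportion as the percent string used in reports
#'
#' Rounds half away from zero to one decimal, e.g. `0.98665 -> "98.7"`.
#'
#' @param x Proportion in `[0, 1]` (or `[-1, 1]` for MCC).
#' @param digits Decimal places. Default 1.
#' @return Character vector of percentages without the `%` sign.
#' @export
percent_format <- function(x, digits = 1) {
  p <- x * 100
  scale <- 10^digits
  rounded <- sign(p) * floor(abs(p) * scale + 0.5) / scale
  formatC(rounded, format = "f", digits = digits)
}
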