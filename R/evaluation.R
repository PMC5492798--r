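#' Prediction accuracy and training size
#'
#' `Acc` is the percentage of correctly predicted labels; `TS` is the
#' selected training set's size as a percentage of the session's rows.
#'
#' @param predictions Integer predicted labels.
#' @param truth Integer true labels, same length.
#' @param voc_size Number of selected training rows (`>= 1`).
#' @param dataset_size Total session rows (`>= voc_size`).
#' @return List with `acc` and `ts` (both percent).
#' @export
accuracy_and_ts <- function(predictions, truth, voc_size, dataset_size) {
  if (length(predictions) != length(truth))
    stop("value error: predictions and truth differ in length")
  if (voc_size < 1 || dataset_size < voc_size)
    stop("value error: need dataset_size >= voc_size >= 1")
  list(acc = 100 * mean(predictions == truth),
       ts = 100 * voc_size / dataset_size)
}

confusion_counts <- function(predictions, truth, classes) {
  vapply(classes, function(cls) {
    c(tp = sum(predictions == cls & truth == cls),
      fp = sum(predictions == cls & truth != cls),
      fn = sum(predictions != cls & truth == cls))
  }, numeric(3))
}

#' Class-weighted F-measure
#'
#' Per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)` are combined
#' into the F-beta score and averaged with weights `w_i = n_i / N` taken
#' from the truth labels. Classes absent from the truth are excluded;
#' any zero denominator yields a per-class score of 0.
#'
#' @param predictions Integer predicted labels.
#' @param truth Integer true labels in `{1..4}`, same length.
#' @param beta Precision/recall trade-off (default 1: equal importance).
#' @return The weighted F score in `[0, 1]`.
#' @export
weighted_f1 <- function(predictions, truth, beta = 1) {
  if (length(truth) == 0) stop("value error: empty input")
  if (length(predictions) != length(truth))
    stop("value error: predictions and truth differ in length")
  classes <- sort(unique(truth))
  cm <- confusion_counts(predictions, truth, classes)
  f_cls <- vapply(seq_along(classes), function(i) {
    tp <- cm["tp", i]; fp <- cm["fp", i]; fn <- cm["fn", i]
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    den <- beta^2 * prec + rec
    if (den > 0) (1 + beta^2) * prec * rec / den else 0
  }, numeric(1))
  w <- vapply(classes, function(cls) mean(truth == cls), numeric(1))
  sum(w * f_cls)
}

#' Per-class accuracy (recall)
#'
#' @param predictions Integer predicted labels.
#' @param truth Integer true labels, same length.
#' @return Named numeric vector: for each class present in the truth,
#'   the percentage of its rows predicted correctly.
#' @export
per_class_accuracy <- function(predictions, truth) {
  if (length(truth) == 0) stop("value error: empty input")
  if (length(predictions) != length(truth))
    stop("value error: predictions and truth differ in length")
  classes <- sort(unique(truth))
  out <- vapply(classes, function(cls) {
    100 * mean(predictions[truth == cls] == cls)
  }, numeric(1))
  nm <- names(activity_codes)[classes]
  nm[is.na(nm)] <- as.character(classes[is.na(nm)])
  names(out) <- nm
  out
}

fit_metrics <- function(fit) {
  list(accuracy = fit$accuracy,
       training_size = fit$training_size,
       weighted_f1 = weighted_f1(fit$predictions, fit$labels),
       per_class_accuracy =
         as.list(per_class_accuracy(fit$predictions, fit$labels)),
       pair = as.integer(fit$pair), C = fit$C, gamma = fit$gamma)
}

#' Compare the iterative fit against the supervised baseline
#'
#' Builds a structured report with both runs' accuracy, training size,
#' weighted F1 and per-class accuracy, plus the deltas the two learning
#' schemes are judged by: the accuracy gap (baseline minus iterative)
#' and the training-size ratio (baseline over iterative).
#'
#' @param iterative A `"har_fit"` with `method = "iterative"`.
#' @param baseline A `"har_fit"` with `method = "baseline"` on the same
#'   session.
#' @param seeds Optional named list of seeds to embed for provenance.
#' @return An object of class `"har_report"` (a nested list).
#' @export
comparison_report <- function(iterative, baseline, seeds = list()) {
  if (!identical(iterative$fingerprint, baseline$fingerprint))
    stop("provenance error: fits come from different sessions")
  rep_ <- list(
    iterative = fit_metrics(iterative),
    baseline = fit_metrics(baseline),
    comparison = list(
      accuracy_gap = baseline$accuracy - iterative$accuracy,
      f1_gap = weighted_f1(baseline$predictions, baseline$labels) -
        weighted_f1(iterative$predictions, iterative$labels),
      ts_ratio = baseline$training_size / iterative$training_size),
    provenance = list(n = iterative$n, seeds = seeds,
                      fingerprint = iterative$fingerprint))
  class(rep_) <- c("har_report", "list")
  rep_
}

#' @export
print.har_report <- function(x, ...) {
  cat("<har_report>\n")
  cat(sprintf("  iterative: Acc %.2f%%  TS %.2f%%  F1 %.4f\n",
              x$iterative$accuracy, x$iterative$training_size,
              x$iterative$weighted_f1))
  cat(sprintf("  baseline : Acc %.2f%%  TS %.2f%%  F1 %.4f\n",
              x$baseline$accuracy, x$baseline$training_size,
              x$baseline$weighted_f1))
  cat(sprintf("  gap (baseline - iterative): %.2f points; TS ratio %.1fx\n",
              x$comparison$accuracy_gap, x$comparison$ts_ratio))
  invisible(x)
}

#' Serialize / restore a comparison report
#'
#' Reports round-trip losslessly through their JSON form.
#'
#' @param report A `"har_report"`.
#' @param path File path.
#' @return `write_report` invisibly returns `path`; `read_report`
#'   returns the `"har_report"`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep_ <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  class(rep_) <- c("har_report", "list")
  rep_
}
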