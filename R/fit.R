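session_fingerprint <- function(features) {
  fm <- feature_matrix(features)
  sprintf("n%d-s%.6g", nrow(fm), sum(fm) + sum(features$label))
}

#' Fit the iterative activity classification model
#'
#' The package's central estimator. For `method = "iterative"`, every
#' unordered pair of the 12 target-function features is tried in turn:
#' the candidate training rows (VoC) are selected by centroid-distance
#' tail selection ([build_voc()]), min-max normalized, a `(C, gamma)`
#' grid search with stratified cross-validation picks the RBF kernel
#' parameters, a one-vs-all SVM is trained on the candidates, and the
#' whole session is classified. The pair with the highest session
#' accuracy wins; the full per-pair table is retained. Pairs that fail
#' (e.g. a class with too few candidates for folding) are recorded and
#' skipped. For `method = "baseline"`, a stratified random
#' `fraction`/`1 - fraction` split replaces the candidate selection on a
#' single feature pair (the conventional supervised reference).
#'
#' @param features A [build_target_function()] result with labels in
#'   `{1,2,3,4}`.
#' @param method `"iterative"` (default) or `"baseline"`.
#' @param config An [svm_config()].
#' @param pair For `"baseline"`: the feature pair to use (default the
#'   first pair; typically the iterative winner's pair).
#' @param fraction For `"baseline"`: training fraction in (0, 1),
#'   default 0.8.
#' @param sd_type Passed to [build_voc()].
#' @param seed Seed controlling fold assignment and the baseline split;
#'   defaults to `config$seed`.
#' @return An object of class `"har_fit"` with elements `method`, `pair`,
#'   `C`, `gamma`, `cv_accuracy`, `accuracy` (session accuracy, percent),
#'   `holdout_accuracy` (accuracy on rows not used for training),
#'   `training_size` (percent of session rows used for training),
#'   `train_indices`, `table` (per-pair results, iterative only),
#'   `model`, `bounds`, `n`, `labels`, `predictions`.
#' @export
har_fit <- function(features, method = c("iterative", "baseline"),
                    config = svm_config(), pair = NULL, fraction = 0.8,
                    sd_type = "population", seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  labels <- features$label
  if (any(!(labels %in% 1:4)))
    stop("features contain null-class rows; drop them before fitting")
  if (method == "iterative") {
    fit_iterative(features, config, sd_type)
  } else {
    fit_baseline(features, config, pair, fraction)
  }
}

fit_one_pair <- function(xy, labels, train_idx, config) {
  test_idx <- setdiff(seq_along(labels), train_idx)
  nm <- minmax_normalize(xy[train_idx, , drop = FALSE])
  gs <- grid_search_svm(nm$train, labels[train_idx], config)
  model <- train_ova_rbf(nm$train, labels[train_idx],
                         C = gs$C, gamma = gs$gamma,
                         tolerance = config$tolerance)
  pred <- integer(length(labels))
  pred[train_idx] <- predict(model, nm$train)
  if (length(test_idx))
    pred[test_idx] <- predict(model, apply_bounds(xy[test_idx, , drop = FALSE],
                                                  nm$bounds))
  list(model = model, bounds = nm$bounds, C = gs$C, gamma = gs$gamma,
       cv_accuracy = gs$cv_accuracy, predictions = pred,
       accuracy = 100 * mean(pred == labels),
       holdout_accuracy = if (length(test_idx))
         100 * mean(pred[test_idx] == labels[test_idx]) else NA_real_)
}

fit_iterative <- function(features, config, sd_type) {
  labels <- features$label
  n <- length(labels)
  pairs <- feature_pairs()
  rows <- vector("list", nrow(pairs))
  best <- NULL
  failures <- character(0)
  for (p in seq_len(nrow(pairs))) {
    j <- unname(pairs[p, "j"]); k <- unname(pairs[p, "k"])
    res <- tryCatch({
      voc <- build_voc(features, c(j, k), sd_type = sd_type)
      xy <- cbind(features[[paste0("f", j)]], features[[paste0("f", k)]])
      fit <- fit_one_pair(xy, labels, voc$indices, config)
      fit$voc <- voc
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("pair (f%d,f%d): %s", j, k,
                            conditionMessage(res)))
      next
    }
    rows[[p]] <- data.frame(
      j = j, k = k, C = res$C, gamma = res$gamma,
      cv_accuracy = res$cv_accuracy, accuracy = res$accuracy,
      holdout_accuracy = res$holdout_accuracy,
      voc_size = length(res$voc$indices),
      training_size = 100 * length(res$voc$indices) / n)
    if (is.null(best) || res$accuracy > best$accuracy) {
      best <- res
      best$pair <- c(j = j, k = k)
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(best))
    stop("all feature pairs failed:\n  ",
         paste(failures, collapse = "\n  "))
  structure(
    list(method = "iterative", pair = best$pair, C = best$C,
         gamma = best$gamma, cv_accuracy = best$cv_accuracy,
         accuracy = best$accuracy,
         holdout_accuracy = best$holdout_accuracy,
         training_size = 100 * length(best$voc$indices) / n,
         train_indices = best$voc$indices, table = tab,
         failures = failures, model = best$model, bounds = best$bounds,
         n = n, labels = labels, predictions = best$predictions,
         fingerprint = session_fingerprint(features)),
    class = "har_fit")
}

fit_baseline <- function(features, config, pair, fraction) {
  if (fraction <= 0 || fraction >= 1)
    stop("split error: fraction must be in (0, 1) so the test set is non-empty")
  if (is.null(pair)) pair <- c(1L, 2L)
  pair <- unname(pair)
  labels <- features$label
  n <- length(labels)
  train_idx <- with_seed(config$seed, {
    unlist(lapply(unique(labels), function(cls) {
      rows <- which(labels == cls)
      sample(rows, max(1L, round(fraction * length(rows))))
    }))
  })
  train_idx <- sort(train_idx)
  if (length(train_idx) >= n)
    stop("split error: empty test set")
  xy <- cbind(features[[paste0("f", pair[1])]],
              features[[paste0("f", pair[2])]])
  res <- fit_one_pair(xy, labels, train_idx, config)
  structure(
    list(method = "baseline", pair = c(j = pair[1], k = pair[2]),
         C = res$C, gamma = res$gamma, cv_accuracy = res$cv_accuracy,
         accuracy = res$holdout_accuracy,
         holdout_accuracy = res$holdout_accuracy,
         session_accuracy = res$accuracy,
         training_size = 100 * length(train_idx) / n,
         train_indices = train_idx, table = NULL, failures = character(0),
         model = res$model, bounds = res$bounds, n = n, labels = labels,
         predictions = res$predictions,
         fingerprint = session_fingerprint(features)),
    class = "har_fit")
}

#' Supervised 80/20 baseline
#'
#' Convenience wrapper around `har_fit(method = "baseline")`: stratified
#' random split, grid search and one-vs-all training on the training
#' fraction, accuracy reported on the held-out rows.
#'
#' @inheritParams har_fit
#' @return A `"har_fit"` object.
#' @export
supervised_baseline <- function(features, pair = NULL, fraction = 0.8,
                                config = svm_config(), seed = NULL) {
  har_fit(features, method = "baseline", config = config, pair = pair,
          fraction = fraction, seed = seed)
}

#' @export
print.har_fit <- function(x, ...) {
  cat(sprintf("<har_fit> %s model on pair (f%d, f%d)\n",
              x$method, x$pair["j"], x$pair["k"]))
  cat(sprintf("  C = %g, gamma = %g (CV accuracy %.2f%%)\n",
              x$C, x$gamma, x$cv_accuracy))
  cat(sprintf("  accuracy = %.2f%%  training size = %.2f%% of %d rows\n",
              x$accuracy, x$training_size, x$n))
  invisible(x)
}

#' @export
summary.har_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$table)) {
    cat("\nTop feature pairs by session accuracy:\n")
    tab <- object$table[order(-object$table$accuracy), ]
    print(utils::head(tab, 5), row.names = FALSE, digits = 4)
    if (length(object$failures))
      cat(sprintf("\n%d pair(s) skipped.\n", length(object$failures)))
  }
  invisible(object)
}

#' Predict activity labels for new feature rows
#'
#' @param object A fitted `"har_fit"`.
#' @param newdata A `"har_features"` data.frame (or any data.frame with
#'   the fitted pair's feature columns).
#' @param ... Unused.
#' @return Integer vector of predicted labels.
#' @export
predict.har_fit <- function(object, newdata, ...) {
  xy <- cbind(newdata[[paste0("f", object$pair["j"])]],
              newdata[[paste0("f", object$pair["k"])]])
  predict(object$model, apply_bounds(xy, object$bounds))
}

#' Plot the fitted feature plane
#'
#' Scatter of the winning feature pair colored by true class, with the
#' training rows (candidates or split) over-plotted in black.
#'
#' @param x A `"har_fit"`.
#' @param features The features the model was fitted on.
#' @param max_points Subsample cap for plotting (default 5000).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.har_fit <- function(x, features, max_points = 5000, ...) {
  xy <- cbind(features[[paste0("f", x$pair["j"])]],
              features[[paste0("f", x$pair["k"])]])
  n <- nrow(xy)
  show <- if (n > max_points) seq(1L, n, length.out = max_points) else seq_len(n)
  cols <- c("firebrick", "steelblue", "goldenrod", "turquoise4")
  graphics::plot(xy[show, 1], xy[show, 2],
                 col = cols[features$label[show]], pch = 16, cex = 0.4,
                 xlab = sprintf("f%d", x$pair["j"]),
                 ylab = sprintf("f%d", x$pair["k"]), ...)
  graphics::points(xy[x$train_indices, 1], xy[x$train_indices, 2],
                   pch = 1, cex = 0.5)
  graphics::legend("topright", legend = names(activity_codes),
                   col = cols, pch = 16, cex = 0.8)
  invisible(x)
}
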