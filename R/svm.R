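#' SVM model-selection configuration
#'
#' Grid-search and cross-validation settings for the one-vs-all RBF SVM.
#' The default grid is integer powers of two from 2^-5 to 2^7 on both the
#' cost and kernel-width axes (13 x 13 = 169 points), searched by
#' stratified 5-fold cross-validation.
#'
#' @param c_exponents Integer exponents for `C = 2^e` (default `-5:7`).
#' @param gamma_exponents Integer exponents for `gamma = 2^e`
#'   (default `-5:7`).
#' @param folds Number of cross-validation folds (default 5, `>= 2`).
#' @param seed Seed for fold assignment and data splits.
#' @param cv_tolerance Optimizer convergence tolerance used for the
#'   cross-validation fits during the grid search (default 0.01): fold
#'   accuracy ranking is insensitive to the last digits of the dual
#'   objective, and the relaxed tolerance speeds the search up several
#'   fold. The winning model is refit at `tolerance`.
#' @param tolerance Convergence tolerance for final model fits
#'   (default 0.001, the libsvm default).
#' @return An object of class `"svm_config"`.
#' @export
svm_config <- function(c_exponents = -5:7, gamma_exponents = -5:7,
                       folds = 5, seed = 1L, cv_tolerance = 0.01,
                       tolerance = 0.001) {
  if (folds < 2) stop("folds must be >= 2")
  structure(list(c_grid = 2^c_exponents, gamma_grid = 2^gamma_exponents,
                 folds = as.integer(folds), seed = as.integer(seed),
                 cv_tolerance = cv_tolerance, tolerance = tolerance),
            class = "svm_config")
}

#' Min-max normalization to [0, 1] with training-set bounds
#'
#' Scales each column of the training matrix to `[0, 1]` using its own
#' minimum and maximum; any other matrix is scaled with the *same*
#' bounds and clipped to `[0, 1]`, so no information flows from test to
#' training data.
#'
#' @param train Training matrix (`>= 2` rows).
#' @param other Optional matrix to scale with the training bounds.
#' @return List with `train`, `other` (or `NULL`) and the `bounds`
#'   (2-row matrix of per-column min and max).
#' @export
minmax_normalize <- function(train, other = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need >= 2 training rows")
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  flat <- hi - lo <= 0
  if (any(flat))
    stop(sprintf("degeneracy error: constant training column(s): %s",
                 paste(which(flat), collapse = ", ")))
  scale_ <- function(m, clip) {
    m <- sweep(sweep(as.matrix(m), 2L, lo), 2L, hi - lo, "/")
    if (clip) m[] <- pmin(1, pmax(0, m))
    m
  }
  list(train = scale_(train, clip = FALSE),
       other = if (!is.null(other)) scale_(other, clip = TRUE),
       bounds = rbind(min = lo, max = hi))
}

apply_bounds <- function(m, bounds) {
  m <- sweep(sweep(as.matrix(m), 2L, bounds["min", ]), 2L,
             bounds["max", ] - bounds["min", ], "/")
  m[] <- pmin(1, pmax(0, m))
  m
}

# Stratified fold assignment, seeded; every class needs >= k members.
stratified_folds <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      rows <- which(labels == cls)
      if (length(rows) < k)
        stop(sprintf("folding error: class %s has %d members (< %d folds)",
                     cls, length(rows), k))
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold
  })
}

#' Train a one-vs-all RBF SVM
#'
#' Fits one binary RBF-kernel SVM per class (class vs rest); prediction
#' takes the class whose machine yields the largest decision value.
#' Deterministic for fixed inputs.
#'
#' @param x Numeric feature matrix (already normalized).
#' @param y Integer class labels (`>= 2` distinct values).
#' @param C Cost parameter.
#' @param gamma RBF kernel width.
#' @param tolerance Optimizer convergence tolerance (libsvm default
#'   0.001).
#' @return An object of class `"ova_svm"`.
#' @export
train_ova_rbf <- function(x, y, C, gamma, tolerance = 0.001) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("training error: need at least 2 classes")
  machines <- lapply(classes, function(cls) {
    ybin <- factor(ifelse(y == cls, "pos", "neg"),
                   levels = c("pos", "neg"))
    e1071::svm(x, ybin, scale = FALSE, kernel = "radial",
               cost = C, gamma = gamma, tolerance = tolerance)
  })
  structure(list(classes = classes, machines = machines,
                 C = C, gamma = gamma),
            class = "ova_svm")
}

#' Predict with a one-vs-all SVM
#'
#' @param object An [train_ova_rbf()] model.
#' @param newdata Feature matrix on the training scale.
#' @param ... Unused.
#' @return Integer vector of predicted class labels.
#' @export
predict.ova_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- vapply(object$machines, function(m) {
    p <- stats::predict(m, newdata, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # e1071 orients the decision value by order of appearance in the
    # training data, recorded in the column name "first/second".
    sgn <- if (startsWith(colnames(dv)[1L], "pos")) 1 else -1
    sgn * as.numeric(dv)
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) scores <- matrix(scores, nrow = 1L)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated grid search for (C, gamma)
#'
#' Evaluates every point of the `C x gamma` grid by stratified k-fold
#' cross-validation with the one-vs-all RBF SVM and returns the point
#' with the highest mean fold accuracy. Ties are broken toward larger
#' `C`, then smaller `gamma` (the high-variance / low-bias preference).
#'
#' @param x Normalized feature matrix.
#' @param y Integer labels; every class needs at least `folds` members.
#' @param cfg An [svm_config()].
#' @return List with `C`, `gamma`, `cv_accuracy` (percent) and the full
#'   `grid` data.frame.
#' @export
grid_search_svm <- function(x, y, cfg = svm_config()) {
  x <- as.matrix(x)
  fold <- stratified_folds(y, cfg$folds, seed = cfg$seed)
  grid <- expand.grid(C = cfg$c_grid, gamma = cfg$gamma_grid)
  grid$cv_accuracy <- NA_real_
  fold_rows <- lapply(seq_len(cfg$folds), function(f) which(fold == f))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(cfg$folds)) {
      test <- fold_rows[[f]]
      model <- train_ova_rbf(x[-test, , drop = FALSE], y[-test],
                             C = grid$C[g], gamma = grid$gamma[g],
                             tolerance = cfg$cv_tolerance)
      correct <- correct +
        sum(predict(model, x[test, , drop = FALSE]) == y[test])
    }
    grid$cv_accuracy[g] <- 100 * correct / length(y)
  }
  best <- order(-grid$cv_accuracy, -grid$C, grid$gamma)[1L]
  list(C = grid$C[best], gamma = grid$gamma[best],
       cv_accuracy = grid$cv_accuracy[best], grid = grid)
}
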