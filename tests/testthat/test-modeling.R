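test_that("min-max normalization uses training bounds only and clips", {
  nm <- minmax_normalize(cbind(c(0, 5, 10), c(1, 2, 3)),
                         other = cbind(c(12, -1), c(2, 2)))
  expect_equal(unname(nm$train[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nm$other[, 1]), c(1, 0))  # clipped to [0, 1]
  expect_equal(unname(nm$other[, 2]), c(0.5, 0.5))
  # idempotent on already-normalized data
  again <- minmax_normalize(nm$train)
  expect_equal(again$train, nm$train)
  expect_error(minmax_normalize(cbind(c(1, 1, 1), c(0, 1, 2))),
               "constant training column")
  expect_error(minmax_normalize(matrix(1, 1, 2)), ">= 2")
})

test_that("one-vs-all training builds one machine per class and separates", {
  f <- toy_features()
  x <- as.matrix(f[, c("f1", "f2")])
  model <- train_ova_rbf(x, f$label, C = 4, gamma = 1)
  expect_length(model$machines, 4)
  pred <- predict(model, x)
  expect_equal(pred, f$label)                 # separable toy: 0 errors
  expect_true(all(pred %in% f$label))
  expect_error(train_ova_rbf(x, rep(1L, nrow(x)), C = 1, gamma = 1),
               "training error")
})

test_that("grid search scores the declared grid and applies the tie rule", {
  f <- toy_features(n_per = 50)
  nm <- minmax_normalize(as.matrix(f[, c("f1", "f2")]))
  cfg <- svm_config(c_exponents = c(0, 2), gamma_exponents = c(-1, 0),
                    folds = 5, seed = 8)
  gs <- grid_search_svm(nm$train, f$label, cfg)
  expect_equal(nrow(gs$grid), 4)
  expect_true(gs$C %in% cfg$c_grid && gs$gamma %in% cfg$gamma_grid)
  expect_equal(gs$cv_accuracy, 100)
  # fully separable: every grid point ties at 100, so the largest C and
  # smallest gamma must win
  expect_equal(gs$C, max(cfg$c_grid))
  expect_equal(gs$gamma, min(cfg$gamma_grid))
  # a class smaller than the fold count cannot be folded
  bad <- f$label; bad[f$label == 4][-(1:3)] <- 1L
  expect_error(grid_search_svm(nm$train, bad, cfg), "folding error")
})

test_that("default grid spans 13x13 integer exponents", {
  cfg <- svm_config()
  expect_equal(length(cfg$c_grid) * length(cfg$gamma_grid), 169)
  expect_equal(range(cfg$c_grid), c(2^-5, 2^7))
  expect_equal(range(cfg$gamma_grid), c(2^-5, 2^7))
})

test_that("iterative fit returns the argmax pair with a full table", {
  f <- toy_features(n_per = 40, sep = 6, d = 12, seed = 71)
  cfg <- svm_config(c_exponents = c(0, 4), gamma_exponents = c(-2, 2),
                    seed = 5)
  fit <- har_fit(f, config = cfg)
  expect_s3_class(fit, "har_fit")
  expect_lte(nrow(fit$table), 66)
  expect_true(all(fit$accuracy >= fit$table$accuracy))
  expect_equal(fit$training_size,
               100 * length(fit$train_indices) / nrow(f))
  # rerun with the same seed is identical
  fit2 <- har_fit(f, config = cfg)
  expect_identical(fit$table, fit2$table)
  expect_identical(predict(fit, f), predict(fit2, f))
  # null-class rows are rejected
  f0 <- f; f0$label[1] <- 0L
  expect_error(har_fit(f0, config = cfg), "null-class")
})

test_that("supervised baseline splits stratified, seeded, and guards edges", {
  f <- toy_features(n_per = 50, seed = 72)
  cfg <- svm_config(c_exponents = 0, gamma_exponents = 0, seed = 2)
  bl <- supervised_baseline(f, pair = c(1, 2), config = cfg)
  expect_equal(bl$training_size, 80)
  # training rows are stratified: 80% of each class
  expect_equal(unname(table(f$label[bl$train_indices])), rep(40L, 4),
               ignore_attr = TRUE)
  expect_equal(bl$accuracy, 100)  # separable toy
  bl2 <- supervised_baseline(f, pair = c(1, 2), config = cfg)
  expect_identical(bl$train_indices, bl2$train_indices)
  expect_error(supervised_baseline(f, fraction = 1), "split error")
})

test_that("normalization bounds never leak test information", {
  f <- toy_features(n_per = 50, seed = 73)
  bl <- supervised_baseline(f, pair = c(1, 2),
                            config = svm_config(c_exponents = 0,
                                                gamma_exponents = 0))
  xy <- cbind(f$f1, f$f2)[bl$train_indices, ]
  expect_equal(unname(bl$bounds["min", ]), unname(apply(xy, 2, min)))
  expect_equal(unname(bl$bounds["max", ]), unname(apply(xy, 2, max)))
})
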