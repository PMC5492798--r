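test_that("read_session parses delimited text, NaN cells and labels", {
  path <- withr::local_tempfile(fileext = ".txt")
  layout <- har_layout(n_imu = 0, n_triaxial = 1)
  writeLines(c("0 1 2 3 1",
               "33.3 4 NaN 6 2",
               "66.6 7 8 9 1"), path)
  s <- read_session(path, layout)
  expect_s3_class(s, "har_session")
  expect_equal(sum(s$missing_mask), 1)
  expect_true(s$missing_mask[2, 2])
  expect_true(all(s$labels %in% c(1, 2)))
  expect_equal(s$values[1, ], c(s01_x = 1, s01_y = 2, s01_z = 3))

  # comma-delimited variant parses identically
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,2,3,1", "33.3,4,NaN,6,2", "66.6,7,8,9,1"), path2)
  s2 <- read_session(path2, layout)
  expect_equal(s2$values, s$values)

  # 6 columns against a 1-sensor layout is a layout error
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 1 2 3 4 1", path3)
  expect_error(read_session(path3, layout), "layout error")

  # non-monotone timestamps and unknown label codes are rejected
  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 1 2 3 1", "5 4 5 6 1"), path4)
  expect_error(read_session(path4, layout), "format error")
  path5 <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 1 2 3 7", path5)
  expect_error(read_session(path5, layout), "label error")
})

test_that("write/read round-trip is the identity, including the mask", {
  cfg <- synth_config(layout = har_layout(1, 2), duration_s = 100 / 30,
                      seed = 11)
  s <- generate_session(cfg)
  expect_equal(nrow(s$values), 100)
  path <- withr::local_tempfile(fileext = ".txt")
  write_session(s, path)
  r <- read_session(path, cfg$layout, sample_rate = s$sample_rate)
  expect_identical(r$timestamps, s$timestamps)
  expect_identical(unname(r$values), unname(s$values))
  expect_identical(r$labels, s$labels)
  expect_identical(unname(r$missing_mask), unname(s$missing_mask))

  # empty stream round-trips
  e <- har_session(numeric(0), matrix(0, 0, 9), integer(0),
                   har_layout(0, 3))
  pe <- withr::local_tempfile(fileext = ".txt")
  write_session(e, pe)
  re <- read_session(pe, har_layout(0, 3), sample_rate = 30)
  expect_equal(nrow(re$values), 0)
})

test_that("the sidecar column map round-trips sensor column indices", {
  layout <- har_layout(1, 2)
  path <- withr::local_tempfile(fileext = ".map")
  write_layout_map(layout, path)
  m <- read_layout_map(path)
  expect_equal(m$timestamp, 1L)
  expect_equal(m$s01, 2:4)
  expect_equal(m$s03, 8:10)
  expect_equal(m$label, 11L)
})

test_that("impute_missing interpolates, edge-fills, and is idempotent", {
  v <- cbind(c(1, NaN, 3), c(NaN, 5, 5), c(2, 2, NaN))
  s <- make_session(v)
  out <- impute_missing(s)
  expect_equal(unname(out$values[, 1]), c(1, 2, 3))
  expect_equal(unname(out$values[, 2]), c(5, 5, 5))
  expect_equal(unname(out$values[, 3]), c(2, 2, 2))
  expect_false(any(out$missing_mask))
  # observed cells unchanged, idempotent
  obs <- !s$missing_mask
  expect_identical(out$values[obs], s$values[obs])
  expect_identical(impute_missing(out)$values, out$values)
  # hold-last-value variant
  locf <- impute_missing(s, method = "locf")
  expect_equal(unname(locf$values[, 1]), c(1, 1, 3))
  expect_equal(unname(locf$values[, 2]), c(5, 5, 5))
  # an entirely missing channel is an error naming the channel
  s2 <- make_session(cbind(c(NaN, NaN, NaN), v[, 1], v[, 3]))
  expect_error(impute_missing(s2), "s01_x")
})

test_that("generate_session is seeded, hits the missing rate, and follows the script", {
  cfg <- synth_config(layout = har_layout(0, 3), duration_s = 10000 / 30,
                      missing_rate = 0.3, seed = 5)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$values), c(10000, 9))
  frac <- mean(a$missing_mask)
  expect_gt(frac, 0.28)
  expect_lt(frac, 0.32)
  # label proportions match the script durations exactly
  expect_equal(unname(table(a$labels)), rep(2500L, 4),
               ignore_attr = TRUE)

  # single-activity script: every label equals 3
  cfg3 <- synth_config(layout = har_layout(0, 1), duration_s = 10,
                       activity_script = list(c(3, 10)), seed = 2)
  s3 <- generate_session(cfg3)
  expect_true(all(s3$labels == 3L))

  # script longer than the session is a config error
  expect_error(synth_config(duration_s = 10,
                            activity_script = list(c(1, 20))),
               "config error")
})

test_that("stand-segment noise matches noise_sigma once gravity is removed", {
  cfg <- synth_config(layout = har_layout(0, 3), duration_s = 400 / 3,
                      activity_script = list(c(1, 400 / 3)),
                      noise_sigma = 80, missing_rate = 0, seed = 9)
  s <- generate_session(cfg)
  resid <- sweep(s$values, 2, colMeans(s$values))
  expect_equal(stats::sd(resid), 80, tolerance = 0.05)
})

test_that("drop_null_rows keeps only the four primitive classes in order", {
  v <- matrix(seq_len(12), 4, 3)
  s <- make_session(v, labels = c(0L, 1L, 0L, 2L))
  d <- drop_null_rows(s)
  expect_equal(d$labels, c(1L, 2L))
  expect_equal(unname(d$values), unname(v[c(2, 4), , drop = FALSE]))
  # all-null becomes empty; no-null is the identity
  e <- drop_null_rows(make_session(v, labels = rep(0L, 4)))
  expect_equal(nrow(e$values), 0)
  s2 <- make_session(v, labels = c(1L, 2L, 3L, 4L))
  expect_identical(drop_null_rows(s2), s2)
})
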