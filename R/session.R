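#' Activity label codes
#'
#' Integer codes used throughout the package for the four primitive
#' locomotion classes, plus 0 for unlabeled (null) rows.
#'
#' @format Named integer vector: stand = 1, walk = 2, sit = 3, lie = 4.
#' @export
activity_codes <- c(stand = 1L, walk = 2L, sit = 3L, lie = 4L)

#' Define a body-worn sensor layout
#'
#' A layout lists the sensors contributing acceleration channels to a
#' session. Every sensor, whether a bare 3-axial accelerometer or a full
#' IMU, contributes exactly three acceleration channels in fixed (x, y, z)
#' order. The default reproduces a typical body-worn deployment of seven
#' IMUs and twelve 3-axial sensors distributed over feet, knees, hip, back,
#' arms, forearms, hands and wrist.
#'
#' @param n_imu Number of IMU devices.
#' @param n_triaxial Number of bare 3-axial acceleration sensors.
#' @param placements Optional character vector of placement names, one per
#'   sensor (IMUs first). Defaults to generic names.
#' @return An object of class `"har_layout"`: a data.frame with columns
#'   `sensor_id`, `placement`, `kind`.
#' @export
har_layout <- function(n_imu = 7, n_triaxial = 12, placements = NULL) {
  n_imu <- as.integer(n_imu)
  n_triaxial <- as.integer(n_triaxial)
  n <- n_imu + n_triaxial
  if (n < 1) stop("layout needs at least one sensor")
  kind <- c(rep("IMU", n_imu), rep("triaxial", n_triaxial))
  if (is.null(placements)) {
    default_imu <- c("left_foot", "right_foot", "back", "right_forearm",
                     "left_forearm", "right_arm", "left_arm")
    default_tri <- c("up_right_knee", "low_right_knee", "hip", "back",
                     "right_forearm_lower", "right_forearm_upper",
                     "left_forearm_lower", "left_forearm_upper",
                     "right_hand", "left_hand", "right_wrist", "chest")
    placements <- c(rep_len(default_imu, n_imu)[seq_len(n_imu)],
                    rep_len(default_tri, n_triaxial)[seq_len(n_triaxial)])
  }
  if (length(placements) != n) stop("placements must name every sensor")
  out <- data.frame(
    sensor_id = sprintf("s%02d", seq_len(n)),
    placement = placements,
    kind = kind,
    stringsAsFactors = FALSE
  )
  class(out) <- c("har_layout", "data.frame")
  out
}

#' Number of acceleration channels in a layout
#' @param layout A [har_layout()].
#' @return Integer, `3 * nrow(layout)`.
#' @export
n_channels <- function(layout) 3L * nrow(layout)

channel_names <- function(layout) {
  as.vector(t(outer(layout$sensor_id, c("x", "y", "z"), paste, sep = "_")))
}

#' Construct a sensor stream
#'
#' The central container: a timestamped multi-channel acceleration matrix
#' with one activity label per row and a missing-value mask. Missing
#' readings are encoded as `NaN` in `values`.
#'
#' @param timestamps Numeric vector of milliseconds, strictly increasing.
#' @param values Numeric matrix, one row per time step, `3 * n_sensors`
#'   columns (arbitrary consistent units, e.g. milli-g).
#' @param labels Integer vector of per-row activity codes in
#'   `{0 (null), 1 (stand), 2 (walk), 3 (sit), 4 (lie)}`.
#' @param layout The [har_layout()] the columns map to.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `"har_session"`.
#' @export
har_session <- function(timestamps, values, labels, layout,
                        sample_rate = 30) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(timestamps) != n || length(labels) != n)
    stop("timestamps, values and labels must have equal row counts")
  if (ncol(values) != n_channels(layout))
    stop(sprintf("layout error: expected %d channels, got %d",
                 n_channels(layout), ncol(values)))
  if (n > 1 && any(diff(timestamps) <= 0))
    stop("format error: timestamps must be strictly increasing")
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% 0:4))
    stop("label error: labels must be in {0,1,2,3,4}")
  colnames(values) <- channel_names(layout)
  structure(
    list(timestamps = as.numeric(timestamps),
         values = values,
         labels = labels,
         missing_mask = is.na(values),
         sample_rate = sample_rate,
         layout = layout),
    class = "har_session")
}

#' @export
print.har_session <- function(x, ...) {
  cat(sprintf("<har_session> %d rows x %d channels (%d sensors), %.6g Hz\n",
              nrow(x$values), ncol(x$values), nrow(x$layout),
              x$sample_rate))
  miss <- mean(x$missing_mask)
  tab <- table(factor(x$labels, levels = 0:4))
  cat(sprintf("  missing: %.1f%%  labels (null/stand/walk/sit/lie): %s\n",
              100 * miss, paste(tab, collapse = "/")))
  invisible(x)
}

#' @export
dim.har_session <- function(x) dim(x$values)

#' Read a columnar session file
#'
#' Parses a whitespace- or comma-delimited numeric text file with one row
#' per time step: first column the timestamp in milliseconds, then
#' `3 * n_sensors` acceleration channels in layout order, and a final
#' integer label column. Missing readings are written as `NaN`.
#'
#' @param path File path.
#' @param layout The expected [har_layout()].
#' @param sample_rate Sampling rate recorded on the returned stream; if
#'   `NULL`, estimated from the median timestamp step.
#' @return A [har_session()].
#' @export
read_session <- function(path, layout, sample_rate = NULL) {
  first <- readLines(path, n = 1L)
  k <- n_channels(layout)
  if (length(first) == 0L) {
    return(har_session(numeric(0), matrix(NA_real_, 0, k), integer(0),
                       layout, sample_rate = if (is.null(sample_rate)) 30
                                             else sample_rate))
  }
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          na.strings = c("NA", "NaN", "nan"),
                          colClasses = "numeric")
  if (ncol(df) != k + 2L)
    stop(sprintf("layout error: file has %d columns, layout expects %d (timestamp + %d channels + label)",
                 ncol(df), k + 2L, k))
  ts <- df[[1L]]
  vals <- as.matrix(df[, 1L + seq_len(k), drop = FALSE])
  dimnames(vals) <- NULL
  vals[is.na(vals)] <- NaN  # the missing sentinel is NaN, not NA
  labs <- df[[ncol(df)]]
  if (anyNA(labs) || any(labs != as.integer(labs)))
    stop("label error: label column must be integer")
  if (any(!(labs %in% 0:4)))
    stop("label error: unknown label code(s): ",
         paste(unique(labs[!(labs %in% 0:4)]), collapse = ", "))
  if (nrow(df) > 1 && any(diff(ts) <= 0))
    stop("format error: timestamps must be strictly increasing")
  if (is.null(sample_rate)) {
    sample_rate <- if (nrow(df) > 1) 1000 / stats::median(diff(ts)) else 30
  }
  har_session(ts, vals, labs, layout, sample_rate = sample_rate)
}

#' Write a session to a delimited text file
#'
#' Values are written with `%.17g` so that [read_session()] reproduces the
#' stream bit-for-bit (values, labels, timestamps and missing mask).
#'
#' @param stream A [har_session()].
#' @param path Output path.
#' @param sep Field separator (default single space).
#' @return Invisibly, `path`.
#' @export
write_session <- function(stream, path, sep = " ") {
  m <- cbind(stream$timestamps, stream$values, stream$labels)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Write or read a sidecar column map for a session file
#'
#' A plain `key: value` text file recording which file columns hold each
#' sensor's (x, y, z) channels, with the timestamp in column 1 and the
#' label in the last column. `read_layout_map` returns a named list of
#' integer column triples.
#'
#' @param layout A [har_layout()].
#' @param path File path for the map.
#' @return `write_layout_map` invisibly returns `path`;
#'   `read_layout_map` returns a named list of integer vectors.
#' @export
write_layout_map <- function(layout, path) {
  k <- nrow(layout)
  lines <- c("timestamp: 1",
             vapply(seq_len(k), function(i) {
               sprintf("%s: %s", layout$sensor_id[i],
                       paste(1L + 3L * (i - 1L) + 1:3, collapse = " "))
             }, character(1)),
             sprintf("label: %d", 3L * k + 2L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_layout_map
#' @export
read_layout_map <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(parts, function(p) as.integer(strsplit(trimws(p[2]),
                                                       " +")[[1]]))
  names(out) <- vapply(parts, function(p) trimws(p[1]), character(1))
  out
}

#' Impute missing sensor readings
#'
#' Fills `NaN` cells per channel. The default interpolates linearly over
#' the timestamps between observed readings and extends the nearest
#' observed value at the edges; `"locf"` carries the last observation
#' forward (first observation backward at the head).
#'
#' @param stream A [har_session()].
#' @param method `"linear"` (default) or `"locf"`.
#' @return A [har_session()] with no missing values; observed cells are
#'   unchanged and the mask is all-`FALSE`.
#' @export
impute_missing <- function(stream, method = c("linear", "locf")) {
  method <- match.arg(method)
  v <- stream$values
  if (!anyNA(v)) {
    stream$missing_mask[] <- FALSE
    return(stream)
  }
  ts <- stream$timestamps
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- !is.na(x)
    if (!any(obs))
      stop(sprintf("imputation error: channel %s is entirely missing",
                   colnames(v)[j]))
    if (all(obs)) next
    if (method == "linear") {
      if (sum(obs) == 1L) {
        x[!obs] <- x[obs]
      } else {
        x[!obs] <- stats::approx(ts[obs], x[obs], xout = ts[!obs],
                                 method = "linear", rule = 2)$y
      }
    } else {
      idx <- cummax(ifelse(obs, seq_along(x), 0L))
      first_obs <- which(obs)[1L]
      idx[idx == 0L] <- first_obs
      x <- x[idx]
    }
    v[, j] <- x
  }
  stream$values <- v
  stream$missing_mask[] <- FALSE
  stream
}

#' Drop unlabeled (null-class) rows
#'
#' Restricts a stream to the four primitive locomotion classes, keeping
#' relative row order.
#'
#' @param stream A [har_session()].
#' @return A [har_session()] whose labels are all in `{1,2,3,4}`.
#' @export
drop_null_rows <- function(stream) {
  keep <- stream$labels %in% 1:4
  stream$timestamps <- stream$timestamps[keep]
  stream$values <- stream$values[keep, , drop = FALSE]
  stream$labels <- stream$labels[keep]
  stream$missing_mask <- stream$missing_mask[keep, , drop = FALSE]
  stream
}
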