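#' Enumerate unordered feature pairs
#'
#' All `C(n, 2)` unordered pairs `(j, k)` with `j < k`, in lexicographic
#' order; 66 pairs for the default 12-feature target function.
#'
#' @param n_features Number of features (default 12).
#' @return Integer matrix with columns `j`, `k`, one row per pair.
#' @export
feature_pairs <- function(n_features = 12) {
  p <- t(utils::combn(n_features, 2))
  colnames(p) <- c("j", "k")
  p
}

#' Class centroid
#'
#' Coordinate-wise arithmetic mean of the class members in a feature
#' plane.
#'
#' @param points Numeric matrix (rows = members).
#' @return Numeric vector of column means.
#' @export
class_centroid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty-class error: no members")
  colMeans(points)
}

#' Distances from class members to an opposite centroid
#'
#' Euclidean distance of each member of one class to the centroid of the
#' opposite class, in member order.
#'
#' @param members Numeric matrix of member coordinates.
#' @param centroid Centroid of the opposite class.
#' @return Numeric vector of distances.
#' @export
distance_vector <- function(members, centroid) {
  members <- as.matrix(members)
  sqrt(rowSums(sweep(members, 2L, centroid)^2))
}

#' Distance-tail candidate selection
#'
#' Selects the members whose distance to the opposite class centroid is
#' at least the mean plus one standard deviation of all such distances
#' (ties at the threshold are included). The default uses the population
#' standard deviation; a single member is always selected (its distance
#' equals the mean and the deviation is zero).
#'
#' @param R Numeric distance vector.
#' @param member_indices Row indices aligned with `R`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The selected indices (subset of `member_indices`).
#' @export
select_candidates <- function(R, member_indices,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(R) != length(member_indices))
    stop("R and member_indices must have equal length")
  if (length(R) == 0) stop("empty-class error: no distances")
  mu <- mean(R)
  sig <- if (length(R) == 1L) 0
         else if (sd_type == "population") sqrt(mean((R - mu)^2))
         else stats::sd(R)
  member_indices[R >= mu + sig]
}

#' Build the vector of candidates (VoC) for one feature pair
#'
#' For every ordered pair of distinct classes `(n, m)`, the members of
#' class `n` in the `(f_j, f_k)` plane are scored by their Euclidean
#' distance to the centroid of class `m`; members in the
#' mean-plus-one-standard-deviation distance tail are selected. The union
#' over all ordered class pairs, deduplicated and sorted, is the
#' candidate training set for that feature pair.
#'
#' @param features A [build_target_function()] result (or data.frame with
#'   `f1..f12` and `label`).
#' @param pair Length-2 integer vector `(j, k)`, `1 <= j < k <= 12`.
#' @param sd_type Passed to [select_candidates()].
#' @return An object of class `"har_voc"`: list with `pair`, sorted
#'   unique `indices`, the selected `values` (2 columns) and `labels`,
#'   and `n_rows`.
#' @export
build_voc <- function(features, pair, sd_type = "population") {
  j <- unname(pair[1L]); k <- unname(pair[2L])
  if (!(j >= 1 && j < k && k <= 12)) stop("pair must satisfy 1 <= j < k <= 12")
  xy <- cbind(features[[paste0("f", j)]], features[[paste0("f", k)]])
  labels <- features$label
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("class-coverage error: need at least 2 classes")
  sel <- integer(0)
  for (n_ in classes) {
    members <- which(labels == n_)
    pts <- xy[members, , drop = FALSE]
    for (m_ in classes) {
      if (m_ == n_) next
      cen <- class_centroid(xy[labels == m_, , drop = FALSE])
      R <- distance_vector(pts, cen)
      sel <- c(sel, select_candidates(R, members, sd_type = sd_type))
    }
  }
  idx <- sort(unique(sel))
  structure(
    list(pair = c(j = j, k = k), indices = idx,
         values = xy[idx, , drop = FALSE], labels = labels[idx],
         n_rows = length(labels)),
    class = "har_voc")
}

#' @export
print.har_voc <- function(x, ...) {
  cat(sprintf("<har_voc> pair (f%d, f%d): %d of %d rows (%.2f%%)\n",
              x$pair["j"], x$pair["k"], length(x$indices), x$n_rows,
              100 * length(x$indices) / x$n_rows))
  invisible(x)
}
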