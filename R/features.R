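#' Signal magnitude vector per sensor
#'
#' Euclidean norm of the 3-axial acceleration of each sensor at each time
#' step; orientation-invariant, so it responds to motion intensity rather
#' than posture.
#'
#' @param stream An imputed [har_session()].
#' @return `n x n_sensors` matrix of magnitudes.
#' @export
signal_magnitude <- function(stream) {
  v <- stream$values
  k <- nrow(stream$layout)
  out <- matrix(0, nrow(v), k)
  for (i in seq_len(k)) {
    cols <- 3L * (i - 1L) + 1:3
    out[, i] <- sqrt(rowSums(v[, cols, drop = FALSE]^2))
  }
  colnames(out) <- stream$layout$sensor_id
  out
}

#' Roll, pitch and yaw angles per sensor
#'
#' The default (`method = "literal"`) computes the axial-ratio angles
#' `roll = atan(accx / (accy + accz))`, `pitch = atan(accy / (accx + accz))`,
#' `yaw = atan(accz / (accx + accy))`, with denominators of magnitude
#' below `eps` replaced by `sign * eps` (`sign(0)` taken as `+1`).
#' `method = "atan2"` gives the conventional gravity-referenced attitude
#' angles `roll = atan2(accy, accz)`,
#' `pitch = atan2(-accx, sqrt(accy^2 + accz^2))`,
#' `yaw = atan2(accz, accx)`.
#'
#' @param stream An imputed [har_session()].
#' @param method `"literal"` (default) or `"atan2"`.
#' @param eps Denominator guard for the literal form.
#' @return `n x 3*n_sensors` matrix, columns grouped per sensor as
#'   (roll, pitch, yaw).
#' @export
rpy_angles <- function(stream, method = c("literal", "atan2"),
                       eps = 1e-9) {
  method <- match.arg(method)
  v <- stream$values
  k <- nrow(stream$layout)
  out <- matrix(0, nrow(v), 3L * k)
  guard <- function(den) {
    s <- ifelse(den >= 0, 1, -1)
    ifelse(abs(den) < eps, s * eps, den)
  }
  for (i in seq_len(k)) {
    cols <- 3L * (i - 1L) + 1:3
    ax <- v[, cols[1]]; ay <- v[, cols[2]]; az <- v[, cols[3]]
    ocols <- 3L * (i - 1L) + 1:3
    if (method == "literal") {
      out[, ocols[1]] <- atan(ax / guard(ay + az))
      out[, ocols[2]] <- atan(ay / guard(ax + az))
      out[, ocols[3]] <- atan(az / guard(ax + ay))
    } else {
      out[, ocols[1]] <- atan2(ay, az)
      out[, ocols[2]] <- atan2(-ax, sqrt(ay^2 + az^2))
      out[, ocols[3]] <- atan2(az, ax)
    }
  }
  colnames(out) <- as.vector(t(outer(stream$layout$sensor_id,
                                     c("roll", "pitch", "yaw"),
                                     paste, sep = "_")))
  out
}

#' Axial component matrix
#'
#' All axial components of all sensors, grouped as all-x columns, then
#' all-y, then all-z; values pass through unchanged.
#'
#' @param stream An imputed [har_session()].
#' @return `n x 3*n_sensors` matrix.
#' @export
axial_matrix <- function(stream) {
  v <- stream$values
  k <- nrow(stream$layout)
  xs <- 3L * (seq_len(k) - 1L) + 1L
  out <- v[, c(xs, xs + 1L, xs + 2L), drop = FALSE]
  colnames(out) <- c(paste0(stream$layout$sensor_id, "_x"),
                     paste0(stream$layout$sensor_id, "_y"),
                     paste0(stream$layout$sensor_id, "_z"))
  out
}

# Deterministic sign convention: the largest-magnitude loading of each
# component is made positive (ties resolved to the first occurrence).
fix_signs <- function(scores, loadings) {
  for (c_ in seq_len(ncol(scores))) {
    jstar <- which.max(abs(loadings[, c_]))
    if (loadings[jstar, c_] < 0) {
      scores[, c_] <- -scores[, c_]
      loadings[, c_] <- -loadings[, c_]
    }
  }
  scores
}

#' Leading principal-component scores
#'
#' Columns are mean-centered and projected onto the leading principal
#' axes (ordered by decreasing explained variance). Row order is
#' preserved and a deterministic sign convention is applied (the
#' largest-magnitude loading of each axis is made positive).
#'
#' @param m Numeric matrix, `>= 3` rows and `>= 2` columns.
#' @param n_components Number of components (default 2).
#' @return `n x n_components` score matrix.
#' @export
pca_scores <- function(m, n_components = 2) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need >= 3 rows and >= 2 columns")
  mc <- sweep(m, 2L, colMeans(m))
  s <- svd(mc, nu = n_components, nv = n_components)
  if (s$d[1L] < 1e-12 * max(1, max(abs(m))))
    stop("degeneracy error: matrix is constant (rank 0 after centering)")
  scores <- s$u %*% diag(s$d[seq_len(n_components)], n_components)
  fix_signs(scores, s$v)
}

#' Leading singular-value scores
#'
#' Projection of the uncentered matrix onto its leading right singular
#' vectors (`U %*% S` restricted to the leading singular values), with
#' the same row preservation and sign convention as [pca_scores()].
#' Unlike PCA this keeps the mean structure, so the two compressions are
#' not redundant.
#'
#' @inheritParams pca_scores
#' @return `n x n_components` score matrix.
#' @export
svd_scores <- function(m, n_components = 2) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need >= 3 rows and >= 2 columns")
  s <- svd(m, nu = n_components, nv = n_components)
  if (s$d[1L] < 1e-12)
    stop("degeneracy error: zero matrix")
  scores <- s$u %*% diag(s$d[seq_len(n_components)], n_components)
  fix_signs(scores, s$v)
}

#' Build the 12-dimensional target function
#'
#' Assembles the per-row feature vector from the three kinematic groups
#' (RPY angles, signal magnitude vector, axial matrix), each compressed
#' to two components by PCA and, separately, by uncentered SVD. Column
#' order is fixed: `f1..f2` = PCA(RPY), `f3..f4` = PCA(SMV),
#' `f5..f6` = PCA(ACC), `f7..f8` = SVD(RPY), `f9..f10` = SVD(SMV),
#' `f11..f12` = SVD(ACC). Row order and labels are carried through
#' unchanged.
#'
#' @param stream An imputed, filtered [har_session()] with at least 3
#'   labeled rows.
#' @param rpy_method Passed to [rpy_angles()].
#' @return An object of class `"har_features"`: a data.frame with columns
#'   `f1`..`f12` and `label`.
#' @export
build_target_function <- function(stream, rpy_method = "literal") {
  groups <- list(
    RPY = rpy_angles(stream, method = rpy_method),
    SMV = signal_magnitude(stream),
    ACC = axial_matrix(stream))
  score <- function(fun, name) {
    tryCatch(fun(groups[[name]]),
             error = function(e)
               stop(sprintf("feature group %s: %s", name,
                            conditionMessage(e)), call. = FALSE))
  }
  cols <- cbind(score(pca_scores, "RPY"), score(pca_scores, "SMV"),
                score(pca_scores, "ACC"), score(svd_scores, "RPY"),
                score(svd_scores, "SMV"), score(svd_scores, "ACC"))
  colnames(cols) <- paste0("f", 1:12)
  out <- as.data.frame(cols)
  out$label <- stream$labels
  class(out) <- c("har_features", "data.frame")
  out
}

#' @export
print.har_features <- function(x, ...) {
  cat(sprintf("<har_features> %d rows x 12 features\n", nrow(x)))
  print(table(factor(x$label, levels = 0:4,
                     labels = c("null", names(activity_codes)))))
  invisible(x)
}

feature_matrix <- function(features) {
  cols <- grep("^f[0-9]+$", names(features), value = TRUE)
  as.matrix(features[, cols, drop = FALSE])
}
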