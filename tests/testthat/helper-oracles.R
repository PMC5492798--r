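# Independent oracles and small fixture builders used across the suite.

# Build a session directly from a values matrix (one sensor per 3 columns).
make_session <- function(values, labels = rep(1L, nrow(values)),
                         sample_rate = 30) {
  values <- as.matrix(values)
  k <- ncol(values) / 3
  stopifnot(k == round(k))
  layout <- har_layout(n_imu = 0, n_triaxial = k)
  ts <- (seq_len(nrow(values)) - 1) * (1000 / sample_rate)
  har_session(ts, values, labels, layout, sample_rate = sample_rate)
}

# Brute-force re-implementation of the candidate selection (steps 5-8):
# plain nested loops, no shared code with build_voc.
oracle_voc <- function(xy, labels, sd_type = "population") {
  classes <- sort(unique(labels))
  picked <- c()
  for (n_ in classes) {
    for (m_ in classes) {
      if (n_ == m_) next
      cen <- c(mean(xy[labels == m_, 1]), mean(xy[labels == m_, 2]))
      members <- which(labels == n_)
      R <- numeric(length(members))
      for (i in seq_along(members)) {
        dx <- xy[members[i], 1] - cen[1]
        dy <- xy[members[i], 2] - cen[2]
        R[i] <- sqrt(dx * dx + dy * dy)
      }
      mu <- sum(R) / length(R)
      if (sd_type == "population") {
        sig <- sqrt(sum((R - mu)^2) / length(R))
      } else {
        sig <- sqrt(sum((R - mu)^2) / max(1, length(R) - 1))
      }
      for (i in seq_along(members)) {
        if (R[i] >= mu + sig) picked <- c(picked, members[i])
      }
    }
  }
  sort(unique(picked))
}

# Brute-force weighted F1 from an explicit confusion matrix.
oracle_weighted_f1 <- function(pred, truth) {
  classes <- sort(unique(truth))
  all_lv <- sort(unique(c(pred, truth)))
  cm <- table(factor(truth, levels = all_lv), factor(pred, levels = all_lv))
  total <- 0
  for (cls in classes) {
    i <- as.character(cls)
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + (sum(truth == cls) / length(truth)) * f1
  }
  total
}

# Signal-to-noise ratio in dB of an estimate against the clean signal.
snr_db <- function(clean, noisy) {
  10 * log10(sum(clean^2) / sum((noisy - clean)^2))
}

# Well-separated 4-class toy feature table (first two columns informative).
toy_features <- function(n_per = 60, sep = 10, d = 2, seed = 70) {
  set.seed(seed)
  means <- rbind(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))
  gaussian_features(n_per, cbind(means, matrix(0, 4, d - 2))[, seq_len(d),
                                                            drop = FALSE])
}

# 4-class Gaussian feature table in d dimensions with given class means.
gaussian_features <- function(n_per_class, means, sigma = 1) {
  d <- ncol(means)
  rows <- do.call(rbind, lapply(seq_len(nrow(means)), function(c_) {
    matrix(stats::rnorm(n_per_class * d, sd = sigma), n_per_class, d) +
      matrix(means[c_, ], n_per_class, d, byrow = TRUE)
  }))
  out <- as.data.frame(rows)
  names(out) <- paste0("f", seq_len(d))
  out$label <- rep(seq_len(nrow(means)), each = n_per_class)
  # shuffle so class blocks are interleaved like a real session
  out <- out[sample.int(nrow(out)), ]
  rownames(out) <- NULL
  class(out) <- c("har_features", "data.frame")
  out
}
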