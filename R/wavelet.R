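# Orthonormal scaling filters (sum = sqrt(2)); Daubechies extremal phase.
wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309,
          0.030841381835560764, 0.0328830116668852,
          -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983,
          -0.12976686756726194, 0.09750160558732304,
          0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511,
          -0.0010773010853084796),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847,
          -0.017369301001807547, -0.044088253930794755,
          0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953)
)

#' Wavelet denoising specification
#'
#' @param family Wavelet family: `"db4"` (default, the common
#'   accelerometry choice), `"haar"`, `"db2"`, `"db6"` or `"db8"` (the
#'   longer filters split the dyadic bands more sharply, useful when the
#'   decomposition depth is chosen to isolate a known signal band).
#' @param level Decomposition depth `J`; `NULL` (default) selects
#'   `min(4, floor(log2(n)) - 2)` per channel at denoising time.
#' @param rule Threshold rule: `"sqtwolog_levelwise"` (default) scales the
#'   universal threshold by a per-scale MAD noise estimate,
#'   `lambda_j = sigma_j * sqrt(2 log N_j)`; `"sqtwolog_global"` uses one
#'   threshold `sigma * sqrt(2 log N)` with `sigma` estimated from the
#'   finest detail scale.
#' @param mode Thresholding mode, `"soft"` (default) or `"hard"`.
#' @return An object of class `"wavelet_spec"`.
#' @export
wavelet_spec <- function(family = "db4", level = NULL,
                         rule = c("sqtwolog_levelwise", "sqtwolog_global"),
                         mode = c("soft", "hard")) {
  family <- match.arg(family, names(wavelet_filters))
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  if (!is.null(level) && level < 1) stop("level error: J must be >= 1")
  structure(list(family = family, level = level, rule = rule, mode = mode),
            class = "wavelet_spec")
}

#' Robust noise scale from wavelet coefficients
#'
#' Median absolute value of the coefficients divided by 0.6745, the 0.75
#' quantile of the standard normal: for Gaussian noise the detail
#' coefficients at a scale are approximately N(0, sigma^2) and this
#' statistic is a consistent, outlier-resistant estimate of sigma.
#'
#' @param coeffs Numeric vector of wavelet coefficients.
#' @param constant The normal consistency constant (default 0.6745).
#' @return Estimated sigma.
#' @export
mad_sigma <- function(coeffs, constant = 0.6745) {
  if (length(coeffs) == 0) stop("value error: empty coefficient vector")
  stats::median(abs(coeffs)) / constant
}

#' Universal (SQTWOLOG) threshold
#'
#' `lambda = sqrt(2 log N)` for a signal of length `N`; multiplied by a
#' per-scale [mad_sigma()] estimate in the level-wise rule. The
#' `literal = TRUE` form returns `2 * log(N)` (no square root) for
#' auditing against the non-standard printed variant of the rule.
#'
#' @param N Signal (or per-scale coefficient) length, `>= 1`.
#' @param literal Use the literal `2 log N` form (default `FALSE`).
#' @return The threshold value.
#' @export
sqtwolog_threshold <- function(N, literal = FALSE) {
  if (N < 1) stop("value error: N must be >= 1")
  if (literal) 2 * log(N) else sqrt(2 * log(N))
}

#' Hard or soft thresholding of wavelet coefficients
#'
#' Hard: keep `k` where `|k| > lambda`, else 0. Soft: shrink,
#' `sign(k) * max(|k| - lambda, 0)`. With `literal = TRUE` the soft rule
#' returns the bare shrink factor `max(0, 1 - lambda/|k|)` (audit form).
#'
#' @param coeffs Numeric coefficients.
#' @param lambda Threshold, `>= 0`.
#' @param mode `"hard"` or `"soft"`.
#' @param literal Audit form of the soft rule (default `FALSE`).
#' @return Thresholded coefficients.
#' @export
threshold_coeffs <- function(coeffs, lambda, mode = c("soft", "hard"),
                             literal = FALSE) {
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be >= 0")
  if (mode == "hard") {
    ifelse(abs(coeffs) > lambda, coeffs, 0)
  } else if (literal) {
    pmax(0, 1 - lambda / abs(coeffs))
  } else {
    sign(coeffs) * pmax(abs(coeffs) - lambda, 0)
  }
}

# One level of the periodized orthogonal DWT (length must be even).
dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  idx <- (outer(2L * (seq_len(half) - 1L), 0:(length(h) - 1L), "+") %% n) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  for (k in seq_len(half)) {
    pos <- ((2L * (k - 1L) + 0:(length(h) - 1L)) %% n) + 1L
    x[pos] <- x[pos] + h * a[k] + g * d[k]
  }
  x
}

#' Dyadic discrete wavelet transform
#'
#' Periodized orthogonal DWT to depth `J`; the input is symmetrically
#' extended at the tail to the next multiple of `2^J` first, so any length
#' `>= 2^J` is accepted and [idwt()] restores it exactly.
#'
#' @param x Numeric signal.
#' @param family Wavelet family name (see [wavelet_spec()]).
#' @param J Decomposition depth.
#' @return List with approximation `a`, detail list `d` (finest first),
#'   `family`, `J` and the original length `n`.
#' @export
dwt <- function(x, family = "db4", J = 4) {
  h <- wavelet_filters[[match.arg(family, names(wavelet_filters))]]
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- length(x)
  if (n < 2^J) stop(sprintf("level error: length %d < 2^%d", n, J))
  m <- as.integer(ceiling(n / 2^J) * 2^J)
  if (m > n) x <- c(x, x[n:(2 * n - m + 1)])  # symmetric tail extension
  d <- vector("list", J)
  for (j in seq_len(J)) {
    s <- dwt_step(x, h, g)
    d[[j]] <- s$d
    x <- s$a
  }
  list(a = x, d = d, family = family, J = J, n = n)
}

#' Inverse dyadic discrete wavelet transform
#'
#' @param w A decomposition from [dwt()].
#' @return The reconstructed signal, truncated to the original length.
#' @export
idwt <- function(w) {
  h <- wavelet_filters[[w$family]]
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  x <- w$a
  for (j in rev(seq_len(w$J))) x <- idwt_step(x, w$d[[j]], h, g)
  x[seq_len(w$n)]
}

#' Wavelet-threshold denoising of one channel
#'
#' Decomposes the channel to depth `J`, thresholds the detail coefficients
#' (the approximation is untouched) with the SQTWOLOG universal rule and a
#' MAD noise estimate, and reconstructs. Output length equals input
#' length.
#'
#' @param channel Numeric signal, length `>= 2^J`.
#' @param spec A [wavelet_spec()].
#' @return The denoised channel.
#' @export
wavelet_denoise <- function(channel, spec = wavelet_spec()) {
  n <- length(channel)
  J <- if (is.null(spec$level)) max(1L, min(4L, floor(log2(n)) - 2L))
       else spec$level
  w <- dwt(channel, family = spec$family, J = J)
  if (spec$rule == "sqtwolog_global") {
    sigma <- mad_sigma(w$d[[1L]])
    lambda <- sigma * sqtwolog_threshold(length(channel))
    w$d <- lapply(w$d, threshold_coeffs, lambda = lambda, mode = spec$mode)
  } else {
    w$d <- lapply(w$d, function(dj) {
      lambda <- mad_sigma(dj) * sqtwolog_threshold(length(dj))
      threshold_coeffs(dj, lambda, mode = spec$mode)
    })
  }
  idwt(w)
}

#' Two-stage consecutive denoising of a stream
#'
#' The package's preprocessing front end: band-pass FIR filtering followed
#' by per-channel wavelet thresholding. `single_stage = TRUE` skips the
#' FIR and applies the wavelet stage only, for comparing the two
#' preprocessing variants.
#'
#' @param stream An imputed [har_session()].
#' @param fir A [fir_bandpass()] design; `NULL` designs the default
#'   2-15 Hz order-40 filter at the stream's sampling rate (the upper edge
#'   is pulled just below Nyquist when the rate is too low for 15 Hz).
#' @param wavelet A [wavelet_spec()].
#' @param single_stage Apply only the wavelet stage (default `FALSE`).
#' @return The filtered [har_session()].
#' @export
two_stage_filter <- function(stream, fir = NULL, wavelet = wavelet_spec(),
                             single_stage = FALSE) {
  if (anyNA(stream$values))
    stop("stream contains NaN; impute before filtering")
  if (!single_stage) {
    if (is.null(fir)) {
      fs <- stream$sample_rate
      fir <- fir_bandpass(order = 40, f_low = 2,
                          f_high = min(15, 0.45 * fs), fs = fs)
    }
    stream <- apply_fir(stream, fir)
  }
  stream$values <- apply(stream$values, 2L, wavelet_denoise, spec = wavelet)
  stream
}
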