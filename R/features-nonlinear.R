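#' Delay embedding of a scalar series
#'
#' @param x numeric vector.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return matrix with `length(x) - (m - 1) * tau` rows and `m` columns.
#' @export
embed_delay <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  if (n < 1) stop("series too short for this embedding")
  sapply(seq_len(m), function(k) x[(1 + (k - 1) * tau):((k - 1) * tau + n)])
}

# delay from the autocorrelation 1/e decay (falls back to the first zero
# crossing, capped); for near-white series this returns 1
default_delay <- function(x, max_lag = max(2L, length(x) %/% 20L)) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  z <- which(a <= exp(-1))
  if (length(z)) z[1] else max_lag
}

# dominant period in samples, from the periodogram peak (DC excluded)
dominant_period <- function(x) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  k <- which.max(p[2:(floor(n / 2) + 1)])   # cycles per series
  max(1L, round(n / k))
}

#' Approximate entropy (regularity statistic)
#'
#' Pincus' ApEn: `Phi_m(r) - Phi_{m+1}(r)` with Chebyshev-distance template
#' matching, self-matches included. The tolerance is expressed as a fraction
#' of the window's standard deviation, which makes the statistic invariant
#' to amplitude scaling. Regular signals score low, irregular signals high.
#'
#' @param window numeric vector (length >= 50 recommended).
#' @param m template length, default 2.
#' @param r tolerance as a fraction of `sd(window)`, default 0.2.
#' @return nonnegative scalar.
#' @export
approximate_entropy <- function(window, m = 2, r = 0.2) {
  if (r <= 0) stop("tolerance r must be positive")
  s <- sd(window)
  if (s == 0) return(0)                      # perfectly regular
  apen_cpp(as.numeric(window), as.integer(m), r * s)
}

#' C0 complexity (stochastic-component fraction)
#'
#' Splits the signal into a "regular" part, reconstructed from the Fourier
#' coefficients whose squared magnitude exceeds `threshold` times the mean
#' squared magnitude, and a residual; returns residual power over total
#' power, a value in [0, 1]. Near 0 for a pure tone, large for broadband
#' noise. The mean is removed first, so the value ignores DC offsets.
#'
#' @param window numeric vector (length >= 64 recommended).
#' @param threshold multiple of the mean spectral power above which a
#'   coefficient is kept in the regular part (default 3).
#' @export
c0_complexity <- function(window, threshold = 3) {
  x <- window - mean(window)
  tot <- sum(x^2)
  if (tot == 0) stop("zero-power window")
  X <- fft(x)
  p <- Mod(X)^2
  keep <- p > threshold * mean(p)
  Xr <- X; Xr[!keep] <- 0
  reg <- Re(fft(Xr, inverse = TRUE)) / length(x)
  min(1, max(0, sum((x - reg)^2) / tot))
}

# shared correlation-sum machinery: log-spaced radius grid + C_m(eps) table
corr_sum_table <- function(x, tau, mmax, theiler, n_eps = 32) {
  rng <- diff(range(x))
  if (rng == 0) stop("degenerate (constant) window")
  eps <- exp(seq(log(rng / 1000), log(rng), length.out = n_eps))
  C <- corr_sums_cpp(as.numeric(x), as.integer(tau), as.integer(mmax),
                     eps, as.integer(theiler))
  list(eps = eps, C = C)
}

# least-squares slope of log C vs log eps over the scaling region
# (C within [c_lo, c_hi]); NA when fewer than 3 usable points
scaling_slope <- function(eps, Cm, c_lo = 0.001, c_hi = 0.05) {
  ok <- is.finite(Cm) & Cm >= c_lo & Cm <= c_hi
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm(log(Cm[ok]) ~ log(eps[ok])))[2])
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Slope of `log C(eps)` versus `log eps` in the scaling region of the
#' correlation integral on a delay embedding. The embedding dimension is
#' chosen from `m_range` by slope saturation: the first m whose slope gain
#' over m-1 drops below 0.15 (for i.i.d. noise the slope keeps growing with
#' m and the largest m in the range is reported, flagged unsaturated).
#'
#' @param window numeric vector; >= 500 samples recommended (shorter input
#'   is accepted with a warning - the estimate is then low-confidence).
#' @param m_range candidate embedding dimensions, default 2:8.
#' @param tau delay in samples; default: autocorrelation 1/e decay time.
#' @param theiler temporal exclusion window; default: the dominant signal
#'   period (capped at a tenth of the window), which keeps temporally
#'   correlated near-phase pairs out of the correlation sum.
#' @return dimension estimate with attribute `saturated`.
#' @export
correlation_dimension <- function(window, m_range = 2:8, tau = NULL,
                                  theiler = NULL) {
  if (length(window) < 500)
    warning("fewer than 500 samples: correlation-dimension estimate is low-confidence")
  if (is.null(tau)) tau <- default_delay(window)
  if (is.null(theiler))
    theiler <- min(dominant_period(window), length(window) %/% 10L)
  tab <- corr_sum_table(window, tau, max(m_range), theiler)
  slopes <- vapply(m_range, function(m) scaling_slope(tab$eps, tab$C[m, ]),
                   numeric(1))
  ok <- which(is.finite(slopes))
  if (!length(ok)) return(structure(NA_real_, saturated = FALSE))
  slopes <- slopes[ok]; ms <- m_range[ok]
  if (length(slopes) == 1)
    return(structure(slopes, saturated = TRUE))
  gain <- diff(slopes)
  sat <- which(gain < 0.15)
  if (length(sat))
    structure(slopes[sat[1] + 1L], saturated = TRUE)
  else
    structure(slopes[length(slopes)], saturated = FALSE)
}

#' Kolmogorov (K2) entropy rate
#'
#' Second-order entropy rate from the ratio of correlation integrals at
#' successive embedding dimensions: `ln(C_m(eps) / C_{m+1}(eps))`, averaged
#' over the scaling region and divided by the delay, in nats per sample.
#' Near zero for periodic signals, positive for chaotic ones.
#'
#' @param window numeric vector.
#' @param m embedding dimension, default 2.
#' @param tau delay; default: autocorrelation 1/e decay time.
#' @param theiler temporal exclusion window; default as in
#'   [correlation_dimension()].
#' @return nonnegative rate, or NA with attribute `undefined = TRUE` when no
#'   radius falls in the scaling region of both dimensions.
#' @export
kolmogorov_entropy <- function(window, m = 2, tau = NULL, theiler = NULL) {
  if (is.null(tau)) tau <- default_delay(window)
  if (is.null(theiler))
    theiler <- min(dominant_period(window), length(window) %/% 10L)
  tab <- corr_sum_table(window, tau, m + 1, theiler)
  Cm <- tab$C[m, ]; Cm1 <- tab$C[m + 1, ]
  ok <- is.finite(Cm) & is.finite(Cm1) & Cm1 > 0 &
    Cm >= 0.01 & Cm <= 0.25
  if (!any(ok)) return(structure(NA_real_, undefined = TRUE))
  max(0, mean(log(Cm[ok] / Cm1[ok])) / tau)
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Tracks the mean log divergence of nearest-neighbour trajectory pairs
#' (Theiler window = dominant signal period) and fits a least-squares slope
#' over the initial linear span of the divergence curve, in nats per sample.
#' Positive values indicate chaos; the construction is invariant to
#' amplitude scaling.
#'
#' @param window numeric vector, >= 500 samples recommended.
#' @param m embedding dimension, default 5.
#' @param tau delay, default 1.
#' @param t_max divergence horizon in samples, default 30.
#' @return slope estimate, or NA flagged `undefined` when no neighbour pair
#'   is available.
#' @export
lyapunov_exponent <- function(window, m = 5, tau = 1, t_max = 30) {
  theiler <- min(dominant_period(window), length(window) %/% 10L)
  # distances below the resolution floor are clamped, so an exactly
  # periodic signal yields a flat divergence curve (slope 0), not a fit
  # to rounding noise
  floor_d <- 1e-10 * max(sd(window), .Machine$double.xmin)
  curve <- rosenstein_cpp(as.numeric(window), as.integer(m),
                          as.integer(tau), as.integer(theiler),
                          as.integer(t_max), floor_d)
  curve <- curve[is.finite(curve)]
  if (length(curve) < 3) return(structure(NA_real_, undefined = TRUE))
  # initial linear span: stop once the curve comes within 0.5 nat of its
  # saturation plateau
  top <- max(curve)
  span <- which(curve < top - 0.5)
  span <- span[span == seq_along(span)]       # leading consecutive run
  if (length(span) < 3) span <- seq_len(min(5L, length(curve)))
  t_axis <- span - 1
  unname(coef(lm(curve[span] ~ t_axis))[2])
}

#' Permutation entropy (ordinal-pattern entropy)
#'
#' Bandt-Pompe entropy of the distribution of ordinal patterns of length
#' `m`, normalized by `log(m!)` so the value lies in [0, 1]: 0 for a fully
#' regular (e.g. monotonic) series, 1 in the limit of a completely random
#' one. Ties are resolved by order of occurrence.
#'
#' @param window numeric vector.
#' @param m pattern order (>= 2), default 3.
#' @param tau delay between pattern elements, default 1.
#' @export
permutation_entropy <- function(window, m = 3, tau = 1) {
  if (m < 2) stop("pattern order m must be >= 2")
  E <- embed_delay(window, m, tau)
  # encode each row's permutation through its pairwise comparisons
  code <- integer(nrow(E))
  bit <- 1L
  for (k in 1:(m - 1)) for (l in (k + 1):m) {
    code <- code + bit * (E[, k] > E[, l])
    bit <- bit * 2L
  }
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  # + 0 normalizes IEEE negative zero for the fully regular case
  -sum(p * log(p)) / log(factorial(m)) + 0
}

#' Singular-spectrum (SVD) entropy
#'
#' Shannon entropy of the normalized singular-value spectrum of the delay
#' trajectory matrix, normalized by `log(m)`; a rank-deficient (highly
#' regular) trajectory scores low, an isotropic (noisy) one scores high.
#' The window mean is removed first.
#'
#' @param window numeric vector.
#' @param m trajectory dimension, default 20.
#' @param tau delay, default 1.
#' @return value in [0, 1]; a constant window gives 0 by convention.
#' @export
svd_entropy <- function(window, m = 20, tau = 1) {
  x <- window - mean(window)
  if (all(x == 0)) return(0)
  s <- svd(embed_delay(x, m, tau), nu = 0, nv = 0)$d
  p <- s / sum(s)
  p <- p[p > 0]
  -sum(p * log(p)) / log(m)
}

#' Shannon entropy of the amplitude distribution
#'
#' Histograms the samples into `n_bins` equal-width bins spanning
#' `[min, max]` and returns the natural-log Shannon entropy of the bin
#' probabilities (`0 log 0 = 0`). A constant window gives 0.
#'
#' @param window numeric vector.
#' @param n_bins number of bins (>= 2), default 16.
#' @export
shannon_entropy <- function(window, n_bins = 16) {
  if (n_bins < 2) stop("need at least 2 bins")
  rng <- range(window)
  if (diff(rng) == 0) return(0)
  idx <- pmin(n_bins, 1L + floor((window - rng[1]) / diff(rng) * n_bins))
  p <- tabulate(idx, n_bins) / length(window)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spectral (power-spectral) entropy
#'
#' Normalizes the periodogram of the mean-removed window to a probability
#' distribution over frequency bins and returns its Shannon entropy divided
#' by the log bin count: near 0 for a pure tone, near 1 for white noise.
#'
#' @param window numeric vector (length >= 8).
#' @param fs sampling rate in Hz.
#' @return value in [0, 1].
#' @export
spectral_entropy <- function(window, fs) {
  x <- window - mean(window)
  if (all(x == 0)) stop("zero window")
  ps <- power_spectrum(x, fs)
  d <- ps$density[-1]                        # DC bin is 0 after mean removal
  p <- d / sum(d)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(d))
}
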