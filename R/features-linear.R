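#' Time-frequency domain window features
#'
#' The nine linear descriptors computed on each sliding window: peak-to-peak
#' amplitude, mean square, variance, the three Hjorth parameters (activity,
#' mobility, complexity), and three periodogram summaries (frequency of the
#' maximum power spectral density, the maximum density itself, and the power
#' sum). Variance is the population variance (divide by n) so that the
#' Hjorth ratios are convention-free; first differences are per-sample
#' (not scaled by fs), so mobility/complexity are in per-sample units.
#'
#' @param window numeric vector of samples.
#' @name linear_features
NULL

#' @rdname linear_features
#' @export
peak_peak <- function(window) {
  if (!length(window)) stop("empty window")
  max(window) - min(window)
}

#' @rdname linear_features
#' @export
mean_square <- function(window) {
  if (!length(window)) stop("empty window")
  mean(window^2)
}

#' @rdname linear_features
#' @export
pop_variance <- function(window) {
  if (length(window) < 2) stop("need at least 2 samples")
  mean((window - mean(window))^2)
}

#' @rdname linear_features
#' @export
hjorth_activity <- function(window) pop_variance(window)

#' @rdname linear_features
#' @export
hjorth_mobility <- function(window) {
  if (length(window) < 3) stop("need at least 3 samples")
  v <- pop_variance(window)
  if (v == 0) stop("zero-variance window")
  sqrt(pop_variance(diff(window)) / v)
}

#' @rdname linear_features
#' @export
hjorth_complexity <- function(window) {
  if (length(window) < 4) stop("need at least 4 samples")
  hjorth_mobility(diff(window)) / hjorth_mobility(window)
}

#' One-sided periodogram of a window
#'
#' Density per FFT bin, scaled so that summing the densities over all bins
#' returns the window's mean square exactly (Parseval).
#'
#' @param window numeric vector (length >= 8).
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz) and `density`.
#' @export
power_spectrum <- function(window, fs) {
  n <- length(window)
  if (n < 8) stop("window too short for a periodogram")
  X <- fft(window)
  nyq <- floor(n / 2)
  p <- Mod(X[1:(nyq + 1)])^2 / n^2
  # double the interior bins so the one-sided sum preserves total power
  interior <- 2:(nyq + if (n %% 2 == 0) 0 else 1)
  p[interior] <- 2 * p[interior]
  list(freq = (0:nyq) * fs / n, density = p)
}

#' @rdname linear_features
#' @param fs sampling rate in Hz.
#' @export
max_psd <- function(window, fs) {
  ps <- power_spectrum(window, fs)
  max(ps$density)
}

#' @rdname linear_features
#' @export
max_psd_freq <- function(window, fs) {
  ps <- power_spectrum(window, fs)
  if (all(ps$density == 0)) {
    warning("all-zero window: maximum-PSD frequency defined as 0 Hz")
    return(0)
  }
  ps$freq[which.max(ps$density)]
}

#' @rdname linear_features
#' @export
power_sum <- function(window, fs) {
  ps <- power_spectrum(window, fs)
  sum(ps$density)
}
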