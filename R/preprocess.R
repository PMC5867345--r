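#' Canonical EEG rhythm bands
#'
#' Theta 4-7 Hz, alpha 8-15 Hz, beta 16-31 Hz and gamma above 32 Hz. The
#' delta band (< 4 Hz) is deliberately absent: it carries sleep-related
#' rather than affective information. The open upper edge of gamma is closed
#' at `min(gamma_high, 0.45 * fs)` when a sampling rate is supplied, keeping
#' clear of the Nyquist frequency and mains-notch territory.
#'
#' @param fs optional sampling rate used to cap the gamma band.
#' @param gamma_high upper gamma cutoff in Hz before the Nyquist cap.
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
rhythm_bands <- function(fs = NULL, gamma_high = 45) {
  hi <- if (is.null(fs)) gamma_high else min(gamma_high, 0.45 * fs)
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low  = c(4, 8, 16, 32),
             high = c(7, 15, 31, hi),
             stringsAsFactors = FALSE)
}

RHYTHMS <- c("theta", "alpha", "beta", "gamma")

#' Design a linear-phase FIR bandpass filter
#'
#' Hanning-windowed FIR design (via [signal::fir1]). The order is even so
#' the group delay `order/2` is an integer sample count, which lets the
#' filter be applied with exactly zero phase by delay compensation.
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (even); default `2 * fs` taps gives a
#'   transition band of roughly 1.5 Hz.
#' @return numeric vector of `order + 1` symmetric filter coefficients with
#'   attributes `fs` and `order`.
#' @export
design_bandpass <- function(low, high, fs, order = 2 * round(fs)) {
  if (order %% 2 != 0) stop("filter order must be even")
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2)
    stop(sprintf("band edge %g Hz reaches the Nyquist frequency %g Hz",
                 high, fs / 2))
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass",
                    window = signal::hanning(order + 1))
  structure(as.numeric(b), fs = fs, order = order, low = low, high = high)
}

#' Frequency response magnitude of an FIR filter
#'
#' @param b coefficients from [design_bandpass()].
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate; defaults to the one stored on `b`.
#' @return magnitude (linear scale) at each frequency.
#' @export
filter_response <- function(b, freqs, fs = attr(b, "fs")) {
  w <- 2 * pi * freqs / fs
  k <- seq_along(b) - 1
  Mod(vapply(w, function(wi) sum(b * exp(-1i * wi * k)), complex(1)))
}

# Zero-phase application of a symmetric odd-length FIR filter: FFT-based
# convolution, then removal of the integer group delay. Output has the
# length of x; the first/last order/2 samples carry edge transients and are
# trimmed downstream before windowing.
fir_apply <- function(x, b) {
  n <- length(x)
  half <- (length(b) - 1L) %/% 2L
  nf <- stats::nextn(n + length(b) - 1L, 2)
  y <- Re(fft(fft(c(x, rep(0, nf - n))) *
              fft(c(b, rep(0, nf - length(b)))), inverse = TRUE)) / nf
  y[(half + 1L):(half + n)]
}

#' Decompose a trial into rhythm-band signals
#'
#' Filters every channel with a zero-phase FIR bandpass per rhythm. Shapes
#' are preserved; edge transients (filter order / 2 samples at each end)
#' remain in place and are trimmed at the windowing stage.
#'
#' @param trial a [trial()] object.
#' @param bands data.frame as produced by [rhythm_bands()].
#' @param order FIR order, passed to [design_bandpass()].
#' @return An object of class `rhythm_bank`: the trial plus one
#'   channels x samples matrix per band.
#' @export
extract_rhythms <- function(trial, bands = rhythm_bands(trial$fs),
                            order = 2 * round(trial$fs)) {
  if (n_samples(trial) < 3 * order)
    stop("trial too short for the filter transient (need >= 3 * order samples)")
  band_signals <- lapply(seq_len(nrow(bands)), function(i) {
    b <- design_bandpass(bands$low[i], bands$high[i], trial$fs, order)
    out <- t(apply(trial$signal, 1, fir_apply, b = b))
    rownames(out) <- trial$channel_labels
    out
  })
  names(band_signals) <- bands$name
  structure(list(trial = trial, band_signals = band_signals,
                 bands = bands, order = order),
            class = "rhythm_bank")
}

#' @export
print.rhythm_bank <- function(x, ...) {
  cat(sprintf("<rhythm_bank %s/%s> bands: %s\n", x$trial$subject_id,
              x$trial$trial_id, paste(names(x$band_signals), collapse = ", ")))
  invisible(x)
}

#' Per-subject channel-wise z-normalization
#'
#' For one subject, pools every channel's samples across all of that
#' subject's trials and z-scores the channel (pooled mean 0, pooled sd 1).
#' Removes per-subject amplitude/offset idiosyncrasies while preserving the
#' relative variability of channels. When given `rhythm_bank` objects the
#' normalization is applied independently per rhythm stream.
#'
#' Subjects must be normalized separately: statistics of one subject never
#' touch another's data.
#'
#' @param xs list of [trial()] or `rhythm_bank` objects, all from the same
#'   subject.
#' @return list of the same class with normalized signals.
#' @export
normalize_subject <- function(xs) {
  stopifnot(length(xs) > 0)
  if (inherits(xs[[1]], "rhythm_bank")) {
    subj <- unique(vapply(xs, function(b) b$trial$subject_id, character(1)))
    if (length(subj) != 1) stop("normalize_subject expects a single subject")
    bands <- names(xs[[1]]$band_signals)
    for (bd in bands) {
      mats <- lapply(xs, function(b) b$band_signals[[bd]])
      mats <- normalize_matrices(mats, band = bd)
      for (i in seq_along(xs)) xs[[i]]$band_signals[[bd]] <- mats[[i]]
    }
    return(xs)
  }
  subj <- unique(vapply(xs, function(tr) tr$subject_id, character(1)))
  if (length(subj) != 1) stop("normalize_subject expects a single subject")
  mats <- normalize_matrices(lapply(xs, `[[`, "signal"))
  for (i in seq_along(xs)) xs[[i]]$signal <- mats[[i]]
  xs
}

# z-score each channel (row) using moments pooled across a list of matrices
normalize_matrices <- function(mats, band = NULL) {
  pooled <- do.call(cbind, mats)
  mu <- rowMeans(pooled)
  sdv <- apply(pooled, 1, sd)      # sample sd; any constant channel is an error
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop("zero-variance channel(s): ",
         paste(rownames(pooled)[bad], collapse = ", "),
         if (!is.null(band)) paste0(" (band ", band, ")") else "")
  lapply(mats, function(m) (m - mu) / sdv)
}

#' Sliding-window plan
#'
#' @param window_len window length in seconds (default 4).
#' @param overlap overlap between consecutive windows in seconds (default 2).
#' @export
window_plan <- function(window_len = 4, overlap = 2) {
  if (!(overlap >= 0 && overlap < window_len))
    stop("need 0 <= overlap < window_len")
  structure(list(window_len = window_len, overlap = overlap),
            class = "window_plan")
}

#' Segment a single-channel series into sliding windows
#'
#' Stride is `window_len - overlap`; the last window never passes the end of
#' the series, so the count is `floor((duration - window_len)/stride) + 1`.
#'
#' @param series numeric vector.
#' @param fs sampling rate in Hz.
#' @param plan a [window_plan()].
#' @return list of numeric windows.
#' @export
segment_windows <- function(series, fs, plan = window_plan()) {
  wl <- round(plan$window_len * fs)
  stride <- round((plan$window_len - plan$overlap) * fs)
  if (length(series) < wl)
    stop("series shorter than one window")
  starts <- seq(1L, length(series) - wl + 1L, by = stride)
  lapply(starts, function(s) series[s:(s + wl - 1L)])
}
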