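#' Configuration for the synthetic affective-EEG generator
#'
#' The generator emulates the statistical structure of film/music-clip EEG
#' emotion experiments: one-minute trials, multi-subject recordings with
#' per-subject amplitude/offset idiosyncrasies, band-limited oscillatory
#' content in the four classical rhythms, class-dependent beta-band
#' frequency/amplitude shifts, and class-dependent inter-channel correlation
#' (the negative class more strongly correlated than the positive one).
#'
#' Inter-channel correlation comes from a latent-factor construction: per
#' rhythm, every channel mixes one global source, one region-local source
#' and an idiosyncratic source, with loadings set so the expected pairwise
#' correlation of the oscillatory part is `base_corr` (+`local_corr` within
#' a region) for positive-class trials and `base_corr + class_corr_gap` for
#' negative-class trials.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_class trials per emotion class per subject.
#' @param n_channels number of electrodes (2-62, labelled from the 62-channel
#'   10-10 montage unless `channel_labels` is supplied).
#' @param channel_labels optional explicit electrode labels.
#' @param fs sampling rate, Hz (default 200, the 62-channel preset;
#'   see [deap_preset()] for a 32-channel/128 Hz variant).
#' @param duration trial length in seconds (default 60).
#' @param class_beta_shift multiplier applied to the beta-band carrier
#'   frequency and amplitude for positive-class trials; 1 = no class effect.
#' @param class_corr_gap additive increment of the negative class's latent
#'   inter-channel correlation over the positive class's `base_corr`.
#' @param base_corr latent inter-channel correlation of positive trials.
#' @param local_corr extra correlation shared within a scalp region.
#' @param subject_scale_sd sd of the per-subject log-normal gain.
#' @param subject_offset_sd sd of the per-subject per-channel DC offset.
#' @param noise_sd sd of the additive broadband noise.
#' @param beta_freq beta carrier centre frequency, Hz.
#' @param am_depth depth of the slow amplitude modulation of every source.
#' @param seed integer RNG seed; fixed seed gives bit-identical datasets.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_subjects = 15, n_trials_per_class = 5,
                             n_channels = 62, channel_labels = NULL,
                             fs = 200, duration = 60,
                             class_beta_shift = 1.25, class_corr_gap = 0.15,
                             base_corr = 0.3, local_corr = 0.05,
                             subject_scale_sd = 0.2, subject_offset_sd = 0.5,
                             noise_sd = 0.3, beta_freq = 20, am_depth = 0.5,
                             seed = 1) {
  if (n_subjects < 1 || n_trials_per_class < 1 || n_channels < 2)
    stop("counts must be positive (and n_channels >= 2)")
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  if (abs(duration * fs - round(duration * fs)) > 1e-9)
    stop("duration * fs must be an integer sample count")
  if (is.null(channel_labels)) {
    if (n_channels > length(MONTAGE62))
      stop("at most ", length(MONTAGE62), " channels without explicit labels")
    channel_labels <- MONTAGE62[seq_len(n_channels)]
  }
  if (length(channel_labels) != n_channels)
    stop("channel_labels must have n_channels entries")
  rho_neg <- base_corr + class_corr_gap + local_corr
  if (base_corr < 0 || class_corr_gap < 0 || rho_neg > 0.99)
    stop("correlation parameters must stay within [0, 0.99]")
  cfg <- list(n_subjects = n_subjects, n_trials_per_class = n_trials_per_class,
              n_channels = n_channels, channel_labels = channel_labels,
              fs = fs, duration = duration,
              class_beta_shift = class_beta_shift,
              class_corr_gap = class_corr_gap, base_corr = base_corr,
              local_corr = local_corr, subject_scale_sd = subject_scale_sd,
              subject_offset_sd = subject_offset_sd, noise_sd = noise_sd,
              beta_freq = beta_freq, am_depth = am_depth, seed = seed)
  class(cfg) <- "generator_config"
  cfg
}

#' 32-channel / 128 Hz generator preset
#'
#' Mirrors the montage and preprocessed sampling rate of the 32-channel
#' music-video experiment.
#'
#' @param n_subjects number of subjects (default 32).
#' @param ... further overrides forwarded to [generator_config()].
#' @export
deap_preset <- function(n_subjects = 32, ...) {
  generator_config(n_subjects = n_subjects, n_channels = 32,
                   channel_labels = MONTAGE32, fs = 128, ...)
}

# 62-channel 10-10 montage (film-clip experiment layout)
MONTAGE62 <- c(
  "FP1", "FPZ", "FP2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "CB1", "O1", "OZ", "O2", "CB2")

# 32-channel 10-20 montage
MONTAGE32 <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
  "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
  "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
  "PO4", "O2")

# one amplitude-modulated narrowband source: carrier at freq f with random
# phase, multiplied by (1 + depth * m(t)) where m is unit-sd smoothed noise
narrowband_source <- function(n, fs, f, depth) {
  phase <- runif(1, 0, 2 * pi)
  k <- max(2L, round(fs))                      # ~1 s smoothing
  m <- stats::filter(rnorm(n + k), rep(1 / k, k), sides = 1)[(k + 1):(n + k)]
  m <- as.numeric(m)
  s <- sd(m)
  if (s > 0) m <- m / s
  am <- pmax(0, 1 + depth * m)
  am * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# deterministic 4-way region id used for the local latent factors
factor_region <- function(labels) {
  reg <- channel_region(labels)
  axis <- ifelse(reg$axis == "central", "anterior", reg$axis)
  side <- ifelse(reg$side == "midline",
                 rep(c("left", "right"), length.out = length(labels)),
                 reg$side)
  match(paste(axis, side), c("anterior left", "anterior right",
                             "posterior left", "posterior right"))
}

#' Generate a labelled multi-subject synthetic EEG dataset
#'
#' See [generator_config()] for the generative model. For a fixed seed the
#' output is bit-for-bit reproducible.
#'
#' @param config a [generator_config()].
#' @return list of [trial()] objects, `n_subjects * 2 * n_trials_per_class`
#'   in total.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- round(config$duration * config$fs)
  nch <- config$n_channels
  region <- factor_region(config$channel_labels)
  bands <- list(theta = c(4.5, 6.5), alpha = c(8.5, 13), gamma = c(33, 42))
  amp <- c(theta = 1, alpha = 0.9, beta = 0.7, gamma = 0.4)
  gamma_top <- min(42, 0.42 * config$fs)
  bands$gamma <- c(33, max(34, gamma_top))

  trials <- list()
  for (s in seq_len(config$n_subjects)) {
    gain <- exp(rnorm(1, 0, config$subject_scale_sd))
    offset <- rnorm(nch, 0, config$subject_offset_sd)
    sid <- sprintf("S%02d", s)
    for (lab in c("negative", "positive")) {
      rho_g <- config$base_corr +
        if (lab == "negative") config$class_corr_gap else 0
      rho_l <- config$local_corr
      l_g <- sqrt(rho_g); l_l <- sqrt(rho_l); l_e <- sqrt(1 - rho_g - rho_l)
      bshift <- if (lab == "positive") config$class_beta_shift else 1
      for (t in seq_len(config$n_trials_per_class)) {
        x <- matrix(0, nch, n)
        for (bd in c("theta", "alpha", "beta", "gamma")) {
          if (bd == "beta") {
            f0 <- config$beta_freq * bshift + runif(1, -1.5, 1.5)
            a <- amp[["beta"]] * bshift
          } else {
            f0 <- runif(1, bands[[bd]][1], bands[[bd]][2])
            a <- amp[[bd]]
          }
          jit <- function() f0 + runif(1, -0.5, 0.5)
          G <- narrowband_source(n, config$fs, jit(), config$am_depth)
          R <- lapply(1:4, function(g)
            narrowband_source(n, config$fs, jit(), config$am_depth))
          for (c_i in seq_len(nch)) {
            E <- narrowband_source(n, config$fs, jit(), config$am_depth)
            x[c_i, ] <- x[c_i, ] +
              a * (l_g * G + l_l * R[[region[c_i]]] + l_e * E)
          }
        }
        x <- x + matrix(rnorm(nch * n, 0, config$noise_sd), nch, n)
        x <- gain * x + offset
        trials[[length(trials) + 1L]] <-
          trial(x, config$fs, lab, sid,
                sprintf("%s%02d", substr(lab, 1, 3), t),
                config$channel_labels)
      }
    }
  }
  trials
}

#' Analytic fixture signals for validating feature extractors
#'
#' @param kind one of `"constant"`, `"sine"`, `"white_noise"`,
#'   `"logistic_map"`, `"lorenz_x"`, `"monotonic_ramp"`.
#' @param n_samples length of the returned series.
#' @param seed optional RNG seed (used by the stochastic kinds).
#' @param ... kind-specific parameters: `value` (constant); `f`, `fs`,
#'   `amplitude`, `phase` (sine); `sd` (white noise); `r`, `x0`
#'   (logistic map, `x <- r x (1 - x)`); `dt` (Lorenz integration step,
#'   sigma = 10, rho = 28, beta = 8/3, x component returned);
#'   `from`, `to` (ramp).
#' @return numeric vector of length `n_samples`.
#' @export
fixture_signal <- function(kind, n_samples, seed = NULL, ...) {
  p <- list(...)
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples
  switch(match.arg(kind, c("constant", "sine", "white_noise", "logistic_map",
                           "lorenz_x", "monotonic_ramp")),
    constant = rep(if (is.null(p$value)) 0 else p$value, n),
    sine = {
      f <- if (is.null(p$f)) 10 else p$f
      fs <- if (is.null(p$fs)) 200 else p$fs
      a <- if (is.null(p$amplitude)) 1 else p$amplitude
      ph <- if (is.null(p$phase)) 0 else p$phase
      a * sin(2 * pi * f * (0:(n - 1)) / fs + ph)
    },
    white_noise = rnorm(n, 0, if (is.null(p$sd)) 1 else p$sd),
    logistic_map = {
      r <- if (is.null(p$r)) 4 else p$r
      if (!(r > 0 && r <= 4)) stop("logistic_map needs r in (0, 4]")
      x <- if (is.null(p$x0)) 0.4 else p$x0
      out <- numeric(n + 100)
      for (i in seq_along(out)) { x <- r * x * (1 - x); out[i] <- x }
      out[101:(n + 100)]
    },
    lorenz_x = {
      dt <- if (is.null(p$dt)) 0.01 else p$dt
      discard <- 1000
      deriv <- function(t, y, parms)
        list(c(10 * (y[2] - y[1]),
               y[1] * (28 - y[3]) - y[2],
               y[1] * y[2] - 8 / 3 * y[3]))
      times <- seq(0, (n + discard) * dt, by = dt)
      sol <- deSolve::ode(c(x = 1, y = 1, z = 1), times, deriv, NULL,
                          method = "rk4")
      as.numeric(sol[(discard + 1):(discard + n), "x"])
    },
    monotonic_ramp = {
      from <- if (is.null(p$from)) 0 else p$from
      to <- if (is.null(p$to)) 1 else p$to
      if (to <= from) stop("ramp needs to > from")
      seq(from, to, length.out = n)
    })
}
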