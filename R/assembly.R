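#' Default parameters for the 18 feature extractors
#'
#' Embedding and tolerance settings follow conventional literature choices:
#' ApEn m = 2, r = 0.2 sd; permutation entropy m = 3, tau = 1; SVD entropy
#' m = 20; correlation dimension scanned over m = 2..8 and K2 at m = 2 with
#' the delay taken from the first autocorrelation zero crossing; Lyapunov
#' m = 5; Shannon entropy 16 bins; C0 threshold 3x mean spectral power.
#'
#' @param ... overrides of any default listed above.
#' @export
feature_params <- function(...) {
  p <- list(apen_m = 2, apen_r = 0.2, c0_threshold = 3,
            cd_m_range = 2:8, cd_tau = NULL,
            k2_m = 2, k2_tau = NULL,
            lyap_m = 5, lyap_tau = 1, lyap_tmax = 30,
            pe_m = 3, pe_tau = 1, svd_m = 20, svd_tau = 1,
            shannon_bins = 16)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown feature parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' The 18-feature catalogue
#'
#' Features 1-9 are the time-frequency descriptors, 10-18 the nonlinear
#' dynamical-system descriptors.
#'
#' @return data.frame with `feature_id`, `name`, `category`.
#' @export
feature_catalogue <- function() {
  data.frame(
    feature_id = 1:18,
    name = c("peak_peak", "mean_square", "variance", "hjorth_activity",
             "hjorth_mobility", "hjorth_complexity", "max_psd_freq",
             "max_psd", "power_sum",
             "approximate_entropy", "c0_complexity", "correlation_dimension",
             "kolmogorov_entropy", "lyapunov_exponent", "permutation_entropy",
             "svd_entropy", "shannon_entropy", "spectral_entropy"),
    category = rep(c("linear", "nonlinear"), each = 9),
    stringsAsFactors = FALSE)
}

# evaluate one feature on one window; estimator failures and flagged
# undefined outputs surface as NA and are imputed downstream
eval_feature <- function(id, w, fs, p) {
  v <- tryCatch(suppressWarnings(switch(as.character(id),
    "1" = peak_peak(w), "2" = mean_square(w), "3" = pop_variance(w),
    "4" = hjorth_activity(w), "5" = hjorth_mobility(w),
    "6" = hjorth_complexity(w), "7" = max_psd_freq(w, fs),
    "8" = max_psd(w, fs), "9" = power_sum(w, fs),
    "10" = approximate_entropy(w, p$apen_m, p$apen_r),
    "11" = c0_complexity(w, p$c0_threshold),
    "12" = correlation_dimension(w, p$cd_m_range, p$cd_tau),
    "13" = kolmogorov_entropy(w, p$k2_m, p$k2_tau),
    "14" = lyapunov_exponent(w, p$lyap_m, p$lyap_tau, p$lyap_tmax),
    "15" = permutation_entropy(w, p$pe_m, p$pe_tau),
    "16" = svd_entropy(w, p$svd_m, p$svd_tau),
    "17" = shannon_entropy(w, p$shannon_bins),
    "18" = spectral_entropy(w, fs))),
    error = function(e) NA_real_)
  v <- as.numeric(v)[1]
  if (!is.finite(v)) NA_real_ else v
}

#' Window-level feature values for one rhythm bank
#'
#' Trims the filter edge transients, segments every channel of every rhythm
#' into sliding windows and evaluates the requested features per window.
#'
#' @param bank a `rhythm_bank` from [extract_rhythms()].
#' @param plan a [window_plan()].
#' @param feature_ids subset of 1:18.
#' @param params [feature_params()].
#' @param edge_trim samples dropped at each end before windowing; defaults
#'   to half the filter order used for the rhythm extraction.
#' @return long data.frame: subject_id, trial_id, label, rhythm, channel,
#'   feature_id, window_index, value.
#' @export
window_features <- function(bank, plan = window_plan(), feature_ids = 1:18,
                            params = feature_params(),
                            edge_trim = bank$order %/% 2) {
  tr <- bank$trial
  fs <- tr$fs
  nf <- length(feature_ids)
  rhythm <- channel <- character(0)
  widx <- integer(0)
  value <- numeric(0)
  for (bd in names(bank$band_signals)) {
    m <- bank$band_signals[[bd]]
    keep <- (edge_trim + 1L):(ncol(m) - edge_trim)
    for (ch in tr$channel_labels) {
      wins <- segment_windows(m[ch, keep], fs, plan)
      vals <- vapply(wins, function(w)
        vapply(feature_ids, eval_feature, numeric(1), w = w, fs = fs,
               p = params), numeric(nf))
      nw <- length(wins)
      rhythm <- c(rhythm, rep(bd, nf * nw))
      channel <- c(channel, rep(ch, nf * nw))
      widx <- c(widx, rep(seq_len(nw), each = nf))
      value <- c(value, as.numeric(vals))
    }
  }
  data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
             label = tr$label, rhythm = rhythm, channel = channel,
             feature_id = rep(feature_ids, length.out = length(value)),
             window_index = widx, value = value, stringsAsFactors = FALSE)
}

#' Assemble the trial x feature table
#'
#' Full pipeline from raw trials to the annotated feature matrix: rhythm
#' extraction, per-subject channel-wise z-normalization of the rhythm
#' streams, edge-trimmed sliding-window feature extraction, and the
#' window-mean reduction (the trial's feature is the mean of its window
#' values). Columns are ordered rhythm-major, then channel, then feature id;
#' with all 18 features the column count is exactly
#' `18 * n_channels * n_bands`.
#'
#' @param trials list of [trial()] objects sharing channels and fs.
#' @param bands rhythm definition, default [rhythm_bands()] at the trials'
#'   sampling rate.
#' @param plan sliding-window plan, default 4 s windows with 2 s overlap.
#' @param feature_ids features to compute (default all 18).
#' @param params [feature_params()].
#' @param order FIR order for the rhythm filters.
#' @param keep_windows retain the window-level long table (needed for the
#'   connectivity analysis).
#' @return A `feature_table`: list with `values` (trials x features matrix,
#'   undefined estimator outputs imputed with the column median and recorded
#'   in `na_mask`), `columns`, `rows`, and optionally `windows`.
#' @export
assemble <- function(trials, bands = NULL, plan = window_plan(),
                     feature_ids = 1:18, params = feature_params(),
                     order = NULL, keep_windows = FALSE) {
  stopifnot(length(trials) > 0)
  fs <- trials[[1]]$fs
  chans <- trials[[1]]$channel_labels
  for (tr in trials)
    if (!identical(tr$channel_labels, chans) || tr$fs != fs)
      stop("trial ", tr$subject_id, "/", tr$trial_id,
           " deviates in channel set or sampling rate")
  if (is.null(bands)) bands <- rhythm_bands(fs)
  if (is.null(order)) order <- 2 * round(fs)

  subjects <- vapply(trials, `[[`, character(1), "subject_id")
  long <- list()
  for (s in unique(subjects)) {
    banks <- lapply(trials[subjects == s], extract_rhythms,
                    bands = bands, order = order)
    banks <- normalize_subject(banks)
    for (b in banks)
      long[[length(long) + 1L]] <-
        window_features(b, plan, feature_ids, params)
  }
  long <- do.call(rbind, long)

  rows <- unique(data.frame(
    subject_id = vapply(trials, `[[`, character(1), "subject_id"),
    trial_id = vapply(trials, `[[`, character(1), "trial_id"),
    label = vapply(trials, `[[`, character(1), "label"),
    stringsAsFactors = FALSE))
  cat_tab <- feature_catalogue()
  columns <- expand.grid(feature_id = feature_ids, channel = chans,
                         rhythm = bands$name, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)[, 3:1]
  columns$category <- cat_tab$category[columns$feature_id]
  columns$name <- sprintf("%s_%s_f%02d", columns$rhythm, columns$channel,
                          columns$feature_id)

  # window-mean reduction into the trials x features matrix
  key_row <- match(paste(long$subject_id, long$trial_id),
                   paste(rows$subject_id, rows$trial_id))
  key_col <- match(paste(long$rhythm, long$channel, long$feature_id),
                   paste(columns$rhythm, columns$channel, columns$feature_id))
  fin <- is.finite(long$value)
  values <- tapply(long$value[fin],
                   list(factor(key_row[fin], seq_len(nrow(rows))),
                        factor(key_col[fin], seq_len(nrow(columns)))),
                   mean)
  values <- matrix(as.numeric(values), nrow(rows), nrow(columns),
                   dimnames = list(paste(rows$subject_id, rows$trial_id,
                                         sep = "/"),
                                   columns$name))
  na_mask <- !is.finite(values)
  if (any(na_mask)) {
    med <- apply(values, 2, median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in which(colSums(na_mask) > 0))
      values[na_mask[, j], j] <- med[j]
  }
  structure(list(values = values, columns = columns, rows = rows,
                 na_mask = na_mask, scaling = NULL,
                 windows = if (keep_windows) long else NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d features (%d subjects; %d imputed cells)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$rows$subject_id)), sum(x$na_mask)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Fit and apply per-column feature scaling
#'
#' Scaling statistics are fitted on `fit_rows` only (training trials) and
#' applied to every row, so held-out subjects never influence the scaling.
#' Min-max scaling maps the fitted rows into [0, 1]; held-out rows may fall
#' outside. Zero-range columns are set to 0 with a warning.
#'
#' @param table a `feature_table`.
#' @param fit_rows row indices used to fit the scaling (default: all rows).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return the table with scaled `values` and a `scaling` record.
#' @export
normalize_features <- function(table, fit_rows = seq_len(nrow(table$values)),
                               method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (!length(fit_rows)) stop("fit_rows must be nonempty")
  v <- table$values
  tr <- v[fit_rows, , drop = FALSE]
  if (method == "minmax") {
    lo <- apply(tr, 2, min); hi <- apply(tr, 2, max)
    rngs <- hi - lo
    flat <- rngs == 0
    if (any(flat))
      warning(sum(flat), " zero-range column(s) set to 0")
    rngs[flat] <- 1
    v <- sweep(sweep(v, 2, lo), 2, rngs, "/")
    v[, flat] <- 0
    table$scaling <- list(method = "minmax", lo = lo, hi = hi)
  } else {
    mu <- colMeans(tr); sdv <- apply(tr, 2, sd)
    flat <- sdv == 0 | !is.finite(sdv)
    if (any(flat))
      warning(sum(flat), " zero-range column(s) set to 0")
    sdv[flat] <- 1
    v <- sweep(sweep(v, 2, mu), 2, sdv, "/")
    v[, flat] <- 0
    table$scaling <- list(method = "zscore", mean = mu, sd = sdv)
  }
  table$values <- v
  table
}

#' Slice a feature table by channel, region, rhythm, feature or category
#'
#' Selectors combine conjunctively; annotation is preserved. Region names
#' are resolved to channel labels through the 10-20 montage partition (see
#' [channel_region()]).
#'
#' @param table a `feature_table`.
#' @param channels,regions,rhythms,feature_ids,category optional selectors.
#' @return the reduced `feature_table`.
#' @export
slice <- function(table, channels = NULL, regions = NULL, rhythms = NULL,
                  feature_ids = NULL, category = NULL) {
  keep <- rep(TRUE, nrow(table$columns))
  if (!is.null(regions)) {
    rc <- unlist(lapply(regions, region_channels,
                        labels = unique(table$columns$channel)))
    channels <- union(channels, rc)
  }
  if (!is.null(channels)) keep <- keep & table$columns$channel %in% channels
  if (!is.null(rhythms)) keep <- keep & table$columns$rhythm %in% rhythms
  if (!is.null(feature_ids)) keep <- keep & table$columns$feature_id %in% feature_ids
  if (!is.null(category)) keep <- keep & table$columns$category %in% category
  if (!any(keep)) stop("empty selection")
  table$values <- table$values[, keep, drop = FALSE]
  table$na_mask <- table$na_mask[, keep, drop = FALSE]
  table$columns <- table$columns[keep, , drop = FALSE]
  if (!is.null(table$windows)) {
    w <- table$windows
    ok <- w$channel %in% unique(table$columns$channel) &
      w$rhythm %in% unique(table$columns$rhythm) &
      w$feature_id %in% unique(table$columns$feature_id)
    table$windows <- w[ok, , drop = FALSE]
  }
  table$scaling <- NULL
  table
}

#' Scalp-region partition of 10-20/10-10 electrode labels
#'
#' Hemisphere from the label's terminal digit (odd = left, even = right,
#' z = midline); anterior/posterior from the letter prefix, with the central
#' row (`C*`, `T7/T8`) in between. Sub-region selectors exclude the cross
#' regions: quadrants drop midline and central-row electrodes, hemispheres
#' drop the midline, anterior/posterior drop the central row.
#'
#' @param labels character electrode names.
#' @return data.frame with `label`, `side`, `axis`.
#' @export
channel_region <- function(labels) {
  up <- toupper(labels)
  num <- gsub("[^0-9]", "", up)
  side <- ifelse(grepl("Z$", up), "midline",
                 ifelse(as.integer(ifelse(num == "", "0", num)) %% 2 == 1,
                        "left", "right"))
  prefix <- gsub("[0-9]|Z$", "", up)
  anterior <- c("FP", "AF", "F", "FT", "FC")
  central <- c("C", "T")
  axis <- ifelse(prefix %in% anterior, "anterior",
                 ifelse(prefix %in% central, "central", "posterior"))
  data.frame(label = labels, side = side, axis = axis,
             stringsAsFactors = FALSE)
}

#' @rdname channel_region
#' @param region one of `"left_anterior"`, `"right_anterior"`,
#'   `"left_posterior"`, `"right_posterior"`, `"left_hemisphere"`,
#'   `"right_hemisphere"`, `"anterior"`, `"posterior"`.
#' @export
region_channels <- function(labels, region) {
  reg <- channel_region(labels)
  sel <- switch(region,
    left_anterior   = reg$side == "left" & reg$axis == "anterior",
    right_anterior  = reg$side == "right" & reg$axis == "anterior",
    left_posterior  = reg$side == "left" & reg$axis == "posterior",
    right_posterior = reg$side == "right" & reg$axis == "posterior",
    left_hemisphere  = reg$side == "left",
    right_hemisphere = reg$side == "right",
    anterior  = reg$axis == "anterior",
    posterior = reg$axis == "posterior",
    stop("unknown region: ", region))
  labels[sel]
}
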