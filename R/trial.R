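#' Construct a single EEG trial
#'
#' A trial is one subject's multi-channel recording for one stimulus, with a
#' binary emotion label. The signal is stored channels x samples.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param label `"negative"` or `"positive"`.
#' @param subject_id,trial_id identifiers.
#' @param channel_labels character vector of 10-20 system electrode names,
#'   one per signal row.
#' @return An object of class `trial`.
#' @export
trial <- function(signal, fs, label, subject_id, trial_id,
                  channel_labels = rownames(signal)) {
  signal <- as.matrix(signal)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop("signal must have exactly length(channel_labels) rows")
  if (!all(is.finite(signal)))
    stop("trial signal contains non-finite samples")
  label <- match.arg(label, c("negative", "positive"))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, label = label,
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         channel_labels = as.character(channel_labels)),
    class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial %s/%s> %d channels x %d samples @ %g Hz, label = %s\n",
              x$subject_id, x$trial_id, nrow(x$signal), ncol(x$signal),
              x$fs, x$label))
  invisible(x)
}

#' @export
dim.trial <- function(x) dim(x$signal)

n_samples <- function(trial) ncol(trial$signal)

#' Split continuous valence ratings into binary emotion labels
#'
#' Ratings above the pivot are labelled positive, ratings below negative;
#' ratings exactly at the pivot fall under neither rule and are flagged for
#' exclusion.
#'
#' @param ratings numeric vector of per-trial ratings (1-9 scale).
#' @param pivot split point, default 5.
#' @return A data.frame with columns `rating`, `label` (NA where excluded)
#'   and `excluded`.
#' @export
binarize_valence <- function(ratings, pivot = 5) {
  label <- ifelse(ratings > pivot, "positive",
                  ifelse(ratings < pivot, "negative", NA_character_))
  data.frame(rating = ratings, label = label, excluded = is.na(label),
             stringsAsFactors = FALSE)
}

#' Write trials to disk as CSV files plus a TSV metadata table
#'
#' Each trial becomes one CSV (rows = samples, one named column per channel);
#' `metadata.tsv` records subject_id, trial_id, label, fs and the file path.
#'
#' @param trials list of [trial()] objects.
#' @param dir output directory (created if absent).
#' @return Invisibly, the metadata data.frame.
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(trials, function(tr) {
    fn <- sprintf("%s_%s.csv", tr$subject_id, tr$trial_id)
    write.csv(as.data.frame(t(tr$signal)), file.path(dir, fn),
              row.names = FALSE)
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               label = tr$label, fs = tr$fs, path = fn,
               stringsAsFactors = FALSE)
  }))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(meta)
}

#' Read trials written by [write_trials()]
#'
#' @param dir directory containing per-trial CSV files and `metadata.tsv`.
#' @return list of [trial()] objects.
#' @export
read_trials <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("no metadata.tsv in ", dir)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(dir, meta$path[i])
    if (!file.exists(f))
      stop("metadata row without file: ", meta$path[i])
    m <- as.matrix(read.csv(f, check.names = FALSE))
    trial(t(m), fs = meta$fs[i], label = meta$label[i],
          subject_id = meta$subject_id[i], trial_id = meta$trial_id[i],
          channel_labels = colnames(m))
  })
}
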