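#' Channel-correlation matrix from window-level feature values
#'
#' For one subject, one emotion group and one (feature, rhythm), the
#' observation unit is the sliding window: each channel contributes the
#' sequence of its window-level feature values pooled across the group's
#' trials, and the matrix holds the Pearson correlation of every channel
#' pair. A channel whose sequence has zero variance is flagged undefined
#' (NA row/column) and excluded from summaries.
#'
#' @param windows long window-level table (see [window_features()] or
#'   `assemble(..., keep_windows = TRUE)$windows`), already restricted to
#'   one subject, group, feature and rhythm.
#' @return symmetric correlation matrix with unit diagonal, channels in
#'   label order.
#' @export
channel_correlation <- function(windows) {
  chans <- unique(windows$channel)
  obs <- sapply(chans, function(ch) {
    w <- windows[windows$channel == ch, ]
    w <- w[order(w$trial_id, w$window_index), ]
    w$value
  })
  if (nrow(obs) < 10)
    warning("fewer than 10 window observations per channel")
  sds <- apply(obs, 2, sd)
  m <- suppressWarnings(cor(obs))
  m[sds == 0, ] <- NA; m[, sds == 0] <- NA
  diag(m) <- ifelse(sds == 0, NA, 1)
  dimnames(m) <- list(chans, chans)
  m
}

#' Per-subject, per-group channel-correlation matrices for one feature
#'
#' Builds the negative-group and positive-group correlation matrix for every
#' subject from the window-level values of one (feature, rhythm), plus the
#' group-averaged matrices.
#'
#' @param table a `feature_table` assembled with `keep_windows = TRUE`.
#' @param feature_id feature (1-18).
#' @param rhythm band name.
#' @return A `group_connectivity`: `matrices[[subject]][[group]]`,
#'   `group_means[[group]]`, and the slice descriptor.
#' @export
group_connectivity <- function(table, feature_id, rhythm) {
  w <- table$windows
  if (is.null(w))
    stop("feature table lacks window-level values; assemble with keep_windows = TRUE")
  w <- w[w$feature_id == feature_id & w$rhythm == rhythm, ]
  if (!nrow(w)) stop("no window values for this feature/rhythm")
  subjects <- unique(w$subject_id)
  mats <- lapply(stats::setNames(subjects, subjects), function(s)
    lapply(stats::setNames(c("negative", "positive"),
                           c("negative", "positive")), function(g) {
      ws <- w[w$subject_id == s & w$label == g, ]
      if (!nrow(ws)) return(NULL)
      suppressWarnings(channel_correlation(ws))
    }))
  avg <- function(g) {
    ms <- Filter(Negate(is.null), lapply(mats, `[[`, g))
    Reduce(`+`, ms) / length(ms)
  }
  structure(list(matrices = mats,
                 group_means = list(negative = avg("negative"),
                                    positive = avg("positive")),
                 feature_id = feature_id, rhythm = rhythm),
            class = "group_connectivity")
}

#' Mean global correlation of a channel-correlation matrix
#'
#' Mean of the strictly-upper-triangle entries (flagged NA entries are
#' excluded).
#'
#' @param m correlation matrix.
#' @export
mean_global_correlation <- function(m) {
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Binarize a correlation matrix into a connection network
#'
#' An edge exists where the signed correlation is strictly greater than the
#' threshold; the diagonal is forced to zero, so a channel never connects to
#' itself. Negative correlations never produce edges at positive thresholds.
#'
#' @param m correlation matrix.
#' @param threshold value in (0, 1).
#' @return A `binary_network`: 0/1 adjacency matrix with attribute
#'   `threshold`.
#' @export
binarize <- function(m, threshold) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  adj <- (m > threshold) * 1
  adj[is.na(adj)] <- 0
  diag(adj) <- 0
  structure(adj, threshold = threshold, class = c("binary_network", "matrix"))
}

#' Clustering coefficients of a binary connection network
#'
#' Per node: twice the number of triangles through the node divided by
#' `degree * (degree - 1)`; nodes of degree < 2 score 0. The global value is
#' the mean over all nodes.
#'
#' @param network adjacency matrix (0/1, symmetric, zero diagonal), e.g.
#'   from [binarize()].
#' @return list with `per_node` (named by channel) and `global`.
#' @export
clustering_coefficients <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(unclass(network) != 0,
                                           mode = "undirected")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- rownames(network)
  list(per_node = cc, global = mean(cc))
}

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Threshold scan of group differences in global clustering
#'
#' For every threshold on the grid, binarizes each subject's group
#' correlation matrices, computes the global clustering coefficient per
#' group, and runs a paired t-test across subjects. Reports the per-point
#' p-values and the maximal contiguous threshold ranges with p < 0.05
#' (formatted `lo~hi`). Thresholds where every network is empty in both
#' groups are skipped.
#'
#' @param conn a `group_connectivity`.
#' @param grid threshold grid, default 0.01 to 0.99 step 0.01.
#' @param alpha significance level, default 0.05.
#' @return A `threshold_scan`: `scan` (per-threshold table) and
#'   `significant_ranges`.
#' @export
threshold_scan <- function(conn, grid = seq(0.01, 0.99, by = 0.01),
                           alpha = 0.05) {
  subjects <- names(conn$matrices)
  both <- subjects[vapply(subjects, function(s)
    !is.null(conn$matrices[[s]]$negative) &&
      !is.null(conn$matrices[[s]]$positive), logical(1))]
  if (length(both) < 3) stop("need >= 3 subjects observed in both groups")
  rows <- lapply(grid, function(th) {
    cn <- vapply(both, function(s)
      clustering_coefficients(binarize(conn$matrices[[s]]$negative, th))$global,
      numeric(1))
    cp <- vapply(both, function(s)
      clustering_coefficients(binarize(conn$matrices[[s]]$positive, th))$global,
      numeric(1))
    if (all(cn == 0) && all(cp == 0))
      return(data.frame(threshold = th, mean_negative = 0, mean_positive = 0,
                        t = NA_real_, p = NA_real_, skipped = TRUE))
    d <- cn - cp
    if (var(d) == 0)
      return(data.frame(threshold = th, mean_negative = mean(cn),
                        mean_positive = mean(cp), t = NA_real_, p = NA_real_,
                        skipped = FALSE))
    tt <- t.test(cn, cp, paired = TRUE)
    data.frame(threshold = th, mean_negative = mean(cn),
               mean_positive = mean(cp), t = unname(tt$statistic),
               p = tt$p.value, skipped = FALSE)
  })
  scan <- do.call(rbind, rows)
  sig <- !is.na(scan$p) & scan$p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ranges <- data.frame(from = grid[starts[r$values]],
                       to = grid[ends[r$values]])
  ranges$scope <- sprintf("%.2f~%.2f", ranges$from, ranges$to)
  structure(list(scan = scan, significant_ranges = ranges,
                 feature_id = conn$feature_id, rhythm = conn$rhythm,
                 alpha = alpha),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan f%02d/%s> significant scope (p < %.2f): %s\n",
              x$feature_id, x$rhythm, x$alpha,
              if (nrow(x$significant_ranges))
                paste(x$significant_ranges$scope, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Correlation structure of the 18 feature types
#'
#' Pearson correlation of every feature-type pair across (trial, channel)
#' observations within one rhythm, using the trial-level feature values.
#'
#' @param table a `feature_table` covering the requested features.
#' @param rhythm band name.
#' @return symmetric correlation matrix (feature ids as dimnames); constant
#'   features are flagged NA.
#' @export
feature_intercorrelation <- function(table, rhythm) {
  cols <- table$columns
  fids <- sort(unique(cols$feature_id))
  chans <- unique(cols$channel)
  obs <- sapply(fids, function(f) {
    idx <- which(cols$rhythm == rhythm & cols$feature_id == f)
    idx <- idx[match(chans, cols$channel[idx])]
    as.numeric(table$values[, idx])
  })
  sds <- apply(obs, 2, sd)
  m <- suppressWarnings(cor(obs))
  m[sds == 0, ] <- NA; m[, sds == 0] <- NA
  diag(m) <- ifelse(sds == 0, NA, 1)
  dimnames(m) <- list(paste0("f", fids), paste0("f", fids))
  m
}

#' Paired group t-tests with star coding
#'
#' Paired t-test of per-subject summaries between the negative and positive
#' groups, one test per grouping cell (e.g. per feature and rhythm), with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param df data.frame with columns `subject_id`, `group` (negative /
#'   positive), `value`, plus optional grouping columns (e.g. `feature_id`,
#'   `rhythm`).
#' @return data.frame with one row per cell: t, p, stars (zero-variance
#'   differences flagged NA).
#' @export
group_ttests <- function(df) {
  idcols <- setdiff(names(df), c("subject_id", "group", "value"))
  key <- if (length(idcols)) interaction(df[idcols], drop = TRUE)
         else factor(rep("all", nrow(df)))
  cells <- split(df, key)
  out <- lapply(cells, function(cell) {
    wide <- merge(cell[cell$group == "negative", c("subject_id", "value")],
                  cell[cell$group == "positive", c("subject_id", "value")],
                  by = "subject_id", suffixes = c("_neg", "_pos"))
    d <- wide$value_neg - wide$value_pos
    base <- cell[1, idcols, drop = FALSE]
    if (length(d) < 2 || var(d) == 0)
      return(cbind(base, data.frame(t = NA_real_,
                                    p = if (all(d == 0)) 1 else NA_real_,
                                    n = length(d))))
    tt <- t.test(wide$value_neg, wide$value_pos, paired = TRUE)
    cbind(base, data.frame(t = unname(tt$statistic), p = tt$p.value,
                           n = length(d)))
  })
  res <- do.call(rbind, out)
  res$stars <- p_stars(res$p)
  rownames(res) <- NULL
  res
}
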