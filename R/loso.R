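# orient e1071 decision values so larger = more "positive"
positive_score <- function(fit, newdata) {
  pr <- predict(fit, newdata, decision.values = TRUE)
  d <- as.numeric(attr(pr, "decision.values"))
  nm <- colnames(attr(pr, "decision.values"))[1]
  if (identical(nm, "positive/negative")) d else -d
}

# re-impute masked cells using medians of the training rows only
impute_from_train <- function(table, train_rows) {
  v <- table$values
  if (!any(table$na_mask)) return(table)
  for (j in which(colSums(table$na_mask) > 0)) {
    tr_ok <- train_rows[!table$na_mask[train_rows, j]]
    med <- if (length(tr_ok)) median(v[tr_ok, j]) else 0
    v[table$na_mask[, j], j] <- med
  }
  table$values <- v
  table
}

#' Leave-one-subject-out evaluation with a linear SVM
#'
#' One fold per subject: feature scaling, missing-value imputation, feature
#' selection and the classifier are all fitted on the remaining subjects'
#' trials only, then evaluated on the held-out subject, so no held-out
#' information can enter the fit. Reports per-subject accuracies, their
#' mean/sd, and the AUC of the ROC built from the pooled held-out decision
#' values.
#'
#' @param table a `feature_table`.
#' @param selector `NULL` (no selection) or one of `"chi2"`, `"mi"`, `"f"`,
#'   `"rfe"`, `"l1"`.
#' @param n_select number of features kept by filter/rfe selectors.
#' @param cost linear SVM cost parameter, default 1.
#' @param scale_method per-fold feature scaling, default `"minmax"`.
#' @param ... extra selector arguments (e.g. `C` for `"l1"`, `k` for
#'   `"rfe"`).
#' @return A `loso_result`.
#' @export
loso_run <- function(table, selector = NULL, n_select = NULL, cost = 1,
                     scale_method = "minmax", ...) {
  subjects <- unique(table$rows$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects for LOSO")
  y_all <- factor(table$rows$label, levels = c("negative", "positive"))
  pooled <- list()
  per <- data.frame(subject_id = subjects, n_test = NA_integer_,
                    accuracy = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(subjects)) {
    test <- which(table$rows$subject_id == subjects[i])
    train <- setdiff(seq_len(nrow(table$values)), test)
    if (length(unique(y_all[test])) < 2) per$flagged[i] <- TRUE
    tab <- impute_from_train(table, train)
    tab <- suppressWarnings(
      normalize_features(tab, fit_rows = train, method = scale_method))
    x <- tab$values
    if (!is.null(selector)) {
      ns <- if (is.null(n_select)) ncol(x) else min(n_select, ncol(x))
      if (identical(selector, "rfe")) ns <- min(ns, ncol(x) - 1)
      sel <- select_features(x[train, , drop = FALSE], y_all[train],
                             method = selector, n_select = ns, ...)
      keep <- if (length(sel$selected)) sel$selected else sel$order[1]
      x <- x[, keep, drop = FALSE]
    }
    fit <- e1071::svm(x[train, , drop = FALSE], y_all[train],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, x[test, , drop = FALSE])
    score <- positive_score(fit, x[test, , drop = FALSE])
    per$n_test[i] <- length(test)
    per$accuracy[i] <- mean(pred == y_all[test])
    pooled[[i]] <- data.frame(subject_id = subjects[i],
                              label = as.character(y_all[test]),
                              score = score,
                              pred = as.character(pred),
                              stringsAsFactors = FALSE)
  }
  if (any(per$flagged))
    warning("fold(s) with a single trial class excluded from the mean: ",
            paste(per$subject_id[per$flagged], collapse = ", "))
  pooled <- do.call(rbind, pooled)
  ok <- !per$flagged
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = pooled$label, predictor = pooled$score,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
  structure(list(per_subject = per,
                 mean_accuracy = mean(per$accuracy[ok]),
                 sd_accuracy = sd(per$accuracy[ok]),
                 pooled = pooled, auc = auc,
                 config = list(selector = selector, n_select = n_select,
                               cost = cost, scale_method = scale_method,
                               extra = list(...))),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d folds | mean accuracy %.4f (sd %.4f) | AUC %.4f\n",
              nrow(x$per_subject), x$mean_accuracy, x$sd_accuracy, x$auc))
  if (!is.null(x$config$selector))
    cat("  selector:", x$config$selector,
        if (!is.null(x$config$n_select)) paste0("(n_select = ", x$config$n_select, ")"),
        "\n")
  invisible(x)
}

#' @export
summary.loso_result <- function(object, ...) {
  print(object)
  print(object$per_subject)
  invisible(object)
}

#' ROC curve points from the pooled held-out decision values
#'
#' @param result a `loso_result`.
#' @return data.frame with `fpr` and `tpr` (threshold-sorted).
#' @export
roc_points <- function(result) {
  r <- pROC::roc(response = result$pooled$label,
                 predictor = result$pooled$score,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}

#' Sweep the number of selected features (or the L1 penalty grid)
#'
#' Runs one LOSO evaluation per grid point. For filter and RFE selectors the
#' grid is the number of retained features; for the `"l1"` selector it is
#' the grid of C values.
#'
#' @param table a `feature_table`.
#' @param selector selection method (see [loso_run()]).
#' @param grid numeric grid.
#' @param ... forwarded to [loso_run()].
#' @return A `loso_sweep`: per-point results plus the best setting by mean
#'   accuracy.
#' @export
sweep_selection_size <- function(table, selector, grid, ...) {
  results <- lapply(grid, function(g) {
    if (identical(selector, "l1")) loso_run(table, selector, C = g, ...)
    else loso_run(table, selector, n_select = g, ...)
  })
  acc <- vapply(results, `[[`, numeric(1), "mean_accuracy")
  best <- which.max(acc)
  structure(list(grid = grid, results = results, mean_accuracy = acc,
                 best_index = best, best_setting = grid[best],
                 best = results[[best]], selector = selector),
            class = "loso_sweep")
}

#' @export
print.loso_sweep <- function(x, ...) {
  cat(sprintf("<loso_sweep %s> %d settings | best %.4f at %g\n",
              x$selector, length(x$grid),
              x$mean_accuracy[x$best_index], x$best_setting))
  invisible(x)
}

#' Searchlight evaluation over manually chosen feature subsets
#'
#' Re-runs the LOSO evaluation independently on every slice along one axis:
#' per channel, per scalp region, per rhythm (the four bands plus their
#' concatenation), per (feature, rhythm) pair, or per feature category
#' (linear/nonlinear). Slices are ranked by mean accuracy and the top sixth
#' is marked.
#'
#' @param table a `feature_table`.
#' @param axis `"channel"`, `"region"`, `"rhythm"`, `"feature"` or
#'   `"category"`.
#' @param ... forwarded to [loso_run()].
#' @return A `searchlight_report`: ranked data.frame (`report`) plus the
#'   underlying `loso_result`s.
#' @export
searchlight <- function(table, axis = c("channel", "region", "rhythm",
                                        "feature", "category"), ...) {
  axis <- match.arg(axis)
  chans <- unique(table$columns$channel)
  rhys <- unique(table$columns$rhythm)
  slices <- switch(axis,
    channel = lapply(stats::setNames(chans, chans), function(ch)
      list(channels = ch)),
    region = {
      regs <- c("left_anterior", "right_anterior", "left_posterior",
                "right_posterior", "left_hemisphere", "right_hemisphere",
                "anterior", "posterior")
      lapply(stats::setNames(regs, regs), function(r) list(regions = r))
    },
    rhythm = c(lapply(stats::setNames(rhys, rhys), function(r)
        list(rhythms = r)),
      list(all = list(rhythms = rhys))),
    feature = {
      combos <- expand.grid(feature_id = unique(table$columns$feature_id),
                            rhythm = rhys, stringsAsFactors = FALSE)
      out <- lapply(seq_len(nrow(combos)), function(i)
        list(feature_ids = combos$feature_id[i], rhythms = combos$rhythm[i]))
      names(out) <- sprintf("f%02d_%s", combos$feature_id, combos$rhythm)
      out
    },
    category = lapply(stats::setNames(unique(table$columns$category),
                                      unique(table$columns$category)),
                      function(cc) list(category = cc)))
  results <- list()
  for (nm in names(slices)) {
    sub <- tryCatch(do.call(slice, c(list(table = table), slices[[nm]])),
                    error = function(e) NULL)
    if (is.null(sub)) { warning("empty slice skipped: ", nm); next }
    results[[nm]] <- loso_run(sub, ...)
  }
  rep <- data.frame(
    slice = names(results),
    n_features = vapply(results, function(r) NA_integer_, integer(1)),
    mean_accuracy = vapply(results, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(results, `[[`, numeric(1), "sd_accuracy"),
    auc = vapply(results, `[[`, numeric(1), "auc"),
    stringsAsFactors = FALSE)
  rep$n_features <- vapply(names(results), function(nm)
    ncol(do.call(slice, c(list(table = table), slices[[nm]]))$values),
    integer(1))
  rep <- rep[order(-rep$mean_accuracy, rep$slice), ]
  rep$rank <- seq_len(nrow(rep))
  rep$top_sixth <- rep$rank <= ceiling(nrow(rep) / 6)
  rownames(rep) <- NULL
  structure(list(axis = axis, report = rep, results = results),
            class = "searchlight_report")
}

#' @export
print.searchlight_report <- function(x, ...) {
  cat(sprintf("<searchlight_report axis=%s> %d slices\n", x$axis,
              nrow(x$report)))
  print(head(x$report, 10))
  invisible(x)
}

#' Pairwise one-way ANOVA against the best-performing method
#'
#' Compares each method's per-subject accuracy list with the best method's
#' by a one-way ANOVA and reports the p-values.
#'
#' @param results named list of `loso_result`s with identical fold sets.
#' @return data.frame with method, mean accuracy, and `p_vs_best` (NA for
#'   the best method itself; flagged NA when both variances are zero).
#' @export
compare_methods <- function(results) {
  stopifnot(length(results) >= 2)
  if (is.null(names(results)))
    names(results) <- paste0("method", seq_along(results))
  accs <- lapply(results, function(r) r$per_subject$accuracy)
  if (length(unique(vapply(accs, length, integer(1)))) != 1)
    stop("per-subject accuracy lists differ in length")
  means <- vapply(accs, mean, numeric(1))
  best <- which.max(means)
  p <- vapply(seq_along(accs), function(i) {
    if (i == best) return(NA_real_)
    v <- c(accs[[best]], accs[[i]])
    g <- factor(rep(c("best", "other"), each = length(accs[[i]])))
    if (var(v) == 0) return(1)               # identical lists
    if (var(accs[[best]]) == 0 && var(accs[[i]]) == 0)
      return(0)                              # degenerate: separated constants
    tab <- anova(aov(v ~ g))
    pv <- tab$`Pr(>F)`[1]
    if (!is.finite(pv)) NA_real_ else pv
  }, numeric(1))
  data.frame(method = names(results), mean_accuracy = means,
             best = seq_along(accs) == best, p_vs_best = p,
             row.names = NULL, stringsAsFactors = FALSE)
}
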