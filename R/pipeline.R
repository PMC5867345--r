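#' Declarative configuration for an end-to-end pipeline run
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param generator a [generator_config()] (used when no `trials_dir` is
#'   given).
#' @param trials_dir optional directory of trials written by
#'   [write_trials()]; overrides the generator.
#' @param window a [window_plan()].
#' @param feature_ids features to extract (default all 18).
#' @param params [feature_params()].
#' @param selector,n_select,C classifier-side selection settings
#'   (see [loso_run()]); `selector = NULL` disables selection.
#' @param cost linear SVM cost.
#' @param searchlight_axes character vector of [searchlight()] axes to run
#'   (default none).
#' @param network optional list with `feature_id`, `rhythm` and `grid` for
#'   the connectivity threshold scan (default none).
#' @param seed integer seed governing the generator.
#' @export
run_config <- function(generator = generator_config(),
                       trials_dir = NULL,
                       window = window_plan(),
                       feature_ids = 1:18,
                       params = feature_params(),
                       selector = NULL, n_select = NULL, C = 0.1,
                       cost = 1,
                       searchlight_axes = character(0),
                       network = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  if (!is.null(network)) {
    unknown <- setdiff(names(network), c("feature_id", "rhythm", "grid"))
    if (length(unknown))
      stop("unknown network config key(s): ", paste(unknown, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Generate (or read) trials, extract rhythm-resolved window features,
#' assemble the feature table, run the LOSO evaluation (optionally with
#' feature selection), and, if configured, the searchlight reports and the
#' channel-connectivity threshold scan. With a fixed seed the whole bundle
#' is reproducible.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the feature table, LOSO
#'   report and scan report are written there as TSV/JSON together with the
#'   serialized configuration.
#' @return list with `table`, `loso`, and optionally `searchlight` and
#'   `network` entries.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  trials <- if (!is.null(config$trials_dir)) read_trials(config$trials_dir)
  else {
    gen <- config$generator
    gen$seed <- config$seed
    generate_dataset(gen)
  }
  table <- assemble(trials, plan = config$window,
                    feature_ids = config$feature_ids,
                    params = config$params,
                    keep_windows = !is.null(config$network))
  loso <- if (identical(config$selector, "l1"))
    loso_run(table, selector = "l1", C = config$C, cost = config$cost)
  else
    loso_run(table, selector = config$selector, n_select = config$n_select,
             cost = config$cost)
  out <- list(table = table, loso = loso)
  if (length(config$searchlight_axes))
    out$searchlight <- lapply(
      stats::setNames(config$searchlight_axes, config$searchlight_axes),
      function(ax) searchlight(table, ax))
  if (!is.null(config$network)) {
    conn <- group_connectivity(table, config$network$feature_id,
                               config$network$rhythm)
    grid <- if (is.null(config$network$grid)) seq(0.01, 0.99, 0.01)
            else config$network$grid
    out$network <- list(connectivity = conn,
                        scan = threshold_scan(conn, grid))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(cbind(out$table$rows, out$table$values),
                file.path(out_dir, "features.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(
      per_subject = out$loso$per_subject,
      mean_accuracy = out$loso$mean_accuracy,
      sd_accuracy = out$loso$sd_accuracy,
      auc = out$loso$auc),
      file.path(out_dir, "loso.json"), auto_unbox = TRUE, digits = NA)
    cfg <- config
    cfg$generator <- unclass(cfg$generator)
    cfg$params <- NULL
    jsonlite::write_json(lapply(unclass(cfg), function(z)
      if (is.atomic(z) || is.null(z)) z else unclass(z)),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, null = "null",
      digits = NA, force = TRUE)
    if (!is.null(out$network))
      write.table(out$network$scan$scan, file.path(out_dir, "scan.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
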