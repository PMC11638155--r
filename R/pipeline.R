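#' End-to-end pipeline configuration
#'
#' A single object describing one full run: cohort source, graph
#' construction, split fractions, per-model training grids and the master
#' seed. The master seed fans out to per-stage seeds by fixed offsets
#' (cohort +1, split +2, training +3), so any stage can be re-run in
#' isolation with the same draw.
#'
#' @param cohort a [cohort_config()] for synthetic generation, used when
#'   `cohort_csv` is `NULL`.
#' @param cohort_csv path to an existing cohort CSV to load instead of
#'   simulating.
#' @param percentile,bandwidth graph sparsification settings (see
#'   [threshold_edges()], [rbf_similarity()]).
#' @param fractions train/val/test fractions (see [stratified_split()]).
#' @param grid hyperparameter grid shared by the three models.
#' @param epochs training epochs per grid point.
#' @param models which of MLP/GCN/GAT to run.
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cohort = default_cohort_config(),
                            cohort_csv = NULL,
                            percentile = 80, bandwidth = "median",
                            fractions = c(train = 0.556, val = 0.140,
                                          test = 0.304),
                            grid = default_grid(), epochs = 100L,
                            models = c("MLP", "GCN", "GAT"),
                            seed = 0L) {
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop_cohortgnn("cohort CSV '%s' does not exist", cohort_csv,
                   class = "cohortgnn_config_error")
  structure(list(cohort = cohort, cohort_csv = cohort_csv,
                 percentile = percentile, bandwidth = bandwidth,
                 fractions = fractions, grid = grid,
                 epochs = as.integer(epochs),
                 models = match.arg(models, c("MLP", "GCN", "GAT"),
                                    several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## Next unused versioned directory: dir, dir-1, dir-2, ...
versioned_dir <- function(dir) {
  if (!dir.exists(dir) || length(list.files(dir, all.files = FALSE)) == 0L)
    return(dir)
  i <- 1L
  while (dir.exists(sprintf("%s-%d", dir, i)) &&
         length(list.files(sprintf("%s-%d", dir, i))) > 0L) i <- i + 1L
  sprintf("%s-%d", dir, i)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full classification pipeline
#'
#' Executes the stages in order: cohort (simulate or load), preprocessing
#' (11-feature design matrix), population graph, stratified split, grid
#' search training of each requested model, and test-set evaluation. Writes
#' all artifacts under `out_dir` (versioned if a previous non-identical run
#' left files there) and logs every defaulted design value actually used
#' (bandwidth, threshold, split sizes). Bit-reproducible as a function of
#' (config, seed).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` skips writing artifacts.
#' @return (invisibly) a list with the cohort, features, graph, summary,
#'   split, per-model `fits` (grid results + test report) and the
#'   `comparison` data frame of test metrics.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- run_stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      pipeline_log("cohort", "loading %s", config$cohort_csv)
      read_cohort_csv(config$cohort_csv)
    } else {
      cfg <- config$cohort
      cfg$seed <- seed + 1L
      pipeline_log("cohort", "simulating %d group(s), seed %d",
                   length(cfg$groups), cfg$seed)
      generate_cohort(cfg)
    }
  })
  pipeline_log("cohort", "%d subjects (%s)", nrow(cohort),
               paste(sprintf("%s=%d", DIAGNOSIS_LEVELS,
                             table(factor(cohort$diagnosis,
                                          levels = DIAGNOSIS_LEVELS))),
                     collapse = ", "))

  features <- run_stage("preprocess", build_feature_matrix(cohort))
  graph <- run_stage("graph", build_graph(features, config$percentile,
                                          config$bandwidth))
  summ <- graph_summary(graph)
  pipeline_log("graph",
               "bandwidth %.4f, threshold %.4f, %d edge entries, avg degree %.1f, %d isolated",
               graph$bandwidth, graph$threshold, summ$n_edge_entries,
               summ$avg_degree, summ$n_isolated)

  split <- run_stage("split",
                     stratified_split(cohort, config$fractions,
                                      seed = seed + 2L))
  pipeline_log("split", "%s",
               paste(sprintf("%s=%d", levels(split$partition),
                             table(split$partition)), collapse = ", "))

  fits <- list()
  for (kind in config$models) {
    fits[[kind]] <- run_stage(kind, {
      spec <- model_spec(kind, in_features = ncol(features$values))
      ei <- if (kind == "MLP") NULL else graph$edge_index
      gs <- grid_search(spec, features, cohort$diagnosis, split,
                        grid = config$grid, epochs = config$epochs,
                        seed = seed + 3L, edge_index = ei)
      pipeline_log(kind, "best lr %.4g, wd %.5g (val accuracy %.2f%%)",
                   gs$best_config$learning_rate,
                   gs$best_config$weight_decay,
                   100 * gs$results$val_accuracy[
                     which(gs$results$learning_rate ==
                             gs$best_config$learning_rate &
                           gs$results$weight_decay ==
                             gs$best_config$weight_decay)])
      report <- evaluate(gs$best_params, features, cohort$diagnosis, split,
                         partition = "test", edge_index = ei)
      pipeline_log(kind, "test accuracy %.2f%%, wPPV %.2f%%, wrecall %.2f%%",
                   100 * report$accuracy, 100 * report$weighted_ppv,
                   100 * report$weighted_recall)
      list(spec = spec, grid = gs, report = report)
    })
  }

  comparison <- data.frame(
    model = names(fits),
    accuracy = vapply(fits, function(f) f$report$accuracy, numeric(1)),
    weighted_ppv = vapply(fits, function(f) f$report$weighted_ppv, numeric(1)),
    weighted_recall = vapply(fits, function(f) f$report$weighted_recall,
                             numeric(1)),
    learning_rate = vapply(fits, function(f) f$grid$best_config$learning_rate,
                           numeric(1)),
    weight_decay = vapply(fits, function(f) f$grid$best_config$weight_decay,
                          numeric(1)),
    row.names = NULL)

  result <- list(cohort = cohort, features = features, graph = graph,
                 summary = summ, split = split, fits = fits,
                 comparison = comparison, seed = seed)

  if (!is.null(out_dir)) {
    out_dir <- versioned_dir(out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pipeline_log("write", "artifacts -> %s", out_dir)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_feature_csv(features, file.path(out_dir, "features.csv"))
    write_edge_tsv(graph, file.path(out_dir, "edges.tsv"),
                   ids = features$row_ids)
    jsonlite::write_json(unclass(summ),
                         file.path(out_dir, "graph_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_split_csv(split, file.path(out_dir, "splits.csv"))
    for (kind in names(fits)) {
      write_eval_report(fits[[kind]]$report,
                        file.path(out_dir, sprintf("eval_%s.json", kind)))
      write_history_csv(fits[[kind]]$grid$best_history,
                        file.path(out_dir, sprintf("history_%s.csv", kind)))
    }
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    result$out_dir <- out_dir
  }
  invisible(result)
}
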