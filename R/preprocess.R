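NUMERIC_FEATURES <- c("age", "education", "mmse", "moca", "fab", "hdrs")
BINARY_FEATURES <- c("comorbidity", "treatment", "rehabilitation")

#' Standardise numeric columns to zero mean and unit variance
#'
#' Uses the sample standard deviation (n - 1 denominator). A constant column
#' is a degenerate input and raises an error rather than dividing by zero.
#'
#' @param table a `cohort_table` or data frame.
#' @param columns numeric column names; default the six numeric features
#'   (age, education, mmse, moca, fab, hdrs).
#' @param scaler optionally, a previously fitted scaler (as returned in
#'   `$scaler`) to apply instead of refitting, for reproducible transforms.
#' @return list with `values` (n x length(columns) matrix) and `scaler`
#'   (per-column `mean` and `sd`).
#' @export
standardize_numeric <- function(table, columns = NUMERIC_FEATURES,
                                scaler = NULL) {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0L)
    stop_cohortgnn("missing numeric columns: %s",
                   paste(missing_cols, collapse = ", "),
                   class = "cohortgnn_schema_error")
  x <- as.matrix(as.data.frame(table)[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  if (is.null(scaler)) {
    if (nrow(x) < 2L)
      stop_cohortgnn("standardisation needs at least 2 rows",
                     class = "cohortgnn_degenerate_error")
    mu <- colMeans(x)
    sdev <- apply(x, 2, stats::sd)
    if (any(sdev == 0))
      stop_cohortgnn("constant column(s) cannot be standardised: %s",
                     paste(columns[sdev == 0], collapse = ", "),
                     class = "cohortgnn_degenerate_error")
    scaler <- list(mean = mu, sd = sdev)
  }
  values <- sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
  dimnames(values) <- list(NULL, columns)
  list(values = values, scaler = scaler)
}

#' One-hot encode categorical columns
#'
#' Sex expands to two indicator columns (`sex_F`, `sex_M`); each binary care
#' flag emits a single 0/1 indicator. The returned manifest maps every raw
#' column to the output column(s) it produced.
#'
#' @param table a `cohort_table` or data frame.
#' @param columns categorical columns; default `sex` plus the three flags.
#' @return list with `values` (indicator matrix) and `manifest`.
#' @export
one_hot_encode <- function(table, columns = c("sex", BINARY_FEATURES)) {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0L)
    stop_cohortgnn("missing categorical columns: %s",
                   paste(missing_cols, collapse = ", "),
                   class = "cohortgnn_schema_error")
  n <- nrow(table)
  blocks <- list(); manifest <- list()
  for (col in columns) {
    v <- as.data.frame(table)[[col]]
    if (col == "sex") {
      bad <- setdiff(unique(v), c("F", "M"))
      if (length(bad) > 0L)
        stop_cohortgnn("unseen sex level(s): %s", paste(bad, collapse = ", "),
                       class = "cohortgnn_schema_error")
      m <- cbind(sex_F = as.numeric(v == "F"), sex_M = as.numeric(v == "M"))
      manifest[[col]] <- colnames(m)
    } else {
      if (!all(v %in% c(0L, 1L)))
        stop_cohortgnn("column '%s' must be binary 0/1", col,
                       class = "cohortgnn_schema_error")
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, col))
      manifest[[col]] <- col
    }
    blocks[[col]] <- m
  }
  values <- do.call(cbind, blocks)
  if (is.null(values)) values <- matrix(0, n, 0)
  rownames(values) <- NULL
  list(values = values, manifest = manifest)
}

#' Build the full 11-column design matrix
#'
#' Concatenates the standardised numeric block and the one-hot block in the
#' fixed order age, education, mmse, moca, fab, hdrs, sex_F, sex_M,
#' comorbidity, treatment, rehabilitation; row order and ids follow the
#' source table.
#'
#' @param table a `cohort_table`.
#' @param scaler optional pre-fitted scaler passed to [standardize_numeric()].
#' @return a `feature_matrix`: list with `values` (n x 11), `column_names`,
#'   `row_ids`, `encoding_manifest`, and the fitted `scaler`.
#' @export
build_feature_matrix <- function(table, scaler = NULL) {
  num <- standardize_numeric(table, scaler = scaler)
  cat_ <- one_hot_encode(table)
  values <- cbind(num$values, cat_$values)
  manifest <- c(as.list(stats::setNames(NUMERIC_FEATURES, NUMERIC_FEATURES)),
                cat_$manifest)
  structure(list(values = values,
                 column_names = colnames(values),
                 row_ids = as.data.frame(table)$id,
                 encoding_manifest = manifest,
                 scaler = num$scaler),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s)\n", nrow(x$values),
              ncol(x$values), paste(x$column_names, collapse = ", ")))
  invisible(x)
}

#' Class- and sex-stratified train/validation/test split
#'
#' Within every diagnosis-by-sex stratum, partition counts follow
#' largest-remainder rounding of `fractions * stratum size`, so each
#' partition's class and sex composition tracks the cohort's within one
#' subject per stratum. Assignment within a stratum is a seeded random
#' permutation. The default fractions 0.556/0.140/0.304 reproduce subset
#' sizes of 119/30/65 on the default 214-subject cohort.
#'
#' @param table a `cohort_table`.
#' @param fractions length-3 non-negative vector summing to 1
#'   (train, val, test).
#' @param seed integer seed.
#' @return a `split_assignment` data frame with columns `id`, `partition`
#'   (factor train/val/test), carrying `fractions` and `seed` attributes.
#' @export
stratified_split <- function(table,
                             fractions = c(train = 0.556, val = 0.140, test = 0.304),
                             seed = 0L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop_cohortgnn("fractions must be 3 non-negative values summing to 1",
                   class = "cohortgnn_config_error")
  parts <- c("train", "val", "test")
  tab <- as.data.frame(table)
  stratum <- interaction(factor(tab$diagnosis, levels = DIAGNOSIS_LEVELS),
                         tab$sex, drop = TRUE)
  partition <- character(nrow(tab))
  n_active <- sum(fractions > 0)
  local_seed(seed, {
    for (s in levels(stratum)) {
      idx <- which(stratum == s)
      counts <- largest_remainder(fractions, length(idx))
      if (length(idx) < n_active)
        warning(sprintf(
          "stratum '%s' has %d subject(s), fewer than the %d non-empty partitions",
          s, length(idx), n_active))
      idx <- idx[sample.int(length(idx))]
      partition[idx] <- rep(parts, counts)
    }
  })
  structure(data.frame(id = tab$id,
                       partition = factor(partition, levels = parts),
                       stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"),
            fractions = fractions, seed = as.integer(seed))
}

## Largest-remainder apportionment of n into length(fractions) integer
## counts; ties on the remainder resolve in partition order.
largest_remainder <- function(fractions, n) {
  quota <- fractions * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(quota - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Write a split assignment as a two-column CSV (`id,partition`)
#' @param split a `split_assignment`.
#' @param path file path.
#' @export
write_split_csv <- function(split, path) {
  utils::write.csv(data.frame(id = split$id, partition = split$partition),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a feature matrix as CSV plus a JSON encoding manifest
#' @param fm a `feature_matrix`.
#' @param path CSV path; the manifest is written beside it as
#'   `<path>.manifest.json`.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(id = fm$row_ids, fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fm$encoding_manifest,
                       paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}
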