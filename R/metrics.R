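#' Confusion matrix over the three diagnosis classes
#'
#' Rows are true classes, columns predicted classes, both ordered
#' Control, MCI, AD. Accepts class labels as strings/factors or 0-based
#' integers (0 = Control, 1 = MCI, 2 = AD).
#'
#' @param y_true,y_pred equal-length class vectors.
#' @return 3 x 3 integer matrix of counts.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_cohortgnn("y_true (%d) and y_pred (%d) differ in length",
                   length(y_true), length(y_pred),
                   class = "cohortgnn_schema_error")
  ti <- as_class_index(y_true)
  pi_ <- as_class_index(y_pred)
  cm <- table(factor(DIAGNOSIS_LEVELS[ti], levels = DIAGNOSIS_LEVELS),
              factor(DIAGNOSIS_LEVELS[pi_], levels = DIAGNOSIS_LEVELS))
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(true = DIAGNOSIS_LEVELS,
                              predicted = DIAGNOSIS_LEVELS))
  m
}

#' Evaluation report from true and predicted classes
#'
#' Computes the confusion matrix, overall accuracy, per-class positive
#' predictive value (precision) and recall (sensitivity), and their
#' support-weighted means. Support-weighted recall equals overall accuracy
#' by construction; the report asserts this identity. A class never
#' predicted gets PPV 0 with a warning.
#'
#' @param y_true,y_pred equal-length class vectors.
#' @return an `eval_report`: list with `confusion_matrix`, `accuracy`,
#'   `weighted_ppv`, `weighted_recall`, and a `per_class` data frame
#'   (class, support, ppv, recall). All metrics are proportions in \[0, 1\].
#' @export
eval_report <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  total <- sum(cm)
  if (total == 0L)
    stop_cohortgnn("cannot evaluate an empty partition",
                   class = "cohortgnn_degenerate_error")
  if (any(predicted == 0 & support > 0))
    warning(sprintf("class(es) never predicted, PPV set to 0: %s",
                    paste(DIAGNOSIS_LEVELS[predicted == 0 & support > 0],
                          collapse = ", ")))
  ppv <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  accuracy <- sum(tp) / total
  w <- support / total
  weighted_ppv <- sum(w * ppv)
  weighted_recall <- sum(w * ifelse(support > 0, recall, 0))
  stopifnot(isTRUE(all.equal(weighted_recall, accuracy)))
  structure(list(confusion_matrix = cm,
                 accuracy = accuracy,
                 weighted_ppv = weighted_ppv,
                 weighted_recall = weighted_recall,
                 per_class = data.frame(class = DIAGNOSIS_LEVELS,
                                        support = as.integer(support),
                                        ppv = unname(ppv),
                                        recall = unname(recall))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> accuracy %.2f%%, weighted PPV %.2f%%, weighted recall %.2f%%\n",
    100 * x$accuracy, 100 * x$weighted_ppv, 100 * x$weighted_recall))
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-8s support %3d  PPV %6.2f%%  recall %6.2f%%\n",
                pc$class[i], pc$support[i], 100 * pc$ppv[i],
                100 * pc$recall[i]))
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion_matrix)
  invisible(x)
}

#' Serialise an evaluation report
#' @param report an `eval_report`.
#' @param path JSON file path; the confusion matrix is also written as
#'   `<path>.confusion.csv`.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = report$accuracy,
    weighted_ppv = report$weighted_ppv,
    weighted_recall = report$weighted_recall,
    per_class = report$per_class,
    confusion_matrix = unclass(report$confusion_matrix)
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  utils::write.csv(as.data.frame(report$confusion_matrix[, , drop = FALSE]),
                   paste0(path, ".confusion.csv"))
  invisible(path)
}
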