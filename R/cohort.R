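#' Specify one diagnostic group of a synthetic cohort
#'
#' A `group_spec` collects the sampling distributions for one diagnosis class:
#' exact subject and female counts, the age distribution, inclusive integer
#' windows and location/scale for the screening instruments (MMSE, MoCA), and
#' distributions for the remaining neuropsychological and care variables.
#'
#' The group sizes, sex counts, age distributions and screening windows of the
#' default cohort (see [default_cohort_config()]) follow the published
#' memory-clinic sample this simulator emulates. Distributions for Education,
#' FAB, HDRS and the three binary care indicators are NOT from that study
#' (which does not report them); the defaults impose a monotone severity
#' ordering so that classes are learnable but overlap realistically.
#'
#' @param label diagnosis class, one of `"Control"`, `"MCI"`, `"AD"`.
#' @param n number of subjects in the group.
#' @param n_female number of females (exact, not sampled); `n_female <= n`.
#' @param age_mean,age_sd age distribution in years; sampled as a normal
#'   truncated to \[55, 95\].
#' @param mmse_range,moca_range inclusive integer windows within \[0, 30\];
#'   scores are discretised truncated normals restricted to the window.
#' @param mmse_mean,mmse_sd,moca_mean,moca_sd location and scale of the
#'   screening scores before discretisation.
#' @param fab_mean,fab_sd Frontal Assessment Battery (scale 0-18).
#' @param hdrs_lambda Poisson rate for the Hamilton Depression Rating Scale
#'   (clipped to \[0, 52\]).
#' @param education_mean,education_sd years of education, clipped to \[3, 20\].
#' @param p_comorbidity,p_treatment,p_rehabilitation Bernoulli probabilities
#'   of the three binary care indicators.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(label, n, n_female, age_mean, age_sd,
                       mmse_range, mmse_mean, mmse_sd,
                       moca_range, moca_mean, moca_sd,
                       fab_mean, fab_sd, hdrs_lambda,
                       education_mean = 9, education_sd = 4,
                       p_comorbidity, p_treatment, p_rehabilitation) {
  label <- match.arg(label, DIAGNOSIS_LEVELS)
  n <- as.integer(n); n_female <- as.integer(n_female)
  if (n < 0L) stop_cohortgnn("group '%s': n must be >= 0", label,
                             class = "cohortgnn_config_error")
  if (n_female > n || n_female < 0L)
    stop_cohortgnn("group '%s': n_female (%d) must be in [0, n = %d]",
                   label, n_female, n, class = "cohortgnn_config_error")
  mmse_range <- as.integer(mmse_range); moca_range <- as.integer(moca_range)
  for (nm in c("mmse_range", "moca_range")) {
    r <- get(nm)
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0L || r[2] > 30L)
      stop_cohortgnn("group '%s': %s must be an inclusive interval within [0, 30]",
                     label, nm, class = "cohortgnn_config_error")
  }
  probs <- c(p_comorbidity, p_treatment, p_rehabilitation)
  if (any(probs < 0 | probs > 1))
    stop_cohortgnn("group '%s': indicator probabilities must lie in [0, 1]",
                   label, class = "cohortgnn_config_error")
  structure(list(
    label = label, n = n, n_female = n_female,
    age_mean = age_mean, age_sd = age_sd,
    mmse_range = mmse_range, mmse_mean = mmse_mean, mmse_sd = mmse_sd,
    moca_range = moca_range, moca_mean = moca_mean, moca_sd = moca_sd,
    fab_mean = fab_mean, fab_sd = fab_sd, hdrs_lambda = hdrs_lambda,
    education_mean = education_mean, education_sd = education_sd,
    p_comorbidity = p_comorbidity, p_treatment = p_treatment,
    p_rehabilitation = p_rehabilitation
  ), class = "group_spec")
}

#' Cohort generation configuration
#'
#' @param groups list of [group_spec()] objects with unique labels.
#' @param seed integer seed controlling all sampling in [generate_cohort()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(groups, seed = 0L) {
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels))
    stop_cohortgnn("group labels must be unique", class = "cohortgnn_config_error")
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default synthetic cohort configuration
#'
#' Mirrors the published study sample: 107 controls (78 F / 29 M, age
#' 74.06 +/- 6.8), 77 amnesic MCI (54 F / 23 M, 75.53 +/- 7.3) and 30 mild AD
#' (19 F / 11 M, 76.33 +/- 6.4); patients have MMSE restricted to 18-28,
#' controls to >= 28 with MoCA > 26. All remaining distributions are
#' simulator defaults (see [group_spec()]).
#'
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
default_cohort_config <- function(seed = 0L) {
  cohort_config(list(
    group_spec("Control", n = 107, n_female = 78,
               age_mean = 74.06, age_sd = 6.8,
               mmse_range = c(28, 30), mmse_mean = 29, mmse_sd = 1,
               moca_range = c(27, 30), moca_mean = 28, moca_sd = 1,
               fab_mean = 16.5, fab_sd = 1.2, hdrs_lambda = 3,
               p_comorbidity = 0.30, p_treatment = 0.02, p_rehabilitation = 0.00),
    group_spec("MCI", n = 77, n_female = 54,
               age_mean = 75.53, age_sd = 7.3,
               mmse_range = c(18, 28), mmse_mean = 25, mmse_sd = 2.5,
               moca_range = c(0, 30), moca_mean = 22, moca_sd = 3,
               fab_mean = 13.5, fab_sd = 2.0, hdrs_lambda = 8,
               p_comorbidity = 0.55, p_treatment = 0.40, p_rehabilitation = 0.30),
    group_spec("AD", n = 30, n_female = 19,
               age_mean = 76.33, age_sd = 6.4,
               mmse_range = c(18, 28), mmse_mean = 21, mmse_sd = 2.5,
               moca_range = c(0, 30), moca_mean = 15, moca_sd = 4,
               fab_mean = 10.5, fab_sd = 2.5, hdrs_lambda = 6,
               p_comorbidity = 0.70, p_treatment = 0.80, p_rehabilitation = 0.50)
  ), seed = seed)
}

sample_group <- function(g) {
  n <- g$n
  if (n == 0L) return(NULL)
  sex <- c(rep("F", g$n_female), rep("M", n - g$n_female))
  sex <- sex[sample.int(n)]
  data.frame(
    diagnosis = rep(g$label, n),
    age = rtrunc_norm(n, g$age_mean, g$age_sd, 55, 95),
    education = pmin(pmax(stats::rnorm(n, g$education_mean, g$education_sd), 3), 20),
    sex = sex,
    mmse = rtrunc_score(n, g$mmse_mean, g$mmse_sd, g$mmse_range[1], g$mmse_range[2]),
    moca = rtrunc_score(n, g$moca_mean, g$moca_sd, g$moca_range[1], g$moca_range[2]),
    fab = rtrunc_score(n, g$fab_mean, g$fab_sd, 0L, 18L),
    hdrs = pmin(stats::rpois(n, g$hdrs_lambda), 52L),
    comorbidity = as.integer(stats::runif(n) < g$p_comorbidity),
    treatment = as.integer(stats::runif(n) < g$p_treatment),
    rehabilitation = as.integer(stats::runif(n) < g$p_rehabilitation),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort table
#'
#' Draws one patient table from a [cohort_config()]. Per-group sex counts are
#' exact (assigned then shuffled, not sampled); ages are truncated normals on
#' \[55, 95\]; screening scores are integers restricted to each group's
#' window, so every generated record already satisfies
#' [apply_inclusion_criteria()]. Bit-reproducible under a fixed config seed.
#'
#' @param config a [cohort_config()]; defaults to [default_cohort_config()].
#' @return a `cohort_table`: a data frame with columns `id`, `diagnosis`,
#'   `age`, `education`, `sex`, `mmse`, `moca`, `fab`, `hdrs`, `comorbidity`,
#'   `treatment`, `rehabilitation`, carrying the generating config as the
#'   `provenance` attribute.
#' @examples
#' cohort <- generate_cohort(default_cohort_config(seed = 1))
#' table(cohort$diagnosis)
#' @export
generate_cohort <- function(config = default_cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- local_seed(config$seed, lapply(config$groups, sample_group))
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) {
    tab <- data.frame(id = character(0), diagnosis = character(0),
                      age = numeric(0), education = numeric(0),
                      sex = character(0), mmse = integer(0), moca = integer(0),
                      fab = integer(0), hdrs = integer(0),
                      comorbidity = integer(0), treatment = integer(0),
                      rehabilitation = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, parts)
    tab <- cbind(id = sprintf("S%03d", seq_len(nrow(tab))), tab,
                 stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  }
  structure(tab, class = c("cohort_table", "data.frame"),
            provenance = list(config = config, seed = config$seed))
}

#' Filter a cohort by the study's inclusion criteria
#'
#' Retains MCI and AD records with 18 <= MMSE <= 28, and Control records with
#' MMSE >= 28 and MoCA > 26 (the conservative cut-off used to exclude
#' preclinical decline in controls). Both rules admit MMSE = 28 exactly, as
#' stated. Record order is preserved.
#'
#' @param table a `cohort_table` or data frame with `diagnosis`, `mmse`,
#'   `moca` columns.
#' @return the filtered table, same class and attributes.
#' @export
apply_inclusion_criteria <- function(table) {
  needed <- c("diagnosis", "mmse", "moca")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L)
    stop_cohortgnn("missing required columns: %s",
                   paste(missing_cols, collapse = ", "),
                   class = "cohortgnn_schema_error")
  keep <- ifelse(table$diagnosis == "Control",
                 table$mmse >= 28 & table$moca > 26,
                 table$mmse >= 18 & table$mmse <= 28)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- class(table)
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects\n", nrow(x)))
  if (nrow(x) > 0L) {
    tab <- table(factor(x$diagnosis, levels = DIAGNOSIS_LEVELS))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  NextMethod()
}

COHORT_COLUMNS <- c("id", "diagnosis", "age", "education", "sex", "mmse",
                    "moca", "fab", "hdrs", "comorbidity", "treatment",
                    "rehabilitation")

#' Read / write a cohort table as CSV
#'
#' The on-disk schema has header
#' `id,diagnosis,age,education,sex,mmse,moca,fab,hdrs,comorbidity,treatment,rehabilitation`,
#' binary flags as 0/1 and diagnosis as literal `Control`/`MCI`/`AD`.
#'
#' @param table a `cohort_table`.
#' @param path file path.
#' @return `read_cohort_csv` returns a `cohort_table`; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, COHORT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(tab))
  if (length(missing_cols) > 0L)
    stop_cohortgnn("cohort CSV lacks columns: %s",
                   paste(missing_cols, collapse = ", "),
                   class = "cohortgnn_schema_error")
  bad <- setdiff(unique(tab$diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad) > 0L)
    stop_cohortgnn("unknown diagnosis label(s): %s", paste(bad, collapse = ", "),
                   class = "cohortgnn_schema_error")
  structure(tab[, COHORT_COLUMNS], class = c("cohort_table", "data.frame"))
}
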