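test_that("standardisation gives zero mean, unit sample sd, and is idempotent", {
  toy <- toy_cohort(rep("MCI", 3))
  toy$age <- c(1, 2, 3)
  out <- standardize_numeric(toy, "age")
  expect_equal(drop(out$values), c(-1, 0, 1))   # forced by the n-1 convention
  again <- standardize_numeric(
    data.frame(age = drop(out$values)), "age")
  expect_equal(again$values, out$values, tolerance = 1e-12)
})

test_that("standardisation matches an independent two-pass oracle", {
  set.seed(50)
  df <- as.data.frame(matrix(rnorm(50 * 6, mean = 3, sd = 4), 50, 6))
  names(df) <- paste0("v", 1:6)
  out <- standardize_numeric(df, names(df))
  for (j in 1:6) {
    v <- df[[j]]
    mu <- sum(v) / length(v)
    sdv <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    expect_equal(out$values[, j], (v - mu) / sdv, tolerance = 1e-12)
    expect_lt(abs(mean(out$values[, j])), 1e-9)
    expect_lt(abs(sd(out$values[, j]) - 1), 1e-9)
  }
})

test_that("constant columns and tiny tables are explicit errors", {
  toy <- toy_cohort(rep("MCI", 4))   # education is constant in the fixture
  expect_error(standardize_numeric(toy, "education"),
               class = "cohortgnn_degenerate_error")
  expect_error(standardize_numeric(toy[1, ], "age"),
               class = "cohortgnn_degenerate_error")
})

test_that("a stored scaler reproduces the matrix bit-identically", {
  cohort <- generate_cohort(small_cohort_config(seed = 8))
  fm1 <- build_feature_matrix(cohort)
  fm2 <- build_feature_matrix(cohort, scaler = fm1$scaler)
  expect_identical(fm1$values, fm2$values)
})

test_that("default schema yields the 11-column design matrix in fixed order", {
  cohort <- generate_cohort(small_cohort_config(seed = 1))
  fm <- build_feature_matrix(cohort)
  expect_equal(ncol(fm$values), 11L)
  expect_equal(fm$column_names,
               c("age", "education", "mmse", "moca", "fab", "hdrs",
                 "sex_F", "sex_M", "comorbidity", "treatment",
                 "rehabilitation"))
  expect_equal(fm$row_ids, cohort$id)
  expect_false(anyNA(fm$values))
  ## manifest maps sex to its two indicators
  expect_equal(fm$encoding_manifest$sex, c("sex_F", "sex_M"))
})

test_that("one-hot indicators match a hand-enumerated table", {
  toy <- toy_cohort(rep("MCI", 8), sex = c("F", "M", "M", "F", "F", "M", "F", "F"))
  toy$comorbidity <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  toy$treatment <- c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L)
  toy$rehabilitation <- c(0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L)
  enc <- one_hot_encode(toy)
  expected <- cbind(
    sex_F = c(1, 0, 0, 1, 1, 0, 1, 1),
    sex_M = c(0, 1, 1, 0, 0, 1, 0, 0),
    comorbidity = c(1, 0, 1, 1, 0, 0, 1, 0),
    treatment = c(0, 0, 1, 0, 1, 0, 0, 1),
    rehabilitation = c(0, 1, 0, 0, 0, 0, 1, 0))
  expect_equal(enc$values, expected)
  expect_true(all(enc$values %in% c(0, 1)))
})

test_that("an all-female table one-hot encodes to a unit sex_F column", {
  toy <- toy_cohort(rep("Control", 5))
  enc <- one_hot_encode(toy)
  expect_equal(unname(enc$values[, "sex_F"]), rep(1, 5))
  expect_equal(unname(enc$values[, "sex_M"]), rep(0, 5))
})

test_that("unseen categorical levels are schema errors", {
  toy <- toy_cohort(rep("MCI", 3), sex = c("F", "X", "M"))
  expect_error(one_hot_encode(toy), class = "cohortgnn_schema_error")
  toy2 <- toy_cohort(rep("MCI", 3))
  toy2$treatment <- c(0L, 2L, 1L)
  expect_error(one_hot_encode(toy2), class = "cohortgnn_schema_error")
})

test_that("degenerate split fractions send everyone to train", {
  cohort <- generate_cohort(small_cohort_config(seed = 2))
  split <- stratified_split(cohort, c(1, 0, 0), seed = 1)
  expect_true(all(split$partition == "train"))
})

test_that("every subject lands in exactly one partition, any fractions/seed", {
  cohort <- generate_cohort(small_cohort_config(seed = 3))
  for (frac in list(c(.5, .2, .3), c(.7, .3, 0), c(1 / 3, 1 / 3, 1 / 3))) {
    for (seed in c(1, 99)) {
      split <- suppressWarnings(stratified_split(cohort, frac, seed = seed))
      expect_setequal(split$id, cohort$id)
      expect_false(anyDuplicated(split$id) > 0)
      expect_false(anyNA(split$partition))
    }
  }
})

test_that("per-stratum counts follow largest-remainder apportionment", {
  cohort <- generate_cohort(small_cohort_config(seed = 7,
                                                n = c(12L, 10L, 8L),
                                                n_female = c(7L, 6L, 4L)))
  fractions <- c(0.5, 0.2, 0.3)
  split <- stratified_split(cohort, fractions, seed = 13)
  part <- split$partition[match(cohort$id, split$id)]
  strata <- interaction(cohort$diagnosis, cohort$sex, drop = TRUE)
  for (s in levels(strata)) {
    idx <- strata == s
    n_s <- sum(idx)
    got <- as.integer(table(part[idx]))
    ## independent apportionment oracle: floor quotas, then hand the
    ## remaining seats to the largest fractional remainders
    quota <- fractions * n_s
    base <- floor(quota)
    seats <- n_s - sum(base)
    expected <- base
    if (seats > 0) {
      take <- order(quota - base, decreasing = TRUE)[seq_len(seats)]
      expected[take] <- expected[take] + 1
    }
    expect_equal(got, as.integer(expected))
    expect_true(all(abs(got - quota) < 1))
  }
})

test_that("default split keeps class proportions within one subject per class", {
  cohort <- generate_cohort(default_cohort_config(seed = 21))
  split <- stratified_split(cohort, seed = 22)
  part <- split$partition[match(cohort$id, split$id)]
  global <- table(factor(cohort$diagnosis, c("Control", "MCI", "AD"))) / nrow(cohort)
  for (p in c("train", "val", "test")) {
    idx <- part == p
    sub <- table(factor(cohort$diagnosis[idx], c("Control", "MCI", "AD")))
    ## each class count within 1+1 of the proportional share (one subject of
    ## slack per diagnosis x sex sub-stratum feeding the class)
    expect_true(all(abs(sub - global * sum(idx)) <= 2))
  }
})

test_that("splits are deterministic in the seed and warn on tiny strata", {
  cohort <- generate_cohort(small_cohort_config(seed = 5))
  s1 <- suppressWarnings(stratified_split(cohort, seed = 42))
  s2 <- suppressWarnings(stratified_split(cohort, seed = 42))
  expect_identical(s1$partition, s2$partition)
  tiny <- toy_cohort(c("Control", "MCI"), sex = c("F", "M"),
                     mmse = c(29L, 25L), moca = c(28L, 20L))
  warns <- capture_warnings(stratified_split(tiny, c(.4, .3, .3), seed = 1))
  expect_length(warns, 2L)   # one per undersized stratum
  expect_match(warns, "fewer than", all = TRUE)
})

test_that("invalid fractions are rejected", {
  cohort <- generate_cohort(small_cohort_config(seed = 6))
  expect_error(stratified_split(cohort, c(.5, .5, .5)),
               class = "cohortgnn_config_error")
  expect_error(stratified_split(cohort, c(-.1, .6, .5)),
               class = "cohortgnn_config_error")
})
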