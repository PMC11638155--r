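## Shared fixture builders and oracles, all generated in code.

## Hand-built cohort table with explicit values (no RNG).
toy_cohort <- function(diagnosis, sex = rep("F", length(diagnosis)),
                       mmse = rep(25L, length(diagnosis)),
                       moca = rep(20L, length(diagnosis))) {
  n <- length(diagnosis)
  structure(data.frame(
    id = sprintf("T%02d", seq_len(n)),
    diagnosis = diagnosis,
    age = seq(60, by = 1, length.out = n),
    education = rep(10, n),
    sex = sex,
    mmse = as.integer(mmse),
    moca = as.integer(moca),
    fab = rep(12L, n),
    hdrs = rep(4L, n),
    comorbidity = rep(0L, n),
    treatment = rep(0L, n),
    rehabilitation = rep(0L, n),
    stringsAsFactors = FALSE
  ), class = c("cohort_table", "data.frame"))
}

## A small cohort config for fast end-to-end runs.
small_cohort_config <- function(seed = 0L, n = c(15L, 10L, 5L),
                                n_female = c(10L, 7L, 3L)) {
  cfg <- default_cohort_config(seed)
  for (i in seq_along(cfg$groups)) {
    cfg$groups[[i]]$n <- n[i]
    cfg$groups[[i]]$n_female <- n_female[i]
  }
  cfg
}

## Central finite-difference gradient of the cross-entropy loss w.r.t. all
## parameters, via repeated deterministic forward passes. Independent of the
## analytic backward pass it is used to check.
fd_gradient <- function(spec, params, x, edge_index, class_idx, h = 1e-5) {
  theta <- cohortgnn:::flatten_params(params)
  loss_at <- function(v) {
    p <- cohortgnn:::unflatten_params(v, params)
    logits <- cohortgnn:::nn_forward_cache(spec, p, x, edge_index,
                                           training = FALSE)$logits
    cohortgnn:::cross_entropy_loss(logits, class_idx)$loss
  }
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    (loss_at(up) - loss_at(dn)) / (2 * h)
  }, numeric(1))
}

analytic_gradient <- function(spec, params, x, edge_index, class_idx) {
  fwd <- cohortgnn:::nn_forward_cache(spec, params, x, edge_index,
                                      training = FALSE)
  ce <- cohortgnn:::cross_entropy_loss(fwd$logits, class_idx)
  cohortgnn:::flatten_params(
    cohortgnn:::nn_backward(spec, params, fwd$cache, ce$dlogits))
}

## Random small feature matrix + connected-ish edge index.
random_instance <- function(n, p = 11, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  pairs <- t(combn(n, 2))
  keep <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
  ei <- rbind(keep, keep[, 2:1, drop = FALSE])
  list(x = x, edge_index = ei[order(ei[, 1], ei[, 2]), , drop = FALSE])
}
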