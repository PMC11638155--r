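#' @keywords internal
"_PACKAGE"

## Canonical diagnosis classes, in severity order used throughout.
DIAGNOSIS_LEVELS <- c("Control", "MCI", "AD")

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Truncated normal via inverse-CDF; exact and vectorised.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Integer instrument score: discretised truncated normal on an inclusive
## integer window.
rtrunc_score <- function(n, mean, sd, lower, upper) {
  x <- round(rtrunc_norm(n, mean, sd, lower - 0.499, upper + 0.499))
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cohortgnn <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cohortgnn_error")))
}
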