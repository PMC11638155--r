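#' Describe one of the three classifier architectures
#'
#' Fixes the layer mathematics of the three models compared in the package:
#' an 11-16-8-3 multilayer perceptron (ReLU, dropout 0.1), a two-layer graph
#' convolutional network with 16 hidden units (ReLU, dropout 0.1), and a
#' two-layer graph attention network whose first layer concatenates 8
#' attention heads of 16 units each (ELU, dropout 0.2) and whose second is a
#' single-head attention layer emitting the 3 class scores. No activation is
#' applied to the output layer; it feeds the softmax cross-entropy loss.
#'
#' @param kind `"MLP"`, `"GCN"` or `"GAT"`.
#' @param in_features number of input features per node (default 11).
#' @param n_classes number of diagnosis classes (default 3).
#' @param hidden hidden widths: MLP `c(16, 8)`; GCN `16`; GAT `16` per head.
#' @param heads number of attention heads in the first GAT layer (default 8).
#' @param dropout dropout rate; defaults 0.1 (MLP/GCN) or 0.2 (GAT).
#' @return a `model_spec`.
#' @export
model_spec <- function(kind = c("MLP", "GCN", "GAT"), in_features = 11,
                       n_classes = 3, hidden = NULL, heads = 8,
                       dropout = NULL) {
  kind <- match.arg(kind)
  hidden <- hidden %||% switch(kind, MLP = c(16L, 8L), GCN = 16L, GAT = 16L)
  dropout <- dropout %||% switch(kind, MLP = 0.1, GCN = 0.1, GAT = 0.2)
  if (any(hidden <= 0)) stop_cohortgnn("hidden widths must be positive",
                                       class = "cohortgnn_config_error")
  if (dropout < 0 || dropout >= 1)
    stop_cohortgnn("dropout must lie in [0, 1)", class = "cohortgnn_config_error")
  structure(list(kind = kind, in_features = as.integer(in_features),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden),
                 heads = if (kind == "GAT") as.integer(heads) else NULL,
                 activation = switch(kind, GAT = "ELU", "ReLU"),
                 dropout = dropout),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  arch <- switch(x$kind,
    MLP = paste(c(x$in_features, x$hidden, x$n_classes), collapse = "-"),
    GCN = paste(c(x$in_features, x$hidden, x$n_classes), collapse = "-"),
    GAT = sprintf("%d-[%dx%d]-%d", x$in_features, x$heads, x$hidden[1], x$n_classes))
  cat(sprintf("<model_spec> %s %s, %s, dropout %.2g\n",
              x$kind, arch, x$activation, x$dropout))
  invisible(x)
}

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

#' Initialise model parameters
#'
#' Weights use uniform Glorot (fan-based) scaling; biases start at zero;
#' attention vectors are initialised like single-output weight columns.
#' Deterministic under a fixed seed.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return a `model_params` nested list of weight matrices and bias vectors,
#'   carrying `spec` and `seed` attributes.
#' @export
init_params <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  p <- local_seed(seed, switch(spec$kind,
    MLP = {
      widths <- c(spec$in_features, spec$hidden, spec$n_classes)
      out <- list()
      for (i in seq_len(length(widths) - 1L)) {
        out[[paste0("W", i)]] <- glorot_uniform(widths[i], widths[i + 1L])
        out[[paste0("b", i)]] <- numeric(widths[i + 1L])
      }
      out
    },
    GCN = list(
      W1 = glorot_uniform(spec$in_features, spec$hidden[1]),
      b1 = numeric(spec$hidden[1]),
      W2 = glorot_uniform(spec$hidden[1], spec$n_classes),
      b2 = numeric(spec$n_classes)
    ),
    GAT = {
      d <- spec$hidden[1]
      heads <- lapply(seq_len(spec$heads), function(h) list(
        W = glorot_uniform(spec$in_features, d),
        a_src = drop(glorot_uniform(d, 1)),
        a_dst = drop(glorot_uniform(d, 1)),
        b = numeric(d)
      ))
      names(heads) <- paste0("h", seq_len(spec$heads))
      concat <- d * spec$heads
      list(layer1 = heads,
           layer2 = list(
             W = glorot_uniform(concat, spec$n_classes),
             a_src = drop(glorot_uniform(spec$n_classes, 1)),
             a_dst = drop(glorot_uniform(spec$n_classes, 1)),
             b = numeric(spec$n_classes)))
    }))
  structure(p, class = "model_params", spec = spec, seed = as.integer(seed))
}

## --- parameter vector plumbing (Adam and gradient checks work on the flat
## vector; forward passes on the nested list) ---

flatten_params <- function(p) as.numeric(unlist(p, use.names = FALSE))

unflatten_params <- function(vec, template) {
  pos <- 0L
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    k <- length(t)
    out <- vec[pos + seq_len(k)]
    pos <<- pos + k
    dim(out) <- dim(t)
    out
  }
  out <- rec(template)
  attributes(out) <- attributes(template)
  out
}

## --- activations and their derivatives ---

relu <- function(z) (z > 0) * z
elu <- function(z) {
  neg <- z <= 0
  z[neg] <- expm1(z[neg])
  z
}
elu_grad <- function(z) {
  g <- exp(pmin(z, 0))
  g[z > 0] <- 1
  g
}
leaky_relu <- function(z, slope = 0.2) {
  neg <- z <= 0
  z[neg] <- slope * z[neg]
  z
}
leaky_relu_grad <- function(z, slope = 0.2) {
  g <- array(1, dim(z) %||% length(z))
  g[z <= 0] <- slope
  g
}

## Row-wise softmax, stable under -Inf masking (every row must keep at least
## one finite entry).
row_softmax <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}

## Inverted dropout mask: scales kept units by 1/(1-rate) so evaluation mode
## needs no rescaling.
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

## Softmax cross-entropy over a subset of rows; returns the mean loss and
## the gradient w.r.t. the full logits matrix (zero outside `rows`).
cross_entropy_loss <- function(logits, class_idx, rows = seq_len(nrow(logits))) {
  p <- row_softmax(logits)
  m <- length(rows)
  loss <- -mean(log(pmax(p[cbind(rows, class_idx[rows])], 1e-300)))
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[rows, ] <- p[rows, , drop = FALSE]
  dlogits[cbind(rows, class_idx[rows])] <-
    dlogits[cbind(rows, class_idx[rows])] - 1
  dlogits[rows, ] <- dlogits[rows, , drop = FALSE] / m
  list(loss = loss, dlogits = dlogits)
}

## Map user-facing labels (diagnosis strings, factors, or 0-based integers)
## to 1-based class indices over DIAGNOSIS_LEVELS.
as_class_index <- function(labels, n_classes = 3L) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, DIAGNOSIS_LEVELS)
    if (anyNA(idx))
      stop_cohortgnn("unknown class label(s): %s",
                     paste(unique(labels[is.na(idx)]), collapse = ", "),
                     class = "cohortgnn_schema_error")
    return(idx)
  }
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_classes))
    stop_cohortgnn("integer labels must lie in {0, ..., %d}", n_classes - 1L,
                   class = "cohortgnn_schema_error")
  labels + 1L
}

check_edge_index <- function(edge_index, n) {
  if (is.null(edge_index) || nrow(edge_index) == 0L)
    return(matrix(integer(0), 0, 2))
  edge_index <- as.matrix(edge_index)
  if (ncol(edge_index) != 2L)
    stop_cohortgnn("edge_index must have two columns (source, target)",
                   class = "cohortgnn_index_error")
  if (max(edge_index) > n || min(edge_index) < 1L)
    stop_cohortgnn("edge_index references nodes outside 1..%d", n,
                   class = "cohortgnn_index_error")
  storage.mode(edge_index) <- "integer"
  edge_index
}
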