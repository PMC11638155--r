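#' Multilayer perceptron forward pass
#'
#' The baseline model: two dense hidden layers of 16 and 8 ReLU units on the
#' 11 node features, a linear 3-unit output layer (no activation; the
#' softmax lives in the loss), and dropout 0.1 on the hidden activations
#' during training only. Evaluation mode is deterministic.
#'
#' @param x n x 11 numeric matrix (or `feature_matrix`).
#' @param params `model_params` from [init_params()] for an MLP spec.
#' @param training logical; when `TRUE`, dropout masks are drawn from the
#'   current RNG state.
#' @return n x 3 logits matrix.
#' @export
mlp_forward <- function(x, params, training = FALSE) {
  mlp_forward_cache(x, params, training)$logits
}

mlp_forward_cache <- function(x, params, training = FALSE, rate = NULL) {
  x <- as_input_matrix(x, nrow(params$W1))
  rate <- rate %||% attr(params, "spec")$dropout %||% 0.1
  n <- nrow(x)
  Z1 <- x %*% params$W1 + rep_row(params$b1, n)
  H1 <- relu(Z1)
  D1 <- if (training) dropout_mask(n, ncol(H1), rate) else NULL
  H1d <- apply_mask(H1, D1)
  Z2 <- H1d %*% params$W2 + rep_row(params$b2, n)
  H2 <- relu(Z2)
  D2 <- if (training) dropout_mask(n, ncol(H2), rate) else NULL
  H2d <- apply_mask(H2, D2)
  logits <- H2d %*% params$W3 + rep_row(params$b3, n)
  list(logits = logits,
       cache = list(x = x, Z1 = Z1, H1d = H1d, Z2 = Z2, H2d = H2d,
                    D1 = D1, D2 = D2))
}

mlp_backward <- function(params, cache, dlogits) {
  dW3 <- t(cache$H2d) %*% dlogits
  db3 <- colSums(dlogits)
  dH2 <- apply_mask(dlogits %*% t(params$W3), cache$D2)
  dZ2 <- dH2 * (cache$Z2 > 0)
  dW2 <- t(cache$H1d) %*% dZ2
  db2 <- colSums(dZ2)
  dH1 <- apply_mask(dZ2 %*% t(params$W2), cache$D1)
  dZ1 <- dH1 * (cache$Z1 > 0)
  dW1 <- t(cache$x) %*% dZ1
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

rep_row <- function(b, n) matrix(b, n, length(b), byrow = TRUE)

as_input_matrix <- function(x, in_features = NULL) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (!is.null(in_features) && ncol(x) != in_features)
    stop_cohortgnn("input has %d columns; model expects %d", ncol(x),
                   in_features, class = "cohortgnn_shape_error")
  x
}
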