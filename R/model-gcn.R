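#' Symmetric-normalised adjacency with self-loops
#'
#' Builds the propagation operator `A_hat = D~^(-1/2) (A + I) D~^(-1/2)` used
#' by the graph convolutional layers: adjacency from the directed edge
#' index, self-loops added, then symmetric degree normalisation. Self-loop
#' augmentation guarantees every node has positive degree, so the operator
#' is finite even for isolated patients.
#'
#' @param edge_index m x 2 integer matrix of directed (source, target)
#'   entries, 1-based.
#' @param n number of nodes.
#' @return dense n x n propagation matrix.
#' @export
normalized_adjacency <- function(edge_index, n) {
  edge_index <- check_edge_index(edge_index, n)
  A <- matrix(0, n, n)
  if (nrow(edge_index) > 0L) A[edge_index] <- 1
  A <- pmax(A, t(A))        # tolerate single-direction listings
  diag(A) <- 0
  At <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Graph convolutional network forward pass
#'
#' Two spectral graph convolutions over the population graph:
#' `h = ReLU(A_hat x W1 + b1)` with 16 hidden units, then
#' `logits = A_hat h W2 + b2` reducing to the 3 class scores. Dropout 0.1 is
#' applied to the hidden activations during training. Propagation runs over
#' all nodes (transductive); only the loss is restricted to training nodes.
#'
#' @param x n x 11 numeric matrix (or `feature_matrix`).
#' @param edge_index directed edge index over the n rows of `x`.
#' @param params `model_params` for a GCN spec.
#' @param training logical; draw dropout masks when `TRUE`.
#' @return n x 3 logits matrix.
#' @export
gcn_forward <- function(x, edge_index, params, training = FALSE) {
  gcn_forward_cache(x, edge_index, params, training)$logits
}

gcn_forward_cache <- function(x, edge_index, params, training = FALSE,
                              A_hat = NULL, rate = NULL) {
  x <- as_input_matrix(x, nrow(params$W1))
  rate <- rate %||% attr(params, "spec")$dropout %||% 0.1
  n <- nrow(x)
  if (is.null(A_hat)) A_hat <- normalized_adjacency(edge_index, n)
  Z1 <- A_hat %*% (x %*% params$W1) + rep_row(params$b1, n)
  H <- relu(Z1)
  D <- if (training) dropout_mask(n, ncol(H), rate) else NULL
  Hd <- apply_mask(H, D)
  logits <- A_hat %*% (Hd %*% params$W2) + rep_row(params$b2, n)
  list(logits = logits,
       cache = list(x = x, A_hat = A_hat, Z1 = Z1, Hd = Hd, D = D))
}

gcn_backward <- function(params, cache, dlogits) {
  ## A_hat is symmetric, so the adjoint of propagation is A_hat itself
  G <- cache$A_hat %*% dlogits
  dW2 <- t(cache$Hd) %*% G
  db2 <- colSums(dlogits)
  dH <- apply_mask(G %*% t(params$W2), cache$D)
  dZ1 <- dH * (cache$Z1 > 0)
  Q <- cache$A_hat %*% dZ1
  dW1 <- t(cache$x) %*% Q
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}
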