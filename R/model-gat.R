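#' Graph attention network forward pass
#'
#' First layer: 8 attention heads, each projecting the 11 features to 16
#' units and attending over graph neighbours plus a self-loop with the
#' standard single-linear-layer attention
#' `e_ij = LeakyReLU(a_src . W x_i + a_dst . W x_j)` (negative slope 0.2),
#' normalised per node by a softmax over its neighbourhood. Head outputs are
#' concatenated (width 128) and passed through ELU. The second layer is a
#' single-head attention layer mapping to the 3 class scores (no output
#' activation). During training, dropout 0.2 is applied to layer inputs and
#' to the normalised attention coefficients.
#'
#' @param x n x 11 numeric matrix (or `feature_matrix`).
#' @param edge_index directed edge index over the n rows of `x`; self-loops
#'   are added internally so isolated patients attend to themselves.
#' @param params `model_params` for a GAT spec.
#' @param training logical; draw dropout masks when `TRUE`.
#' @param return_attention when `TRUE`, attach the per-head first-layer
#'   attention matrices and the second-layer attention matrix as the
#'   `attention` attribute of the logits.
#' @return n x 3 logits matrix.
#' @export
gat_forward <- function(x, edge_index, params, training = FALSE,
                        return_attention = FALSE) {
  out <- gat_forward_cache(x, edge_index, params, training)
  logits <- out$logits
  if (return_attention) {
    attr(logits, "attention") <- list(
      layer1 = lapply(out$cache$heads, function(h) h$alpha),
      layer2 = out$cache$l2$alpha)
  }
  logits
}

## One attention head on input X (n x p) -> (n x d), with cache for backprop.
gat_layer_forward <- function(head, X, adj, rate, training) {
  n <- nrow(X)
  H <- X %*% head$W
  f <- drop(H %*% head$a_src)
  g <- drop(H %*% head$a_dst)
  E <- outer(f, g, "+")                    # e_ij = f_i + g_j
  El <- leaky_relu(E)
  El[!adj] <- -Inf
  alpha <- row_softmax(El)
  Dm <- if (training) dropout_mask(n, n, rate) else NULL
  alpha_d <- apply_mask(alpha, Dm)
  Z <- alpha_d %*% H + rep_row(head$b, n)
  list(Z = Z, cache = list(H = H, E = E, adj = adj, alpha = alpha,
                           alpha_d = alpha_d, Dm = Dm))
}

gat_layer_backward <- function(X, head, cache, dZ) {
  db <- colSums(dZ)
  dalpha_d <- dZ %*% t(cache$H)
  dH <- t(cache$alpha_d) %*% dZ
  dalpha <- apply_mask(dalpha_d, cache$Dm)
  srow <- rowSums(dalpha * cache$alpha)
  dEl <- cache$alpha * (dalpha - srow)     # softmax jacobian, row-wise
  dE <- dEl * leaky_relu_grad(cache$E)
  dE[!cache$adj] <- 0
  df <- rowSums(dE)
  dg <- colSums(dE)
  dH <- dH + outer(df, head$a_src) + outer(dg, head$a_dst)
  list(grads = list(W = t(X) %*% dH,
                    a_src = drop(t(cache$H) %*% df),
                    a_dst = drop(t(cache$H) %*% dg),
                    b = db),
       dX = dH %*% t(head$W))
}

gat_forward_cache <- function(x, edge_index, params, training = FALSE,
                              adj = NULL, rate = NULL) {
  x <- as_input_matrix(x, nrow(params$layer1[[1]]$W))
  rate <- rate %||% attr(params, "spec")$dropout %||% 0.2
  n <- nrow(x)
  if (is.null(adj)) adj <- attention_mask(edge_index, n)
  D0 <- if (training) dropout_mask(n, ncol(x), rate) else NULL
  X0 <- apply_mask(x, D0)
  heads <- lapply(params$layer1, function(head)
    gat_layer_forward(head, X0, adj, rate, training))
  C <- do.call(cbind, lapply(heads, `[[`, "Z"))
  A1 <- elu(C)
  D1 <- if (training) dropout_mask(n, ncol(A1), rate) else NULL
  A1d <- apply_mask(A1, D1)
  l2 <- gat_layer_forward(params$layer2, A1d, adj, rate, training)
  list(logits = l2$Z,
       cache = list(x = x, X0 = X0, D0 = D0, adj = adj,
                    heads = lapply(heads, `[[`, "cache"),
                    C = C, A1d = A1d, D1 = D1, l2 = l2$cache))
}

gat_backward <- function(params, cache, dlogits) {
  l2 <- gat_layer_backward(cache$A1d, params$layer2, cache$l2, dlogits)
  dA1 <- apply_mask(l2$dX, cache$D1)
  dC <- dA1 * elu_grad(cache$C)
  d <- ncol(params$layer1[[1]]$W)
  grads1 <- vector("list", length(params$layer1))
  names(grads1) <- names(params$layer1)
  for (h in seq_along(params$layer1)) {
    cols <- (h - 1L) * d + seq_len(d)
    bk <- gat_layer_backward(cache$X0, params$layer1[[h]],
                             cache$heads[[h]], dC[, cols, drop = FALSE])
    grads1[[h]] <- bk$grads
  }
  list(layer1 = grads1, layer2 = l2$grads)
}

## Boolean neighbourhood mask including self-loops.
attention_mask <- function(edge_index, n) {
  edge_index <- check_edge_index(edge_index, n)
  adj <- matrix(FALSE, n, n)
  if (nrow(edge_index) > 0L) {
    adj[edge_index] <- TRUE
    adj <- adj | t(adj)
  }
  diag(adj) <- TRUE
  adj
}
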