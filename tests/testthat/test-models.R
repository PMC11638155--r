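test_that("initialisation is seeded, shaped, and Glorot-bounded", {
  spec <- model_spec("MLP")
  p1 <- init_params(spec, seed = 3)
  p2 <- init_params(spec, seed = 3)
  expect_identical(p1, p2)
  p3 <- init_params(spec, seed = 4)
  expect_false(identical(p1$W1, p3$W1))
  expect_equal(dim(p1$W1), c(11L, 16L))
  expect_equal(dim(p1$W2), c(16L, 8L))
  expect_equal(dim(p1$W3), c(8L, 3L))
  expect_equal(p1$b3, rep(0, 3))
  expect_true(all(abs(p1$W1) <= sqrt(6 / (11 + 16))))

  gat <- init_params(model_spec("GAT"), seed = 5)
  expect_length(gat$layer1, 8L)
  expect_equal(dim(gat$layer1$h1$W), c(11L, 16L))
  expect_length(gat$layer1$h1$a_src, 16L)
  expect_equal(dim(gat$layer2$W), c(128L, 3L))
})

test_that("all-zero MLP parameters give uniform class probabilities", {
  spec <- model_spec("MLP")
  p <- init_params(spec, seed = 1)
  zero <- cohortgnn:::unflatten_params(
    numeric(length(cohortgnn:::flatten_params(p))), p)
  x <- matrix(rnorm(4 * 11), 4, 11)
  logits <- mlp_forward(x, zero)
  expect_equal(logits, matrix(0, 4, 3))
  probs <- exp(logits) / rowSums(exp(logits))
  expect_equal(probs, matrix(1 / 3, 4, 3))
})

test_that("MLP forward matches a pencil-and-paper pass on sparse weights", {
  spec <- model_spec("MLP")
  p <- init_params(spec, seed = 1)
  zero <- cohortgnn:::unflatten_params(
    numeric(length(cohortgnn:::flatten_params(p))), p)
  zero$W1[1, 1] <- 1; zero$W1[2, 2] <- -1; zero$b1[2] <- 1
  zero$W2[1, 1] <- 2; zero$W2[2, 2] <- 3
  zero$W3[1, 3] <- 1; zero$W3[2, 1] <- 0.5; zero$b3[2] <- -0.25
  x <- matrix(0, 1, 11); x[1] <- 2; x[2] <- 3
  ## by hand: z1 = (2, -3 + 1, 0, ...) -> h1 = (2, 0, ...)
  ##          z2 = (2*2, 0*3, 0, ...)  -> h2 = (4, 0, ...)
  ##          logits = (0.5*0, -0.25, 4*1) = (0, -0.25, 4)
  expect_equal(mlp_forward(x, zero), cbind(0, -0.25, 4))
})

test_that("evaluation mode is deterministic; training mode applies dropout", {
  spec <- model_spec("MLP")
  p <- init_params(spec, seed = 2)
  x <- matrix(rnorm(6 * 11), 6, 11)
  set.seed(1); a <- mlp_forward(x, p)
  set.seed(999); b <- mlp_forward(x, p)
  expect_identical(a, b)
  set.seed(1); tr1 <- mlp_forward(x, p, training = TRUE)
  set.seed(2); tr2 <- mlp_forward(x, p, training = TRUE)
  expect_false(identical(tr1, tr2))
})

test_that("the normalised adjacency matches the 2-node hand computation", {
  ei <- rbind(c(1L, 2L), c(2L, 1L))
  A_hat <- normalized_adjacency(ei, 2)
  expect_equal(A_hat, matrix(0.5, 2, 2))
  expect_error(normalized_adjacency(rbind(c(1L, 3L)), 2),
               class = "cohortgnn_index_error")
})

test_that("GCN with an empty edge set equals the matched node-wise network", {
  spec <- model_spec("GCN")
  p <- init_params(spec, seed = 6)
  x <- matrix(rnorm(7 * 11), 7, 11)
  got <- gcn_forward(x, matrix(integer(0), 0, 2), p)
  ## no-graph oracle: per-node two-layer network, A_hat = I
  h <- pmax(x %*% p$W1 + matrix(p$b1, 7, 16, byrow = TRUE), 0)
  want <- h %*% p$W2 + matrix(p$b2, 7, 3, byrow = TRUE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("GCN forward equals a dense brute-force oracle on a 6-node graph", {
  spec <- model_spec("GCN")
  p <- init_params(spec, seed = 7)
  inst <- random_instance(6, seed = 70)
  got <- gcn_forward(inst$x, inst$edge_index, p)
  ## oracle: build A-hat explicitly with loops, then apply the formula
  n <- 6
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(inst$edge_index)))
    A[inst$edge_index[r, 1], inst$edge_index[r, 2]] <- 1
  At <- A + diag(n)
  Dh <- diag(1 / sqrt(rowSums(At)))
  Ah <- Dh %*% At %*% Dh
  H <- pmax(Ah %*% inst$x %*% p$W1 + matrix(p$b1, n, 16, byrow = TRUE), 0)
  want <- Ah %*% H %*% p$W2 + matrix(p$b2, n, 3, byrow = TRUE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("GAT attention rows are normalised and isolated nodes self-attend", {
  spec <- model_spec("GAT")
  p <- init_params(spec, seed = 8)
  ## node 5 is isolated
  ei <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L), c(3L, 4L), c(4L, 3L))
  x <- matrix(rnorm(5 * 11), 5, 11)
  logits <- gat_forward(x, ei, p, return_attention = TRUE)
  att <- attr(logits, "attention")
  for (alpha in att$layer1) {
    expect_equal(rowSums(alpha), rep(1, 5), tolerance = 1e-12)
    expect_equal(alpha[5, 5], 1)
    expect_equal(alpha[5, -5], rep(0, 4))
  }
  expect_equal(rowSums(att$layer2), rep(1, 5), tolerance = 1e-12)
  ## the isolated node's pre-activation layer-1 output is exactly its own
  ## projected feature vector, head by head
  fwd <- cohortgnn:::gat_forward_cache(x, ei, p, training = FALSE)
  own <- unlist(lapply(p$layer1, function(h) drop(x[5, ] %*% h$W) + h$b))
  expect_equal(unname(fwd$cache$C[5, ]), unname(own), tolerance = 1e-12)
})

test_that("a 2-node single-head attention matches the hand-computed softmax", {
  spec <- model_spec("GAT", in_features = 2, hidden = 2, heads = 1,
                     n_classes = 2)
  p <- init_params(spec, seed = 9)
  ## overwrite with small fixed weights so the softmax is hand-checkable
  p$layer1$h1$W <- rbind(c(1, 0), c(0, 1))
  p$layer1$h1$a_src <- c(1, 0)
  p$layer1$h1$a_dst <- c(0, 1)
  p$layer1$h1$b <- c(0, 0)
  x <- rbind(c(0.2, 0.4), c(0.6, 0.8))
  ei <- rbind(c(1L, 2L), c(2L, 1L))
  ## by hand, H = x; f = H a_src = (.2, .6); g = H a_dst = (.4, .8)
  ## e_11 = .2 + .4 = .6 ; e_12 = .2 + .8 = 1.0 (both positive: LeakyReLU id)
  ## alpha_1. = softmax(.6, 1.0)
  a11 <- exp(.6) / (exp(.6) + exp(1))
  a12 <- exp(1) / (exp(.6) + exp(1))
  ## z_1 = a11 * H_1 + a12 * H_2
  z1 <- a11 * x[1, ] + a12 * x[2, ]
  fwd <- cohortgnn:::gat_forward_cache(x, ei, p, training = FALSE)
  alpha <- fwd$cache$heads[[1]]$alpha
  expect_equal(alpha[1, ], c(a11, a12), tolerance = 1e-12)
  head_out <- fwd$cache$C[, 1:2]
  expect_equal(head_out[1, ], z1, tolerance = 1e-12)
})

test_that("forward passes are permutation-equivariant", {
  inst <- random_instance(8, seed = 80)
  set.seed(81)
  perm <- sample(8)
  ei_perm <- cbind(perm[inst$edge_index[, 1]], perm[inst$edge_index[, 2]])
  for (kind in c("MLP", "GCN", "GAT")) {
    spec <- model_spec(kind)
    p <- init_params(spec, seed = 10)
    base <- switch(kind,
      MLP = mlp_forward(inst$x, p),
      GCN = gcn_forward(inst$x, inst$edge_index, p),
      GAT = gat_forward(inst$x, inst$edge_index, p))
    xp <- inst$x
    xp[perm, ] <- inst$x
    permuted <- switch(kind,
      MLP = mlp_forward(xp, p),
      GCN = gcn_forward(xp, ei_perm, p),
      GAT = gat_forward(xp, ei_perm, p))
    got <- base
    got[] <- permuted[perm, ]
    expect_equal(got, base, tolerance = 1e-10)
  }
})

test_that("logits stay finite for extreme inputs and degree-0 nodes", {
  inst <- random_instance(6, seed = 82)
  x <- inst$x * 50
  x[3, ] <- 0
  ei <- matrix(integer(0), 0, 2)   # every node isolated
  for (kind in c("MLP", "GCN", "GAT")) {
    p <- init_params(model_spec(kind), seed = 11)
    logits <- switch(kind,
      MLP = mlp_forward(x, p),
      GCN = gcn_forward(x, ei, p),
      GAT = gat_forward(x, ei, p))
    expect_true(all(is.finite(logits)))
  }
})

test_that("column-count mismatches are shape errors", {
  p <- init_params(model_spec("MLP"), seed = 12)
  expect_error(mlp_forward(matrix(0, 3, 7), p),
               class = "cohortgnn_shape_error")
})
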