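#' Cosine kNN adjacency over cells
#'
#' Builds the cell graph used by both the GCN and the attention stages:
#' cosine similarity between rows of `features`, each node keeps its `k` most
#' similar other nodes (every neighbour tied with the k-th similarity is
#' kept, so the result is deterministic and permutation-equivariant), and the
#' directed graph is union-symmetrised. Zero diagonal.
#'
#' @param features n x p numeric matrix, one row per cell.
#' @param k neighbourhood size, `k < n`.
#' @return n x n sparse symmetric 0/1 `Matrix` with zero diagonal.
#' @export
build_knn_adjacency <- function(features, k) {
  features <- as_dense(features)
  n <- nrow(features)
  if (k >= n) stop_config("knn_k (%d) must be smaller than the number of cells (%d)", k, n)
  if (k < 1L) stop_config("knn_k must be >= 1")
  norms <- sqrt(rowSums(features^2))
  safe <- ifelse(norms > 0, norms, 1)
  U <- features / safe
  S <- tcrossprod(U)
  # round away float fuzz so genuinely tied similarities are detected
  S <- round(S, 12L)
  diag(S) <- -Inf
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    thr <- sort(S[i, ], decreasing = TRUE)[k]
    A[i, S[i, ] >= thr] <- TRUE
  }
  A <- A | t(A)
  diag(A) <- FALSE
  as(Matrix::Matrix(A * 1, sparse = TRUE), "CsparseMatrix")
}

# Symmetric-normalised propagation operator D'^(-1/2) (A + I) D'^(-1/2).
gcn_propagator <- function(A) {
  n <- nrow(A)
  Ap <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Ap))
  Matrix::Diagonal(n, dinv) %*% Ap %*% Matrix::Diagonal(n, dinv)
}

relu <- function(x) pmax(x, 0)

glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Graph-convolution forward pass
#'
#' Layer-wise propagation `H_l = sigma(D'^(-1/2) (A + I) D'^(-1/2) H_{l-1}
#' W_l)` with ReLU on hidden layers and identity on the output layer. The
#' self-loop guarantees every augmented degree is positive.
#'
#' @param A n x n adjacency (0/1, zero diagonal).
#' @param H n x p input node features.
#' @param weights list of layer weight matrices chaining p -> ... -> d.
#' @return n x d node representation.
#' @export
gcn_forward <- function(A, H, weights) {
  S <- gcn_propagator(A)
  L <- length(weights)
  H <- as_dense(H)
  for (l in seq_len(L)) {
    H <- as_dense(S %*% H) %*% weights[[l]]
    if (l < L) H <- relu(H)
  }
  H
}

# Forward pass retaining intermediates for backprop.
gcn_forward_cache <- function(S, H0, weights) {
  L <- length(weights)
  P <- vector("list", L)   # S %*% H_{l-1}
  Z <- vector("list", L)   # pre-activations
  H <- as_dense(H0)
  for (l in seq_len(L)) {
    P[[l]] <- as_dense(S %*% H)
    Z[[l]] <- P[[l]] %*% weights[[l]]
    H <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  list(out = H, P = P, Z = Z)
}

# Gradients of a loss w.r.t. layer weights given d(loss)/d(output).
gcn_backward <- function(S, cache, weights, dOut) {
  L <- length(weights)
  grads <- vector("list", L)
  dH <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- if (l < L) dH * (cache$Z[[l]] > 0) else dH
    grads[[l]] <- crossprod(cache$P[[l]], dZ)
    if (l > 1L) dH <- as_dense(S %*% (dZ %*% t(weights[[l]])))
  }
  grads
}

# One Adam step over a nested list of parameter matrices.
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    g <- grads[[i]] + weight_decay * params[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}
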