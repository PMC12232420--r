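#' Masked attention coefficients for one head
#'
#' Computes `e_ij = LeakyReLU(a^T [W h_i || W h_j])` (negative slope 0.2) for
#' every edge of `graph` and normalises by softmax over each node's
#' neighbourhood, so row i is supported on the neighbours of i and sums to 1.
#' The graph must contain self-loops so every neighbourhood is non-empty.
#'
#' @param Hprev n x F node features.
#' @param Wk F x Fp head weight matrix.
#' @param a attention vector of length `2 * Fp`.
#' @param graph n x n 0/1 adjacency including self-loops.
#' @return n x n sparse attention matrix with unit row sums.
#' @export
attention_coefficients <- function(Hprev, Wk, a, graph) {
  Hprev <- as_dense(Hprev)
  G <- as_dense(graph) > 0
  n <- nrow(Hprev)
  if (any(rowSums(G) == 0)) {
    stop_input("graph has an empty neighbourhood; add self-loops first")
  }
  Fp <- ncol(Wk)
  stopifnot(length(a) == 2L * Fp)
  WH <- Hprev %*% Wk
  s_self <- drop(WH %*% a[seq_len(Fp)])
  s_neigh <- drop(WH %*% a[Fp + seq_len(Fp)])
  E <- outer(s_self, s_neigh, `+`)
  E <- ifelse(E > 0, E, 0.2 * E)               # LeakyReLU, slope 0.2
  E[!G] <- -Inf
  # row-wise softmax, shifted for stability
  E <- E - apply(E, 1L, max)
  A <- exp(E)
  A[!G] <- 0
  A <- A / rowSums(A)
  as(Matrix::Matrix(A, sparse = TRUE), "CsparseMatrix")
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

#' One multi-head graph-attention layer
#'
#' Per head q: aggregate `sum_j a_ij W_q h_j`; the head outputs are averaged
#' and the activation applied once to the average (ELU on hidden layers,
#' identity on the final layer).
#'
#' @param Hprev n x F node features.
#' @param heads list of heads, each a list with `W` (F x Fp) and `a`
#'   (length 2 Fp).
#' @param graph n x n adjacency with self-loops.
#' @param final logical: final layer (identity activation) or hidden (ELU).
#' @return n x Fp matrix.
#' @export
gat_layer <- function(Hprev, heads, graph, final = FALSE) {
  stopifnot(length(heads) >= 1L)
  Hprev <- as_dense(Hprev)
  agg <- lapply(heads, function(h) {
    att <- attention_coefficients(Hprev, h$W, h$a, graph)
    as_dense(att %*% (Hprev %*% h$W))
  })
  out <- Reduce(`+`, agg) / length(agg)
  if (final) out else elu(out)
}

# Seed-derived attention parameters: `layers` layers of `heads` heads, each
# mapping width -> width so the final embedding keeps m rows.
init_hgat_params <- function(width, layers, heads, seed) {
  set.seed(child_seed(seed, 57L))
  lapply(seq_len(layers), function(l) {
    lapply(seq_len(heads), function(q) {
      list(W = glorot_init(width, width),
           a = runif(2L * width, -sqrt(3 / width), sqrt(3 / width)))
    })
  })
}

#' High-order shared representation by hierarchical graph attention
#'
#' Treats the n cells as nodes with the columns of the shared anchor graph
#' `Zs` as features, builds a cosine kNN graph over them with self-loops, and
#' applies `layers` multi-head attention layers (each width-preserving, heads
#' averaged, ELU between layers). Parameters are drawn deterministically from
#' `seed` and are not trained: the stage acts as fixed random-feature
#' propagation of high-order neighbourhood structure. Returns the propagated
#' representation transposed back to anchors x cells.
#'
#' @param Zs m x n shared anchor graph (column-stochastic).
#' @param layers,heads attention depth and head count.
#' @param knn_k neighbourhood size for the cell graph.
#' @param seed integer seed for the parameter draw.
#' @param params optional pre-built parameter list (as from the internal
#'   initialiser) overriding the seeded draw.
#' @param graph optional pre-built n x n adjacency (self-loops added if
#'   missing).
#' @param return_state logical: also return the per-layer attention matrices
#'   and parameters.
#' @return m x n matrix `Zs_prime`, or a list with `Zs_prime`, `attention`,
#'   `params`, `graph` when `return_state = TRUE`.
#' @export
run_hgat <- function(Zs, layers = 2L, heads = 3L, knn_k = 15L, seed = 1L,
                     params = NULL, graph = NULL, return_state = FALSE) {
  Zs <- as_dense(Zs)
  m <- nrow(Zs); n <- ncol(Zs)
  H <- t(Zs)                                   # cells as nodes, F = m
  if (is.null(graph)) {
    graph <- build_knn_adjacency(H, k = min(knn_k, n - 1L))
  }
  graph <- as_dense(graph)
  diag(graph) <- 1                             # self-loops
  params <- params %||% init_hgat_params(m, layers, heads, seed)
  attn <- vector("list", length(params))
  for (l in seq_along(params)) {
    final <- l == length(params)
    if (return_state) {
      attn[[l]] <- lapply(params[[l]], function(h) {
        attention_coefficients(H, h$W, h$a, graph)
      })
    }
    H <- gat_layer(H, params[[l]], graph, final = final)
  }
  check_finite(H, "attention output")
  Zs_prime <- t(H)
  if (return_state) {
    list(Zs_prime = Zs_prime, attention = attn, params = params, graph = graph)
  } else {
    Zs_prime
  }
}
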