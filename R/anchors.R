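#' Initial anchors by k-means on a random cell subsample
#'
#' Draws a random subsample of cells from the merged view, runs k-means with
#' `m` centers on it, and returns the centroids as the initial anchor matrix
#' Y0. Deterministic given `seed`.
#'
#' @param merged an [omics_view()] (typically the merged view).
#' @param m number of anchors, `m <= n`.
#' @param seed integer seed.
#' @param subsample_size cells to subsample; default `min(n, max(5 m, 200))`.
#' @return d x m matrix of anchor columns.
#' @export
init_anchors <- function(merged, m, seed, subsample_size = NULL) {
  stopifnot(inherits(merged, "omics_view"))
  X <- as_dense(merged$matrix)
  n <- ncol(X)
  if (m > n) stop_config("m = %d anchors exceed the %d available cells", m, n)
  subsample_size <- subsample_size %||% min(n, max(5L * m, 200L))
  subsample_size <- max(subsample_size, m)
  set.seed(child_seed(seed, 11L))
  idx <- sort(sample.int(n, subsample_size))
  pts <- t(X[, idx, drop = FALSE])
  ndistinct <- nrow(unique(pts))
  if (ndistinct <= m) {
    # fewer distinct cells than anchors: the distinct columns are the centroids,
    # recycled to m (k-means would reject more centers than distinct points)
    ctr <- unique(pts)
    ctr <- ctr[rep_len(seq_len(nrow(ctr)), m), , drop = FALSE]
    return(t(ctr))
  }
  km <- kmeans(pts, centers = m, nstart = 5L, iter.max = 100L)
  t(km$centers)
}

#' Fit an omic-specific anchor graph
#'
#' Minimises `||X - Y Z||_F^2 + rho ||Z||_F^2` subject to the columns of Z
#' lying on the probability simplex, by alternating a Z-step (ridge solution
#' projected column-wise onto the simplex, with a projected-gradient fallback
#' that guarantees the objective never increases) and an optional Y-step
#' (ridge least-squares anchor refit, accepted only if non-increasing).
#'
#' @param view an [omics_view()].
#' @param Y0 d x m initial anchor matrix.
#' @param rho ridge weight on Z (>= 0).
#' @param max_iter outer iteration cap.
#' @param tol relative objective-change stopping threshold.
#' @param refit_anchors logical; `FALSE` freezes Y at `Y0`.
#' @return An `anchor_model`: list with `Y`, `Z`, `rho`, `objective_trace`.
#' @export
fit_specific_graph <- function(view, Y0, rho = 1.0, max_iter = 50L,
                               tol = 1e-8, refit_anchors = TRUE) {
  stopifnot(inherits(view, "omics_view"))
  X <- as_dense(view$matrix)
  Y <- as_dense(Y0)
  if (nrow(Y) != nrow(X)) stop_input("Y0 has %d rows but X has %d", nrow(Y), nrow(X))
  m <- ncol(Y); n <- ncol(X)
  obj <- function(Y, Z) fnorm2(X - Y %*% Z) + rho * fnorm2(Z)
  Z <- matrix(1 / m, m, n)
  trace <- obj(Y, Z)
  for (it in seq_len(max_iter)) {
    f_cur <- trace[length(trace)]
    # Z-step: ridge minimiser + simplex projection, guarded
    G <- crossprod(Y) + rho * diag(m)
    B <- crossprod(Y, X)
    Zprop <- project_columns_to_simplex(solve(G, B))
    if (obj(Y, Zprop) <= f_cur) {
      Z <- Zprop
    } else {
      # monotone fallback: projected gradient with step 1/L
      L <- 2 * (norm(G, type = "2"))
      for (s in 1:3) {
        grad <- 2 * (G %*% Z - B)
        Z <- project_columns_to_simplex(Z - grad / L)
      }
    }
    f_z <- obj(Y, Z)
    # Y-step: least-squares anchor refit, greedy-accepted
    if (refit_anchors) {
      ZZt <- tcrossprod(Z) + 1e-8 * diag(m)
      Yprop <- X %*% t(Z) %*% solve(ZZt)
      if (obj(Yprop, Z) <= f_z) Y <- Yprop
    }
    f_new <- obj(Y, Z)
    if (!is.finite(f_new)) stop_numerical("specific anchor-graph objective diverged")
    trace <- c(trace, f_new)
    if (abs(f_cur - f_new) <= tol * max(1, abs(f_cur))) break
  }
  structure(list(Y = Y, Z = Z, rho = rho, objective_trace = trace),
            class = "anchor_model")
}

#' @export
print.anchor_model <- function(x, ...) {
  cat(sprintf("<anchor_model> %d anchors x %d cells, objective %.4g after %d iterations\n",
              nrow(x$Z), ncol(x$Z), x$objective_trace[length(x$objective_trace)],
              length(x$objective_trace) - 1L))
  invisible(x)
}

# ---- shared-model block updates --------------------------------------------

#' Aggregate GCN outputs into a shared anchor-graph estimate
#'
#' The GCN's link to the shared model: `Zs = sum_i alpha_i Ys^T G_i^T` where
#' `G_i` is view i's n x d node representation. No simplex projection is
#' applied here.
#'
#' @param Ys d x m shared anchor matrix.
#' @param gcn_outputs list of n x d matrices.
#' @param alpha view weight vector.
#' @return m x n matrix.
#' @export
shared_Zs_from_gcn <- function(Ys, gcn_outputs, alpha) {
  stopifnot(length(gcn_outputs) == length(alpha))
  Reduce(`+`, Map(function(G, a) a * crossprod(Ys, t(G)), gcn_outputs, alpha))
}

#' Orthogonal-Procrustes update of a view's projection matrix
#'
#' Maximises `Tr(W^T X Zs^T Ys^T)` over `W^T W = I_d`: with thin SVD
#' `X Zs^T Ys^T = U S V^T`, the maximiser is `W = U V^T`.
#'
#' @param Xi d_i x n view matrix.
#' @param Ys d x m shared anchors.
#' @param Zs m x n shared graph.
#' @return d_i x d matrix with orthonormal columns.
#' @export
update_W <- function(Xi, Ys, Zs) {
  Xi <- as_dense(Xi)
  M <- Xi %*% t(Zs) %*% t(Ys)
  sv <- svd(M)
  if (min(sv$d) < 1e-12) {
    warning("near-rank-deficient Procrustes target in update_W")
  }
  sv$u %*% t(sv$v)
}

#' Orthogonal-Procrustes update of the shared anchors
#'
#' Maximises `Tr(Ys^T N)` with `N = sum_i alpha_i^2 W_i^T X_i Zs^T` over
#' `Ys^T Ys = I_m`; solved by the SVD of N as in [update_W()].
#'
#' @param views list of [omics_view()] (or plain matrices).
#' @param W list of d_i x d projections.
#' @param Zs m x n shared graph.
#' @param alpha view weights.
#' @return d x m matrix with orthonormal columns.
#' @export
update_Ys <- function(views, W, Zs, alpha) {
  mats <- lapply(views, view_matrix)
  N <- Reduce(`+`, Map(function(X, Wi, a) a^2 * crossprod(Wi, X) %*% t(Zs),
                       mats, W, alpha))
  sv <- svd(N)
  if (min(sv$d) < 1e-12) {
    warning("near-rank-deficient Procrustes target in update_Ys")
  }
  sv$u %*% t(sv$v)
}

view_matrix <- function(v) {
  if (inherits(v, "omics_view")) as_dense(v$matrix) else as_dense(v)
}

#' Closed-form update of the shared anchor graph
#'
#' With W, Ys and alpha fixed, the shared objective is a separable quadratic
#' in the columns of Zs; its constrained minimiser is the column-wise simplex
#' projection of `C = (sum_i alpha_i^2 Ys^T W_i^T X_i) / (sum_i alpha_i^2 +
#' ridge)`. `ridge = 1` accounts for the unit-weight `||Zs||_F^2` penalty of
#' the shared objective so the update is its exact block minimiser; `ridge =
#' 0` drops the penalty from the update.
#'
#' @param views list of views or matrices.
#' @param W list of projections.
#' @param Ys shared anchors.
#' @param alpha view weights on the simplex with `sum(alpha^2) > 0`.
#' @param ridge weight of the `||Zs||^2` term in the update (default 1).
#' @return m x n column-stochastic matrix.
#' @export
update_Zs <- function(views, W, Ys, alpha, ridge = 1) {
  stopifnot(sum(alpha^2) > 0)
  mats <- lapply(views, view_matrix)
  num <- Reduce(`+`, Map(function(X, Wi, a) a^2 * crossprod(Ys, crossprod(Wi, X)),
                         mats, W, alpha))
  C <- num / (sum(alpha^2) + ridge)
  project_columns_to_simplex(C)
}

#' Residual-inverse view weights
#'
#' Given per-view reconstruction residuals `O_i = ||X_i - W_i Ys Zs||_F^2`,
#' the simplex-constrained minimiser of `sum_i alpha_i^2 O_i` is
#' `alpha_i = (1/O_i) / sum_j (1/O_j)`. Views with exactly zero residual take
#' the limit: weight 1 split uniformly among the zero-residual views.
#'
#' @param O numeric vector of non-negative residuals.
#' @return Weight vector on the probability simplex.
#' @export
update_alpha <- function(O) {
  if (any(O < 0)) stop_input("residuals must be non-negative")
  if (any(O == 0)) {
    a <- as.numeric(O == 0)
    return(a / sum(a))
  }
  inv <- 1 / O
  inv / sum(inv)
}

#' Shared-model objective
#'
#' `sum_i alpha_i^2 ||X_i - W_i Ys Zs||_F^2 + ||Zs||_F^2`, returned together
#' with the per-view residuals `O_i`.
#'
#' @param views list of views or matrices.
#' @param W,Ys,Zs,alpha current blocks.
#' @return List with `value` and `O`.
#' @export
shared_objective <- function(views, W, Ys, Zs, alpha) {
  mats <- lapply(views, view_matrix)
  YsZs <- Ys %*% Zs
  O <- mapply(function(X, Wi) fnorm2(X - Wi %*% YsZs), mats, W)
  list(value = sum(alpha^2 * O) + fnorm2(Zs), O = as.numeric(O))
}
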