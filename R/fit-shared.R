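#' Cooperative fit of the shared anchor model
#'
#' Learns the shared anchors Ys, shared anchor graph Zs, per-view orthonormal
#' projections W_i and view weights alpha by interleaving two phases:
#'
#' * a **GCN phase**, one Adam gradient step per iteration on the per-view
#'   graph-convolution weights, minimising the shared objective with Zs tied
#'   to the GCN aggregation (see [shared_Zs_from_gcn()]);
#' * a **closed-form phase** every `validate_every` iterations: the
#'   simplex-projected GCN estimate of Zs is accepted into the model state if
#'   it lowers the objective, then one cycle of block updates runs
#'   ([update_W()] per view, [update_Zs()], [update_Ys()], [update_alpha()]),
#'   each of which is the exact minimiser of its block and therefore never
#'   increases the objective.
#'
#' The recorded `objective_trace` (one entry per closed-form cycle) is
#' non-increasing. The fit stops at `max_iterations` or when the relative
#' objective change between cycles drops below `tolerance`.
#'
#' @param views list of >= 2 [omics_view()]s over the same cells.
#' @param config a [run_config()].
#' @param Y0 initial anchor matrix from [init_anchors()] on the merged view
#'   (rows matching the view whose feature space Y0 lives in do not matter:
#'   Y0 is reduced to the shared dimension by truncated SVD).
#' @return A `shared_model`: list with `Ys`, `Zs`, `W`, `alpha`, `gcn`
#'   (weights, adjacency, inputs), `embed_dim`, `objective_trace`,
#'   `alpha_trace`, `O`.
#' @export
fit_shared <- function(views, config, Y0) {
  stopifnot(length(views) >= 2L)
  mats <- lapply(views, view_matrix)
  ns <- vapply(mats, ncol, 0L)
  if (length(unique(ns)) != 1L) stop_input("views disagree on cell count")
  n <- ns[1L]
  v <- length(views)
  m <- config$m
  d <- config$embed_dim
  check_anchor_budget(config, n)
  dims <- vapply(mats, nrow, 0L)
  if (d > min(dims)) {
    stop_config("embed_dim (%d) exceeds the smallest view dimension (%d)", d, min(dims))
  }
  set.seed(child_seed(config$seed, 23L))

  # --- initialisation --------------------------------------------------------
  # shared anchors: Y0 reduced to d rows by truncated SVD, then orthonormalised
  Y0 <- as_dense(Y0)
  sv0 <- svd(Y0, nu = min(d, ncol(Y0)), nv = 0)
  U0 <- sv0$u
  if (ncol(U0) < d) U0 <- cbind(U0, matrix(0, nrow(U0), d - ncol(U0)))
  P <- crossprod(U0, Y0)                       # d x m
  Ys <- qr.Q(qr(P + 1e-12 * diag(nrow(P))[, seq_len(ncol(P)), drop = FALSE]))
  if (ncol(Ys) < m) stop_numerical("could not orthonormalise initial shared anchors")
  Zs <- matrix(1 / m, m, n)
  alpha <- rep(1 / v, v)
  W <- lapply(mats, update_W, Ys = Ys, Zs = Zs)

  # GCN inputs: each view reduced to d-dimensional cell features by SVD
  H <- lapply(mats, function(X) {
    sv <- svd(X, nu = d, nv = d)
    t(X) %*% sv$u                              # n x d
  })
  A <- lapply(H, build_knn_adjacency, k = min(config$knn_k, n - 1L))
  S <- lapply(A, gcn_propagator)
  gcn_w <- lapply(seq_len(v), function(i) {
    set.seed(child_seed(config$seed, 100L + i))
    lapply(seq_len(config$gcn_layers), function(l) glorot_init(d, d))
  })
  adam <- lapply(gcn_w, adam_init)

  objective <- function(Zs_) shared_objective(mats, W, Ys, Zs_, alpha)
  cur <- objective(Zs)
  trace <- cur$value
  alpha_trace <- list(alpha)
  Zs_gcn <- NULL

  for (it in seq_len(config$max_iterations)) {
    # --- GCN phase: one Adam step per view on the aggregation-tied loss ------
    caches <- Map(function(Si, Hi, wi) gcn_forward_cache(Si, Hi, wi), S, H, gcn_w)
    G <- lapply(caches, `[[`, "out")
    Zs_gcn <- shared_Zs_from_gcn(Ys, G, alpha)
    M <- lapply(W, function(Wi) Wi %*% Ys)     # d_i x m
    R <- Map(function(X, Mi) X - Mi %*% Zs_gcn, mats, M)
    dZs <- 2 * Zs_gcn - 2 * Reduce(`+`, Map(function(Mi, Ri, a) a^2 * crossprod(Mi, Ri),
                                            M, R, alpha))
    for (i in seq_len(v)) {
      dG <- alpha[i] * t(Ys %*% dZs)           # n x d
      grads <- gcn_backward(S[[i]], caches[[i]], gcn_w[[i]], dG)
      st <- adam_step(gcn_w[[i]], grads, adam[[i]],
                      lr = config$gcn_lr, weight_decay = config$gcn_weight_decay)
      gcn_w[[i]] <- st$params
      adam[[i]] <- st$state
    }

    # --- closed-form phase ---------------------------------------------------
    if (it %% config$validate_every == 0L || it == config$max_iterations) {
      proposal <- project_columns_to_simplex(Zs_gcn)
      if (objective(proposal)$value < objective(Zs)$value) Zs <- proposal
      W <- lapply(mats, update_W, Ys = Ys, Zs = Zs)
      Zs <- update_Zs(mats, W, Ys, alpha)
      Ys <- update_Ys(mats, W, Zs, alpha)
      cur <- shared_objective(mats, W, Ys, Zs, alpha)
      alpha <- update_alpha(cur$O)
      cur <- shared_objective(mats, W, Ys, Zs, alpha)
      if (!is.finite(cur$value)) {
        stop_numerical("shared objective diverged (phase: closed-form cycle %d)",
                       length(trace))
      }
      f_prev <- trace[length(trace)]
      trace <- c(trace, cur$value)
      alpha_trace <- c(alpha_trace, list(alpha))
      if (abs(f_prev - cur$value) <= config$tolerance * max(1, abs(f_prev))) break
    }
  }

  structure(
    list(Ys = Ys, Zs = Zs, W = W, alpha = alpha,
         gcn = list(weights = gcn_w, adjacency = A, inputs = H),
         embed_dim = d, m = m,
         objective_trace = trace,
         alpha_trace = do.call(rbind, alpha_trace),
         O = cur$O),
    class = "shared_model"
  )
}

#' @export
print.shared_model <- function(x, ...) {
  cat(sprintf("<shared_model> %d anchors, %d cells, %d views; objective %.4g; alpha = %s\n",
              nrow(x$Zs), ncol(x$Zs), length(x$W),
              x$objective_trace[length(x$objective_trace)],
              paste(sprintf("%.3f", x$alpha), collapse = ", ")))
  invisible(x)
}
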