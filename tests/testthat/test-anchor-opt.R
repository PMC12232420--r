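# ---- anchor initialisation -------------------------------------------------

test_that("init_anchors recovers the centers of well-separated point masses", {
  set.seed(1)
  n <- 60
  centers <- cbind(c(10, 10, 10), c(-10, -10, -10))
  X <- centers[, rep(1:2, each = n / 2)] + matrix(rnorm(3 * n, sd = 1e-4), 3, n)
  v <- omics_view(abs(X) + 1, "rna")
  Y <- init_anchors(v, m = 2, seed = 7)
  got <- Y[, order(Y[1, ])]
  want <- vapply(split(seq_len(n), rep(1:2, each = n / 2)),
                 function(ix) rowMeans(abs(X[, ix]) + 1), numeric(3))
  want <- want[, order(want[1, ])]
  expect_equal(got, want, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("init_anchors is deterministic and validates the anchor budget", {
  dat <- tiny_paired_views(seed = 8)
  a <- init_anchors(dat$rna, 6, seed = 3)
  b <- init_anchors(dat$rna, 6, seed = 3)
  expect_identical(a, b)
  expect_error(init_anchors(dat$rna, 1000, seed = 3),
               class = "scanchor_config_error")
})

test_that("with one anchor per cell the anchors are a permutation of cells", {
  set.seed(2)
  X <- matrix(runif(3 * 5, 1, 9), 3, 5)
  v <- omics_view(X, "rna")
  Y <- init_anchors(v, m = 5, seed = 1, subsample_size = 5)
  # every anchor is one of the cell columns and every cell appears
  key <- function(M) apply(round(M, 9), 2, paste, collapse = ",")
  expect_setequal(key(Y), key(X))
})

# ---- specific anchor graphs ------------------------------------------------

test_that("fit_specific_graph respects the one-anchor simplex collapse", {
  dat <- tiny_paired_views(seed = 9, n = 20, d_rna = 8, d_atac = 8)
  v <- normalize_view(dat$rna)
  Y0 <- matrix(rowMeans(as.matrix(v$matrix)), ncol = 1)
  fit <- fit_specific_graph(v, Y0, rho = 0.5)
  expect_equal(fit$Z, matrix(1, 1, 20), ignore_attr = TRUE)
})

test_that("orthogonal columns with matching anchors reach zero objective", {
  X <- diag(4) * 3
  v <- omics_view(X, "rna")
  fit <- fit_specific_graph(v, X, rho = 0, refit_anchors = FALSE)
  final <- fit$objective_trace[length(fit$objective_trace)]
  # Z = I is feasible with objective 0; the fit must do at least as well
  expect_lt(final, 1e-10)
})

test_that("specific fit improves on the uniform-Z start and satisfies constraints", {
  set.seed(10)
  X <- matrix(abs(rnorm(10 * 50)), 10, 50)
  v <- omics_view(X, "rna")
  Y0 <- init_anchors(v, 5, seed = 2)
  fit <- fit_specific_graph(v, Y0, rho = 1)
  Zu <- matrix(1 / 5, 5, 50)
  f0 <- sum((X - Y0 %*% Zu)^2) + sum(Zu^2)
  expect_lte(fit$objective_trace[length(fit$objective_trace)], f0)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  expect_true(all(fit$Z >= 0))
  expect_equal(colSums(fit$Z), rep(1, 50), tolerance = 1e-8)
})

# ---- block updates against oracles -----------------------------------------

test_that("update_W fixes Procrustes identities and beats a 2x2 grid oracle", {
  Zs <- diag(2); Ys <- diag(2)            # M = Xi when d = m = 2
  expect_equal(update_W(diag(2), Ys, Zs), diag(2))
  Q <- matrix(c(cos(0.4), sin(0.4), -sin(0.4), cos(0.4)), 2, 2)
  expect_equal(update_W(Q, Ys, Zs), Q)
  set.seed(11)
  for (rep in 1:5) {
    M <- matrix(rnorm(4), 2, 2)
    W <- update_W(M, Ys, Zs)
    ours <- sum(diag(t(W) %*% M))
    thetas <- seq(0, 2 * pi, by = 0.001)
    best <- max(
      max(cos(thetas) * (M[1, 1] + M[2, 2]) + sin(thetas) * (M[2, 1] - M[1, 2])),
      max(cos(thetas) * (M[1, 1] - M[2, 2]) + sin(thetas) * (M[2, 1] + M[1, 2]))
    )
    expect_equal(ours, best, tolerance = 1e-3)
    expect_equal(crossprod(W), diag(2), tolerance = 1e-6)
  }
})

test_that("update_Ys attains a higher trace than random orthonormal samples", {
  set.seed(12)
  inst <- make_shared_instance(seed = 12)
  Ys <- update_Ys(inst$X, inst$W, inst$Zs, inst$alpha)
  N <- Reduce(`+`, Map(function(X, Wi, a) a^2 * crossprod(Wi, X) %*% t(inst$Zs),
                       inst$X, inst$W, inst$alpha))
  ours <- sum(diag(crossprod(Ys, N)))
  samples <- replicate(2000, sum(diag(crossprod(rand_orthonormal(4, 4), N))))
  expect_gte(ours, max(samples) - 1e-9)
  expect_equal(crossprod(Ys), diag(4), tolerance = 1e-6)
  # orthonormal fixed point
  Q <- rand_orthonormal(5, 3)
  sv <- svd(Q)
  expect_equal(sv$u %*% t(sv$v), Q, tolerance = 1e-9)
})

test_that("update_Zs is the constrained block minimiser of the shared objective", {
  set.seed(13)
  inst <- make_shared_instance(seed = 13)
  Zs <- update_Zs(inst$X, inst$W, inst$Ys, inst$alpha)
  expect_true(all(Zs >= 0))
  expect_equal(colSums(Zs), rep(1, inst$n), tolerance = 1e-8)
  f <- function(Z) shared_objective(inst$X, inst$W, inst$Ys, Z, inst$alpha)$value
  ours <- f(Zs)
  for (t in 1:300) expect_lte(ours, f(rand_feasible_Z(inst$m, inst$n)) + 1e-10)
})

test_that("update_Zs maps equal-information columns to uniform columns", {
  # identical cells: the target C has equal columns, each projecting to a
  # common simplex point; with zero signal the projection is uniform
  X <- list(matrix(0, 6, 10))
  W <- list(rand_orthonormal(6, 4))
  Ys <- rand_orthonormal(4, 3)
  Zs <- update_Zs(X, W, Ys, alpha = 1)
  expect_equal(Zs, matrix(1 / 3, 3, 10), tolerance = 1e-12)
})

test_that("update_alpha matches direct evaluation and a simplex-grid oracle", {
  expect_equal(update_alpha(c(1, 1)), c(0.5, 0.5))
  expect_equal(update_alpha(c(1, 3)), c(0.75, 0.25))
  expect_equal(update_alpha(c(0, 2, 0)), c(0.5, 0, 0.5))
  set.seed(14)
  for (rep in 1:5) {
    O <- runif(3, 0.2, 4)
    a <- update_alpha(O)
    expect_equal(sum(a), 1, tolerance = 1e-10)
    # 0.01-step grid over the 3-simplex
    g <- seq(0, 1, by = 0.01)
    grid_best <- Inf
    for (a1 in g) for (a2 in g[g <= 1 - a1 + 1e-12]) {
      a3 <- 1 - a1 - a2
      grid_best <- min(grid_best, a1^2 * O[1] + a2^2 * O[2] + a3^2 * O[3])
    }
    expect_lte(sum(a^2 * O), grid_best + 1e-12)
    expect_lt(grid_best - sum(a^2 * O), 1e-3)
  }
})

test_that("shared_objective matches a term-by-term brute-force evaluation", {
  set.seed(15)
  inst <- make_shared_instance(seed = 15)
  got <- shared_objective(inst$X, inst$W, inst$Ys, inst$Zs, inst$alpha)
  brute <- 0
  for (i in seq_along(inst$X)) {
    R <- inst$X[[i]] - inst$W[[i]] %*% inst$Ys %*% inst$Zs
    term <- 0
    for (r in seq_len(nrow(R))) for (cc in seq_len(ncol(R))) term <- term + R[r, cc]^2
    expect_equal(got$O[i], term, tolerance = 1e-10)
    brute <- brute + inst$alpha[i]^2 * term
  }
  expect_equal(got$value, brute + sum(inst$Zs^2), tolerance = 1e-10)
  # residuals do not depend on the weights
  got2 <- shared_objective(inst$X, inst$W, inst$Ys, inst$Zs, c(0.9, 0.1))
  expect_equal(got2$O, got$O)
  # perfect reconstruction leaves only the regulariser
  X0 <- Map(function(Wi) Wi %*% inst$Ys %*% inst$Zs, inst$W)
  expect_equal(shared_objective(X0, inst$W, inst$Ys, inst$Zs, inst$alpha)$value,
               sum(inst$Zs^2), tolerance = 1e-10)
})

# ---- GCN -------------------------------------------------------------------

test_that("gcn_forward collapses to layer-composed sigma(HW) on an edgeless graph", {
  set.seed(16)
  A <- matrix(0, 5, 5)
  H <- matrix(rnorm(5 * 3), 5, 3)
  W1 <- matrix(rnorm(9), 3, 3); W2 <- matrix(rnorm(6), 3, 2)
  out <- gcn_forward(A, H, list(W1, W2))
  expect_equal(out, pmax(H %*% W1, 0) %*% W2, tolerance = 1e-12)
})

test_that("gcn_forward matches the hand-computed 3-node path example", {
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  H <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  W <- matrix(c(1, 2), 2, 1)
  # D'^{-1/2} A' D'^{-1/2} with degrees (2, 3, 2); H W = (1, 2, 3) per node
  expected <- c(0.5 * 1 + 1 / sqrt(6) * 2,
                1 / sqrt(6) * 1 + 1 / 3 * 2 + 1 / sqrt(6) * 3,
                1 / sqrt(6) * 2 + 0.5 * 3)
  out <- gcn_forward(A, H, list(W))
  expect_equal(drop(out), expected, tolerance = 1e-12)
})

test_that("identical node rows on a complete graph yield identical outputs", {
  A <- 1 - diag(4)
  H <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  out <- gcn_forward(A, H, list(matrix(rnorm(9), 3, 3)))
  expect_equal(out[1, ], out[3, ], tolerance = 1e-12)
})

test_that("shared_Zs_from_gcn reduces correctly and matches the explicit sum", {
  set.seed(17)
  G <- matrix(rnorm(6 * 3), 6, 3)
  expect_equal(shared_Zs_from_gcn(diag(3), list(G), 1), t(G))
  expect_equal(shared_Zs_from_gcn(diag(3), list(G, G), c(0.5, 0.5)), t(G))
  Ys <- rand_orthonormal(4, 3)
  G2 <- matrix(rnorm(6 * 4), 6, 4)
  G1 <- matrix(rnorm(6 * 4), 6, 4)
  a <- c(0.3, 0.7)
  want <- a[1] * t(Ys) %*% t(G1) + a[2] * t(Ys) %*% t(G2)
  expect_equal(shared_Zs_from_gcn(Ys, list(G1, G2), a), want, tolerance = 1e-12)
})

# ---- cooperative shared fit ------------------------------------------------

test_that("fit_shared beats the planted parameters on noise-free data", {
  inst <- make_shared_instance(dims = c(20, 30), n = 50, m = 4, d = 4,
                               noise = 0, seed = 18)
  views <- lapply(inst$X, function(X) {
    omics_view(X - min(X), "rna", normalized = TRUE)
  })
  # re-plant after the shift so the planted objective is exact
  mats <- lapply(views, function(v) v$matrix)
  cfg <- run_config(n_clusters = 2, anchor_multiplier = 10, seed = 5,
                    max_iterations = 60, validate_every = 10, knn_k = 5,
                    use_merged_view = FALSE)
  cfg$m <- 4L; cfg$embed_dim <- 4L  # small planted instance
  Y0 <- init_anchors(views[[1]], 4, seed = 5)
  fit <- suppressWarnings(fit_shared(views, cfg, Y0))
  planted <- shared_objective(mats, inst$W, inst$Ys,
                              inst$Zs, inst$alpha)$value
  final <- fit$objective_trace[length(fit$objective_trace)]
  expect_lte(final, planted + sum(inst$Zs^2))
})

test_that("two identical views earn exactly equal weights", {
  dat <- tiny_paired_views(seed = 19, n = 40, d_rna = 20, d_atac = 20)
  v <- normalize_view(dat$rna)
  cfg <- run_config(n_clusters = 2, seed = 4, max_iterations = 40,
                    validate_every = 10, knn_k = 5, use_merged_view = FALSE)
  Y0 <- init_anchors(v, cfg$m, seed = 4)
  fit <- suppressWarnings(fit_shared(list(v, v), cfg, Y0))
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("fit_shared is bitwise reproducible for a fixed seed", {
  dat <- tiny_paired_views(seed = 20, n = 30, d_rna = 25, d_atac = 30)
  v1 <- normalize_view(dat$rna); v2 <- normalize_view(dat$atac)
  cfg <- run_config(n_clusters = 2, seed = 9, max_iterations = 30,
                    validate_every = 10, knn_k = 5, use_merged_view = FALSE)
  Y0 <- init_anchors(v1, cfg$m, seed = 9)
  f1 <- suppressWarnings(fit_shared(list(v1, v2), cfg, Y0))
  f2 <- suppressWarnings(fit_shared(list(v1, v2), cfg, Y0))
  expect_identical(f1$Zs, f2$Zs)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("each closed-form block alone never increases the shared objective", {
  set.seed(21)
  for (rep in 1:20) {
    inst <- make_shared_instance(dims = sample(c(8, 12), 2, TRUE), seed = 200 + rep,
                                 noise = 0.3)
    # random (non-optimal) starting blocks
    W <- lapply(inst$dims, function(di) rand_orthonormal(di, inst$d))
    Ys <- rand_orthonormal(inst$d, inst$m)
    Zs <- rand_feasible_Z(inst$m, inst$n)
    alpha <- update_alpha(runif(2, 0.5, 2))
    f0 <- shared_objective(inst$X, W, Ys, Zs, alpha)$value
    fW <- shared_objective(inst$X, lapply(inst$X, update_W, Ys = Ys, Zs = Zs),
                           Ys, Zs, alpha)$value
    fZ <- shared_objective(inst$X, W, Ys, update_Zs(inst$X, W, Ys, alpha),
                           alpha)$value
    fY <- shared_objective(inst$X, W, update_Ys(inst$X, W, Zs, alpha), Zs,
                           alpha)$value
    O <- shared_objective(inst$X, W, Ys, Zs, alpha)$O
    fA <- shared_objective(inst$X, W, Ys, Zs, update_alpha(O))$value
    expect_lte(fW, f0 + 1e-8)
    expect_lte(fZ, f0 + 1e-8)
    expect_lte(fY, f0 + 1e-8)
    expect_lte(fA, f0 + 1e-8)
  }
})
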