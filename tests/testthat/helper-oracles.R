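# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the implementation it checks.

# Exact simplex projection by KKT support enumeration (small vectors only):
# the optimum is v_S shifted by a common constant on some support S, zero off
# it; enumerate all supports and keep the feasible candidate closest to v.
simplex_qp_enum <- function(v) {
  m <- length(v)
  best <- NULL; best_d <- Inf
  for (mask in seq_len(2^m - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    shift <- (1 - sum(v[S])) / length(S)
    z <- numeric(m)
    z[S] <- v[S] + shift
    if (all(z[S] >= -1e-12)) {
      z <- pmax(z, 0)
      d2 <- sum((z - v)^2)
      if (d2 < best_d - 1e-15) { best_d <- d2; best <- z }
    }
  }
  best
}

# Simplex projection by bisection on the water-filling threshold tau with
# sum(pmax(v - tau, 0)) = 1 (monotone decreasing in tau).
simplex_qp_bisect <- function(v, iters = 200L) {
  lo <- min(v) - 1; hi <- max(v)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sum(pmax(v - mid, 0)) > 1) lo <- mid else hi <- mid
  }
  pmax(v - (lo + hi) / 2, 0)
}

# Pair-counting adjusted Rand index, O(n^2) explicit loop.
ari_pair_oracle <- function(p, q) {
  n <- length(p)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- p[i] == p[j]; sq <- q[i] == q[j]
      if (sp && sq) a <- a + 1
      else if (sp) b <- b + 1
      else if (sq) cc <- cc + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - b * cc) / denom
}

# Loop-based NMI with arithmetic-mean normalisation.
nmi_loop_oracle <- function(p, q) {
  n <- length(p)
  pu <- unique(p); qu <- unique(q)
  mi <- 0
  for (x in pu) {
    for (y in qu) {
      nij <- sum(p == x & q == y)
      if (nij > 0) {
        mi <- mi + (nij / n) * log((nij / n) / ((sum(p == x) / n) * (sum(q == y) / n)))
      }
    }
  }
  hx <- 0; for (x in pu) { px <- sum(p == x) / n; hx <- hx - px * log(px) }
  hy <- 0; for (y in qu) { py <- sum(q == y) / n; hy <- hy - py * log(py) }
  if (hx + hy == 0) return(1)
  mi / ((hx + hy) / 2)
}

# Hungarian accuracy by brute force over label bijections (small k).
acc_brute_oracle <- function(pred, truth) {
  pu <- unique(pred); tu <- unique(truth)
  k <- max(length(pu), length(tu))
  pu <- c(pu, rep(NA, k - length(pu)))
  tu <- c(tu, rep(NA, k - length(tu)))
  perms <- function(x) if (length(x) <= 1) list(x) else {
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i])) out <- c(out, list(c(x[i], rest)))
    }
    out
  }
  best <- 0
  for (pp in perms(seq_len(k))) {
    mapped <- tu[pp][match(pred, pu)]
    best <- max(best, sum(!is.na(mapped) & mapped == truth))
  }
  best / length(pred)
}

# Random matrix with orthonormal columns (QR of a Gaussian draw).
rand_orthonormal <- function(nr, nc) {
  qr.Q(qr(matrix(rnorm(nr * nc), nr, nc)))[, seq_len(nc), drop = FALSE]
}

# Random column-stochastic matrix (uniform Dirichlet columns).
rand_feasible_Z <- function(m, n) {
  Z <- matrix(-log(runif(m * n)), m, n)
  sweep(Z, 2, colSums(Z), "/")
}

# A small planted shared-model instance X_i = W_i Ys Zs + noise.
make_shared_instance <- function(dims = c(8, 12), n = 40, m = 4, d = 4,
                                 noise = 0.05, seed = 1) {
  set.seed(seed)
  Ys <- rand_orthonormal(d, m)
  Zs <- rand_feasible_Z(m, n)
  W <- lapply(dims, function(di) rand_orthonormal(di, d))
  X <- Map(function(Wi, di) Wi %*% Ys %*% Zs + noise * matrix(rnorm(di * n), di, n),
           W, dims)
  list(X = X, W = W, Ys = Ys, Zs = Zs,
       alpha = rep(1 / length(dims), length(dims)),
       dims = dims, n = n, m = m, d = d)
}

# One closed-form block cycle on raw matrices; returns the updated state.
closed_form_cycle <- function(X, W, Ys, Zs, alpha) {
  W <- lapply(X, update_W, Ys = Ys, Zs = Zs)
  Zs <- update_Zs(X, W, Ys, alpha)
  Ys <- update_Ys(X, W, Zs, alpha)
  alpha <- update_alpha(shared_objective(X, W, Ys, Zs, alpha)$O)
  list(W = W, Ys = Ys, Zs = Zs, alpha = alpha,
       value = shared_objective(X, W, Ys, Zs, alpha)$value)
}

# Small deterministic raw-count views for I/O and pipeline tests.
tiny_paired_views <- function(seed = 1, n = 60, k = 2, d_rna = 30, d_atac = 40,
                              ...) {
  generate_multiome(synthetic_spec(
    n_cells = n, n_clusters = k, d_rna = d_rna, d_atac = d_atac,
    rna_mean_separation = 1.5, dropout_rate = 0.2, seed = seed, ...))
}
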