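#' Complete a specific anchor graph with high-order shared structure
#'
#' Hadamard (elementwise) product of the high-order shared representation
#' with one omic's specific anchor graph: entries of the specific graph are
#' re-weighted by the shared structure, imputing cross-omic signal into the
#' modality-specific representation.
#'
#' @param Zs_prime m x n high-order shared representation.
#' @param Zspec m x n specific anchor graph.
#' @return m x n elementwise product.
#' @export
impute <- function(Zs_prime, Zspec) {
  Zs_prime <- as_dense(Zs_prime); Zspec <- as_dense(Zspec)
  if (!identical(dim(Zs_prime), dim(Zspec))) {
    stop_input("shape mismatch: %dx%d vs %dx%d",
               nrow(Zs_prime), ncol(Zs_prime), nrow(Zspec), ncol(Zspec))
  }
  Zs_prime * Zspec
}

#' Fuse the two imputed embeddings
#'
#' Convex combination `theta * Z_im1 + (1 - theta) * Z_im2` of the RNA- and
#' ATAC-side imputed embeddings; the default `theta = 0.5` is the balanced
#' 0.5:0.5 completion operator.
#'
#' @param Z_im1,Z_im2 m x n imputed embeddings.
#' @param theta weight on `Z_im1`, strictly inside (0, 1).
#' @return m x n fused embedding.
#' @export
fuse <- function(Z_im1, Z_im2, theta = 0.5) {
  if (!(is.numeric(theta) && length(theta) == 1L && theta > 0 && theta < 1)) {
    stop_config("theta must lie strictly inside (0, 1)")
  }
  Z_im1 <- as_dense(Z_im1); Z_im2 <- as_dense(Z_im2)
  if (!identical(dim(Z_im1), dim(Z_im2))) {
    stop_input("shape mismatch between imputed embeddings")
  }
  theta * Z_im1 + (1 - theta) * Z_im2
}

#' Cluster cells on the fused embedding
#'
#' k-means over the n columns of `Z_final` (cells as points in the m anchor
#' dimensions); best of `restarts` seeded initialisations by within-cluster
#' sum of squares. Deterministic given `seed`. Labels are 0-based.
#'
#' @param Z_final m x n fused embedding.
#' @param k number of clusters, `k <= n`.
#' @param seed integer seed.
#' @param restarts number of k-means restarts.
#' @return Integer vector of n labels in `0..k-1`.
#' @export
cluster_cells <- function(Z_final, k, seed = 1L, restarts = 10L) {
  Z_final <- as_dense(Z_final)
  n <- ncol(Z_final)
  if (k > n) stop_config("k = %d clusters exceed the %d cells", k, n)
  if (k == 1L) return(rep.int(0L, n))
  pts <- t(Z_final)
  ndistinct <- nrow(unique(pts))
  set.seed(child_seed(seed, 71L))
  if (ndistinct <= k) {
    # as many clusters as distinct points: assign by pattern identity
    ids <- match(apply(pts, 1L, paste, collapse = "\r"),
                 unique(apply(pts, 1L, paste, collapse = "\r")))
    return(as.integer(ids - 1L) %% k)
  }
  km <- kmeans(pts, centers = k, nstart = restarts, iter.max = 100L)
  as.integer(km$cluster - 1L)
}

#' Assemble a fusion result
#'
#' Runs [impute()] on both specific graphs, [fuse()]s them, clusters the
#' fused embedding, and returns everything downstream code needs.
#'
#' @param Zs_prime m x n high-order shared representation.
#' @param Z1,Z2 specific anchor graphs (RNA, ATAC).
#' @param theta fusion weight.
#' @param k cluster count.
#' @param seed,restarts clustering controls.
#' @return A `fusion_result`: list with `Z_im1`, `Z_im2`, `theta`, `Z_final`,
#'   `labels`, `n_clusters`.
#' @export
fuse_and_cluster <- function(Zs_prime, Z1, Z2, theta = 0.5, k, seed = 1L,
                             restarts = 10L) {
  Z_im1 <- impute(Zs_prime, Z1)
  Z_im2 <- impute(Zs_prime, Z2)
  Z_final <- fuse(Z_im1, Z_im2, theta)
  labels <- cluster_cells(Z_final, k, seed = seed, restarts = restarts)
  structure(
    list(Z_im1 = Z_im1, Z_im2 = Z_im2, theta = theta, Z_final = Z_final,
         labels = labels, n_clusters = as.integer(k)),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d cells in %d clusters (theta = %.2f)\n",
              length(x$labels), x$n_clusters, x$theta))
  invisible(x)
}
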