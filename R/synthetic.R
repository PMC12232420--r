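#' Specification of a paired two-view synthetic dataset
#'
#' Describes a planted-cluster paired multiome: one latent partition of the
#' cells drives both views. The RNA view draws over-dispersed
#' negative-binomial counts whose cluster log-means are separated by
#' `rna_mean_separation` latent standard deviations, then zeroes entries at
#' `dropout_rate` (dropout). The ATAC view is near-binary: each cluster owns
#' a designated block of peaks that open with probability `atac_open_prob_in`
#' in its cells and `atac_open_prob_out` elsewhere.
#'
#' The defaults define the package's reference study conditions: 300 cells,
#' 3 balanced clusters, 200 genes, 500 peaks, strong RNA separation (1.5),
#' NB dispersion 0.5, 30% dropout, peak-open rates 0.3 (in-cluster) vs 0.03.
#'
#' @param n_cells,n_clusters,d_rna,d_atac dataset dimensions (all feature
#'   counts must be >= `n_clusters`).
#' @param cluster_proportions simplex vector of length `n_clusters`.
#' @param rna_mean_separation distance between cluster log-mean centroids, in
#'   units of the latent SD.
#' @param rna_dispersion negative-binomial overdispersion (size = 1 /
#'   dispersion).
#' @param atac_open_prob_in,atac_open_prob_out Bernoulli open rates for
#'   in-cluster vs out-of-cluster peaks (`in > out` required).
#' @param dropout_rate RNA dropout probability in `[0, 1)`.
#' @param deterministic_proportions logical: make cluster sizes exactly
#'   proportional instead of multinomial draws.
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 300L, n_clusters = 3L,
                           d_rna = 200L, d_atac = 500L,
                           cluster_proportions = NULL,
                           rna_mean_separation = 1.5,
                           rna_dispersion = 0.5,
                           atac_open_prob_in = 0.3,
                           atac_open_prob_out = 0.03,
                           dropout_rate = 0.3,
                           deterministic_proportions = FALSE,
                           seed = 1L) {
  k <- as.integer(n_clusters)
  props <- cluster_proportions %||% rep(1 / k, k)
  if (length(props) != k || any(props <= 0) || abs(sum(props) - 1) > 1e-8) {
    stop_config("cluster_proportions must be a positive simplex vector of length %d", k)
  }
  if (!(atac_open_prob_in > atac_open_prob_out)) {
    stop_config("atac_open_prob_in must exceed atac_open_prob_out")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate must lie in [0, 1)")
  }
  if (min(d_rna, d_atac) < k) stop_config("all feature dimensions must be >= n_clusters")
  if (n_cells < 2L * k) stop_config("need at least 2 cells per cluster on average")
  structure(
    list(n_cells = as.integer(n_cells), n_clusters = k,
         d_rna = as.integer(d_rna), d_atac = as.integer(d_atac),
         cluster_proportions = props,
         rna_mean_separation = rna_mean_separation,
         rna_dispersion = rna_dispersion,
         atac_open_prob_in = atac_open_prob_in,
         atac_open_prob_out = atac_open_prob_out,
         dropout_rate = dropout_rate,
         deterministic_proportions = isTRUE(deterministic_proportions),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a paired synthetic multiome
#'
#' Draws labels, RNA counts and ATAC indicators per the spec; both views
#' share the same barcodes. Bitwise deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `rna` and `atac` ([omics_view()]s) and `labels`
#'   (integer vector in `1..n_clusters`).
#' @export
generate_multiome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; k <- spec$n_clusters
  if (spec$deterministic_proportions) {
    sizes <- floor(spec$cluster_proportions * n)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    labels <- rep(seq_len(k), times = sizes)
  } else {
    labels <- sample(seq_len(k), n, replace = TRUE, prob = spec$cluster_proportions)
    # every planted cluster must be populated
    empty <- setdiff(seq_len(k), unique(labels))
    for (cl in empty) labels[sample.int(n, 1L)] <- cl
  }
  barcodes <- sprintf("cell-%04d", seq_len(n))

  # RNA: NB counts with cluster-shifted log-means, then dropout
  base_logmu <- rnorm(spec$d_rna, mean = 1.0, sd = 0.5)
  shifts <- matrix(rnorm(spec$d_rna * k, 0, 1), spec$d_rna, k)
  shifts <- sweep(shifts, 1L, rowMeans(shifts))   # centre so separation is relative
  mu <- exp(base_logmu + spec$rna_mean_separation * shifts[, labels, drop = FALSE])
  size <- 1 / max(spec$rna_dispersion, 1e-8)
  rna <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                spec$d_rna, n)
  if (spec$dropout_rate > 0) {
    keep <- matrix(runif(length(rna)) >= spec$dropout_rate, spec$d_rna, n)
    rna <- rna * keep
  }

  # ATAC: block-structured Bernoulli openings
  block <- rep(seq_len(k), length.out = spec$d_atac)  # peak -> owning cluster
  p <- matrix(spec$atac_open_prob_out, spec$d_atac, n)
  p[block[row(p)] == labels[col(p)]] <- spec$atac_open_prob_in
  atac <- matrix(rbinom(length(p), 1L, as.vector(p)), spec$d_atac, n)

  list(
    rna = omics_view(rna, "rna",
                     sprintf("gene-%04d", seq_len(spec$d_rna)), barcodes),
    atac = omics_view(atac, "atac",
                      sprintf("peak-%04d", seq_len(spec$d_atac)), barcodes),
    labels = as.integer(labels)
  )
}
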