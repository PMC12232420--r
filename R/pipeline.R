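#' Run the full anchor-graph clustering pipeline
#'
#' Orchestrates every stage: read (or accept) the two raw views, normalise,
#' build the merged view, initialise anchors, fit the two omic-specific
#' anchor graphs, fit the shared model cooperatively, propagate the shared
#' graph through the hierarchical attention stage, complete the specific
#' graphs by Hadamard imputation, fuse, cluster, and (when ground truth is
#' available) evaluate. Two ablation switches mirror the stage structure:
#' `mac_only` clusters the shared anchor graph directly (no attention, no
#' fusion) and `no_hgat` replaces the high-order representation by all-ones
#' so the imputation is the identity.
#'
#' @param config a [run_config()].
#' @param rna,atac [omics_view()]s of raw counts, or file paths understood by
#'   [read_view()] (MTX triplets or dense delimited).
#' @param labels optional ground-truth labels: a vector aligned with the
#'   barcodes or a two-column TSV path.
#' @param out_dir optional output directory; when given, labels TSV,
#'   embedding CSV, metrics JSON and a run manifest are written there
#'   (partial outputs are removed if a stage fails).
#' @param no_hgat,mac_only ablation switches (see above).
#' @param format on-disk format when `rna`/`atac` are paths.
#' @return A `run_manifest`: list with `config`, `labels` (predicted,
#'   0-based), `embedding` (m x n), `fusion`, `shared`, `specific`,
#'   `metrics` (`NULL` without truth), `stage_seconds`, `input_digests`,
#'   `output_paths`.
#' @export
run_pipeline <- function(config, rna, atac, labels = NULL, out_dir = NULL,
                         no_hgat = FALSE, mac_only = FALSE,
                         format = c("mtx", "dense_delimited")) {
  format <- match.arg(format)
  stopifnot(inherits(config, "run_config"))
  timings <- numeric(0)
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    value
  }
  digests <- list()
  written <- character()
  on_failure <- function(e) {
    for (p in written) if (file.exists(p)) unlink(p)
    stop(e)
  }

  tryCatch({
    if (is.character(rna)) {
      digests$rna <- unname(tools::md5sum(rna))
      rna <- tick("read_rna", read_view(rna, format, "rna"))
    }
    if (is.character(atac)) {
      digests$atac <- unname(tools::md5sum(atac))
      atac <- tick("read_atac", read_view(atac, format, "atac"))
    }
    stopifnot(inherits(rna, "omics_view"), inherits(atac, "omics_view"))
    if (is.character(labels)) labels <- read_labels(labels, rna$barcodes)
    n <- ncol(rna$matrix)
    check_anchor_budget(config, n)

    rna_n <- tick("normalize", {
      a <- if (rna$normalized) rna else normalize_view(rna)
      a
    })
    atac_n <- if (atac$normalized) atac else normalize_view(atac)
    merged <- tick("merge", make_merged_view(rna_n, atac_n))

    Y0 <- tick("init_anchors", init_anchors(merged, config$m, config$seed))

    # the merged-view anchors restrict to each omic's feature block
    d1 <- nrow(rna_n$matrix)
    spec_rna <- tick("specific_rna",
                     fit_specific_graph(rna_n, Y0[seq_len(d1), , drop = FALSE],
                                        rho = config$rho,
                                        refit_anchors = config$refit_anchors))
    spec_atac <- tick("specific_atac",
                      fit_specific_graph(atac_n, Y0[-seq_len(d1), , drop = FALSE],
                                         rho = config$rho,
                                         refit_anchors = config$refit_anchors))

    views <- if (config$use_merged_view) list(rna_n, atac_n, merged) else list(rna_n, atac_n)
    shared <- tick("fit_shared", fit_shared(views, config, Y0))

    if (mac_only) {
      final_labels <- tick("cluster", cluster_cells(shared$Zs, config$n_clusters,
                                                    seed = config$seed,
                                                    restarts = config$restarts))
      fusion <- NULL
      embedding <- shared$Zs
    } else {
      Zs_prime <- if (no_hgat) {
        matrix(1, nrow(shared$Zs), ncol(shared$Zs))
      } else {
        tick("hgat", run_hgat(shared$Zs, layers = config$gat_layers,
                              heads = config$gat_heads,
                              knn_k = config$knn_k, seed = config$seed))
      }
      fusion <- tick("fuse_cluster",
                     fuse_and_cluster(Zs_prime, spec_rna$Z, spec_atac$Z,
                                      theta = config$theta, k = config$n_clusters,
                                      seed = config$seed, restarts = config$restarts))
      final_labels <- fusion$labels
      embedding <- fusion$Z_final
    }

    metrics <- NULL
    if (!is.null(labels)) {
      metrics <- tick("metrics", compute_report(final_labels, labels, embedding))
    }

    out_paths <- list()
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      out_paths$labels <- file.path(out_dir, "labels.tsv")
      written <- c(written, out_paths$labels)
      write.table(data.frame(barcode = rna$barcodes, cluster = final_labels),
                  out_paths$labels, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      out_paths$embedding <- file.path(out_dir, "embedding.csv")
      written <- c(written, out_paths$embedding)
      emb <- embedding
      dimnames(emb) <- list(sprintf("anchor-%d", seq_len(nrow(emb))), rna$barcodes)
      write.table(emb, out_paths$embedding, sep = ",", quote = FALSE, col.names = NA)
      if (!is.null(metrics)) {
        out_paths$metrics <- file.path(out_dir, "metrics.json")
        written <- c(written, out_paths$metrics)
        jsonlite::write_json(report_as_list(metrics), out_paths$metrics,
                             auto_unbox = TRUE, digits = NA)
      }
      out_paths$manifest <- file.path(out_dir, "manifest.json")
      written <- c(written, out_paths$manifest)
      jsonlite::write_json(
        list(config = unclass(config), seed = config$seed,
             input_digests = digests,
             ablation = list(no_hgat = no_hgat, mac_only = mac_only),
             objective_trace = shared$objective_trace,
             specific_traces = list(rna = spec_rna$objective_trace,
                                    atac = spec_atac$objective_trace),
             alpha = shared$alpha,
             stage_seconds = as.list(timings),
             output_paths = out_paths),
        out_paths$manifest, auto_unbox = TRUE, digits = NA)
    }

    structure(
      list(config = config, labels = final_labels, embedding = embedding,
           fusion = fusion, shared = shared,
           specific = list(rna = spec_rna, atac = spec_atac),
           metrics = metrics, stage_seconds = timings,
           input_digests = digests, output_paths = out_paths,
           ablation = list(no_hgat = no_hgat, mac_only = mac_only)),
      class = "run_manifest"
    )
  }, scanchor_error = on_failure)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d cells -> %d clusters (seed %d)\n",
              length(x$labels), x$config$n_clusters, x$config$seed))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
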