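#' Construct an omics view
#'
#' An `omics_view` holds one modality's feature-by-cell matrix together with
#' feature names and cell barcodes. Columns are cells throughout the package;
#' a view of the RNA modality is the d1 x n gene-by-cell matrix X1, the ATAC
#' modality the d2 x n peak-by-cell matrix X2, and `merged` their row-wise
#' concatenation.
#'
#' @param matrix feature x cell numeric matrix (base or `Matrix` sparse);
#'   non-negative when holding raw counts.
#' @param modality one of `"rna"`, `"atac"`, `"merged"`.
#' @param feature_names character vector, one per row; generated if `NULL`.
#' @param barcodes character vector, one per column, unique; generated if
#'   `NULL`.
#' @param normalized logical flag recording whether [normalize_view()] has
#'   already been applied (guards against silent double normalisation).
#' @return An object of class `omics_view`.
#' @export
omics_view <- function(matrix, modality = c("rna", "atac", "merged"),
                       feature_names = NULL, barcodes = NULL,
                       normalized = FALSE) {
  modality <- match.arg(modality)
  if (!(is.matrix(matrix) || is(matrix, "Matrix"))) {
    stop_input("matrix must be a base matrix or a Matrix object")
  }
  d <- nrow(matrix); n <- ncol(matrix)
  if (d < 1L || n < 2L) {
    stop_input("view must have at least 1 feature and 2 cells (got %d x %d)", d, n)
  }
  feature_names <- feature_names %||% sprintf("%s-feature-%d", modality, seq_len(d))
  barcodes <- barcodes %||% sprintf("cell-%d", seq_len(n))
  if (length(feature_names) != d) {
    stop_format("feature name count (%d) does not match row count (%d)",
                length(feature_names), d)
  }
  if (length(barcodes) != n) {
    stop_format("barcode count (%d) does not match column count (%d)",
                length(barcodes), n)
  }
  if (anyDuplicated(barcodes)) stop_format("barcodes must be unique")
  vals <- if (is(matrix, "sparseMatrix")) matrix@x else matrix
  if (length(vals) && !all(is.finite(vals))) {
    stop_input("view matrix contains NaN/Inf")
  }
  if (!normalized && length(vals) && any(vals < 0)) {
    stop_input("raw count matrix must be non-negative")
  }
  structure(
    list(matrix = matrix, modality = modality,
         feature_names = as.character(feature_names),
         barcodes = as.character(barcodes),
         normalized = isTRUE(normalized)),
    class = "omics_view"
  )
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("<omics_view> %s: %d features x %d cells%s\n",
              x$modality, nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @export
dim.omics_view <- function(x) dim(x$matrix)

#' Run configuration
#'
#' Collects every tunable of the pipeline. `m = anchor_multiplier *
#' n_clusters` anchors summarise the n cells; the shared embedding dimension
#' `embed_dim` defaults to m (the smallest value compatible with the
#' orthonormal shared-anchor constraint).
#'
#' @param n_clusters number of clusters k (>= 1).
#' @param anchor_multiplier anchors per cluster; one of 10, 20, 30, 40, 50, 60.
#' @param theta fusion weight on the RNA-side imputed embedding, in (0, 1).
#' @param rho ridge weight on the specific anchor graphs.
#' @param gcn_layers,gcn_lr,gcn_weight_decay GCN depth and Adam settings.
#' @param max_iterations total iteration budget of the shared fit.
#' @param validate_every closed-form cycle (and logging) period, iterations.
#' @param gat_layers,gat_heads attention depth and head count.
#' @param knn_k neighbourhood size for all kNN graphs.
#' @param seed integer seed controlling every random draw.
#' @param tolerance relative objective-change stopping threshold.
#' @param embed_dim shared embedding dimension d (>= m); `NULL` means m.
#' @param refit_anchors logical: refit specific anchors Y each cycle.
#' @param use_merged_view logical: include the merged view as a third view in
#'   the shared model.
#' @param train_gat logical: take gradient steps on the attention parameters
#'   (default `FALSE`: fixed random-feature propagation).
#' @param restarts k-means restarts for the final clustering.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_clusters,
                       anchor_multiplier = 10L,
                       theta = 0.5,
                       rho = 1.0,
                       gcn_layers = 2L,
                       gcn_lr = 0.01,
                       gcn_weight_decay = 5e-3,
                       max_iterations = 1000L,
                       validate_every = 30L,
                       gat_layers = 2L,
                       gat_heads = 3L,
                       knn_k = 15L,
                       seed = 1L,
                       tolerance = 1e-6,
                       embed_dim = NULL,
                       refit_anchors = TRUE,
                       use_merged_view = TRUE,
                       train_gat = FALSE,
                       restarts = 10L) {
  if (!is.numeric(n_clusters) || n_clusters < 1) {
    stop_config("n_clusters must be a positive integer")
  }
  if (!anchor_multiplier %in% c(10L, 20L, 30L, 40L, 50L, 60L)) {
    stop_config("anchor_multiplier must be one of 10, 20, 30, 40, 50, 60")
  }
  if (!(theta > 0 && theta < 1)) stop_config("theta must lie in (0, 1)")
  if (rho < 0) stop_config("rho must be non-negative")
  m <- as.integer(anchor_multiplier) * as.integer(n_clusters)
  d <- as.integer(embed_dim %||% m)
  if (d < m) stop_config("embed_dim (%d) must be >= number of anchors m (%d)", d, m)
  structure(
    list(n_clusters = as.integer(n_clusters),
         anchor_multiplier = as.integer(anchor_multiplier),
         m = m, embed_dim = d,
         theta = theta, rho = rho,
         gcn_layers = as.integer(gcn_layers), gcn_lr = gcn_lr,
         gcn_weight_decay = gcn_weight_decay,
         max_iterations = as.integer(max_iterations),
         validate_every = as.integer(validate_every),
         gat_layers = as.integer(gat_layers), gat_heads = as.integer(gat_heads),
         knn_k = as.integer(knn_k), seed = as.integer(seed),
         tolerance = tolerance,
         refit_anchors = isTRUE(refit_anchors),
         use_merged_view = isTRUE(use_merged_view),
         train_gat = isTRUE(train_gat),
         restarts = as.integer(restarts)),
    class = "run_config"
  )
}

check_anchor_budget <- function(config, n) {
  if (config$m > n) {
    stop_config("m = %d anchors exceed the %d available cells", config$m, n)
  }
  invisible(config)
}

#' Read a run configuration from a flat key:value text file
#'
#' Lines look like `n_clusters: 3`; unknown keys raise a format error; `#`
#' comments and blank lines are ignored.
#'
#' @param path file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop_format("unparseable config line: %s", lines[bad][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop_format("unknown config key(s): %s",
                                   paste(unknown, collapse = ", "))
  args <- lapply(vals, function(v) {
    if (v %in% c("TRUE", "FALSE", "true", "false")) return(as.logical(toupper(v)))
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(args) <- keys
  do.call(run_config, args)
}

# ---- file I/O --------------------------------------------------------------

#' Read a view from disk
#'
#' Two layouts are supported. `mtx`: a MatrixMarket file plus companion
#' feature and barcode TSVs (first column used), cellranger-style
#' (`features.tsv`/`barcodes.tsv` next to the `.mtx`, or explicit paths).
#' On-disk orientation is inferred from companion lengths: whichever matrix
#' dimension matches the feature count becomes rows. `dense_delimited`: a
#' CSV/TSV with a header row of barcodes and feature names in the first
#' column.
#'
#' @param path matrix file path.
#' @param format `"mtx"` or `"dense_delimited"`.
#' @param modality passed to [omics_view()].
#' @param features_path,barcodes_path companion files for `mtx`; default to
#'   `features.tsv` / `barcodes.tsv` in `path`'s directory.
#' @param transpose orientation override: `NA` (infer), `TRUE` (on-disk rows
#'   are cells), `FALSE` (on-disk rows are features).
#' @param sep field separator for `dense_delimited` (default inferred from
#'   extension: `,` for `.csv`, tab otherwise).
#' @return An [omics_view()].
#' @export
read_view <- function(path, format = c("mtx", "dense_delimited"),
                      modality = c("rna", "atac", "merged"),
                      features_path = NULL, barcodes_path = NULL,
                      transpose = NA, sep = NULL) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop_input("matrix file not found: %s", path)
  if (format == "mtx") {
    dirn <- dirname(path)
    features_path <- features_path %||% file.path(dirn, "features.tsv")
    barcodes_path <- barcodes_path %||% file.path(dirn, "barcodes.tsv")
    if (!file.exists(features_path)) stop_input("feature file not found: %s", features_path)
    if (!file.exists(barcodes_path)) stop_input("barcode file not found: %s", barcodes_path)
    mat <- Matrix::readMM(path)
    # binary matrices come back as value-less pattern matrices
    if (is(mat, "nMatrix") || is(mat, "lMatrix")) mat <- mat * 1
    feats <- read.table(features_path, sep = "\t", header = FALSE,
                        colClasses = "character")[[1]]
    bcs <- read.table(barcodes_path, sep = "\t", header = FALSE,
                      colClasses = "character")[[1]]
    df <- length(feats); nb <- length(bcs)
    orient <- if (is.na(transpose)) {
      if (nrow(mat) == df && ncol(mat) == nb) FALSE
      else if (nrow(mat) == nb && ncol(mat) == df) TRUE
      else stop_format(paste0(
        "matrix is %d x %d but companions list %d features and %d barcodes"),
        nrow(mat), ncol(mat), df, nb)
    } else isTRUE(transpose)
    if (orient) mat <- Matrix::t(mat)
    if (nrow(mat) != df || ncol(mat) != nb) {
      stop_format("matrix is %d x %d after orientation but companions list %d features and %d barcodes",
                  nrow(mat), ncol(mat), df, nb)
    }
    omics_view(as(mat, "CsparseMatrix"), modality, feats, bcs)
  } else {
    sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
    df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                     check.names = FALSE)
    mat <- as.matrix(df)
    if (!is.numeric(mat)) stop_format("dense matrix contains non-numeric entries")
    omics_view(mat, modality, rownames(df), colnames(df))
  }
}

#' Write a view to disk
#'
#' Inverse of [read_view()]: `mtx` writes `matrix.mtx` (or the given file
#' name) plus `features.tsv` and `barcodes.tsv`; `dense_delimited` writes one
#' delimited table with a barcode header and feature row names.
#'
#' @param view an [omics_view()].
#' @param path output matrix file path (its directory receives companions for
#'   `mtx`).
#' @param format `"mtx"` or `"dense_delimited"`.
#' @return `path`, invisibly.
#' @export
write_view <- function(view, path, format = c("mtx", "dense_delimited")) {
  format <- match.arg(format)
  stopifnot(inherits(view, "omics_view"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(as(as(view$matrix, "CsparseMatrix"), "generalMatrix"), path)
    dirn <- dirname(path)
    writeLines(view$feature_names, file.path(dirn, "features.tsv"))
    writeLines(view$barcodes, file.path(dirn, "barcodes.tsv"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    m <- as_dense(view$matrix)
    dimnames(m) <- list(view$feature_names, view$barcodes)
    write.table(m, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Read ground-truth labels
#'
#' Two-column TSV (barcode, label), no header. Labels are returned in the
#' order of `barcodes` when given.
#'
#' @param path TSV path.
#' @param barcodes optional barcode order to align to.
#' @return Character vector of labels (named by barcode).
#' @export
read_labels <- function(path, barcodes = NULL) {
  if (!file.exists(path)) stop_input("label file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_format("label file must have two columns (barcode, label)")
  labels <- stats::setNames(df[[2]], df[[1]])
  if (!is.null(barcodes)) {
    missing <- setdiff(barcodes, names(labels))
    if (length(missing)) {
      stop_format("labels missing for %d barcode(s), e.g. %s",
                  length(missing), missing[1])
    }
    labels <- labels[barcodes]
  }
  labels
}

# ---- normalisation ---------------------------------------------------------

#' Normalise a view
#'
#' Modality-specific transforms of raw counts. RNA: per-cell library-size
#' scaling to the median library size (or `target_scale`) followed by
#' log(1+x). ATAC: TF-IDF weighting (term frequency per cell times
#' log-inverse document frequency per peak). Merged views are normalised by
#' normalising the parts they were stacked from, so calling this on a merged
#' view is rejected; build merged views from normalised parts with
#' [make_merged_view()]. All-zero columns are left as zeros.
#'
#' @param view an [omics_view()] holding raw counts.
#' @param target_scale RNA library-size target; default median library size.
#' @return A normalised [omics_view()] with the `normalized` flag set.
#' @export
normalize_view <- function(view, target_scale = NULL) {
  stopifnot(inherits(view, "omics_view"))
  if (view$normalized) {
    stop_input("view is already normalized; refusing to double-apply")
  }
  X <- view$matrix
  total <- sum(X)
  if (total == 0) stop_input("all-zero matrix cannot be normalized")
  if (view$modality == "rna") {
    libs <- Matrix::colSums(X)
    scale_to <- target_scale %||% stats::median(libs[libs > 0])
    sf <- ifelse(libs > 0, scale_to / libs, 0)
    Xn <- as_dense(X) %*% diag(sf, length(sf))
    Xn <- log1p(Xn)
  } else if (view$modality == "atac") {
    # TF-IDF: tf = per-cell frequency, idf = log(1 + n / (1 + peak count))
    Xd <- as_dense(X)
    libs <- colSums(Xd)
    tf <- sweep(Xd, 2, ifelse(libs > 0, libs, 1), "/")
    df <- rowSums(Xd > 0)
    idf <- log1p(ncol(Xd) / (1 + df))
    Xn <- tf * idf
  } else {
    stop_input("merged views are built from normalized parts; normalize rna/atac first")
  }
  check_finite(Xn, "normalized matrix")
  omics_view(Xn, view$modality, view$feature_names, view$barcodes,
             normalized = TRUE)
}

#' Stack two views into a merged view
#'
#' Row-wise concatenation (RNA features first) of two views over the same
#' cells, forming the merged view that enters the shared model as a third
#' view.
#'
#' @param rna,atac views with identical barcode order.
#' @return A merged [omics_view()].
#' @export
make_merged_view <- function(rna, atac) {
  stopifnot(inherits(rna, "omics_view"), inherits(atac, "omics_view"))
  if (!identical(rna$barcodes, atac$barcodes)) {
    stop_input("views are not aligned: barcode order differs")
  }
  if (rna$normalized != atac$normalized) {
    stop_input("cannot merge a normalized with an unnormalized view")
  }
  mat <- rbind(as_dense(rna$matrix), as_dense(atac$matrix))
  omics_view(mat, "merged",
             c(rna$feature_names, atac$feature_names),
             rna$barcodes, normalized = rna$normalized)
}
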