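# Shortest-augmenting-path solution of the square min-cost assignment
# problem (O(n^3)); returns the assigned column for each row.
hungarian_min <- function(C) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- -1L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- C[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  cols <- integer(n)
  for (j in seq_len(n)) cols[p[j + 1L]] <- j
  cols
}

contingency <- function(pred, truth) {
  table(factor(pred), factor(truth))
}

#' Hungarian-matched clustering accuracy
#'
#' Finds the one-to-one correspondence between predicted and true labels that
#' maximises the number of agreeing cells (rectangular label sets allowed by
#' zero-padding) and returns the matched proportion together with the
#' mapping.
#'
#' @param pred,truth equal-length label vectors (any atomic type).
#' @return List with `acc` (in `[0,1]`) and `mapping` (named character
#'   vector, predicted level -> matched true level; `NA` for predicted
#'   clusters left unmatched).
#' @export
hungarian_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_input("pred (%d) and truth (%d) differ in length", length(pred), length(truth))
  }
  if (length(pred) < 1L) stop_input("need at least one cell")
  ct <- contingency(pred, truth)
  r <- nrow(ct); c <- ncol(ct); s <- max(r, c)
  counts <- matrix(0, s, s)
  counts[seq_len(r), seq_len(c)] <- ct
  cols <- hungarian_min(max(counts) - counts)
  matched <- sum(counts[cbind(seq_len(s), cols)])
  mapping <- rep(NA_character_, r)
  names(mapping) <- rownames(ct)
  for (i in seq_len(r)) if (cols[i] <= c) mapping[i] <- colnames(ct)[cols[i]]
  list(acc = matched / length(pred), mapping = mapping)
}

#' Normalized mutual information
#'
#' Mutual information of the two label partitions normalised by the
#' arithmetic mean of their entropies (natural log). Two trivial one-cluster
#' partitions score 1; a zero normaliser otherwise scores 0.
#'
#' @param pred,truth equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi_score <- function(pred, truth) {
  ct <- as.matrix(contingency(pred, truth))
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj_[col(pij)[nz]])))
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  denom <- (hx + hy) / 2
  if (denom == 0) return(if (hx == 0 && hy == 0) 1 else 0)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement adjusted for chance via the contingency-table
#' formula; returns 1 when the index is degenerate (both partitions trivial).
#'
#' @param pred,truth equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
ari_score <- function(pred, truth) {
  ct <- as.matrix(contingency(pred, truth))
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (maxi - expected)
}

#' Full clustering evaluation report
#'
#' Computes Hungarian-matched accuracy, NMI (arithmetic-mean normalisation),
#' ARI, and precision/recall/F1 macro-averaged over the true classes after
#' applying the Hungarian mapping. When an embedding is supplied, the mean
#' silhouette of the cells under the predicted labels (Euclidean distance) is
#' added; a single predicted cluster makes the silhouette undefined, which is
#' reported as an error flag rather than a number.
#'
#' @param pred,truth equal-length label vectors.
#' @param embedding optional m x n matrix (cells as columns) for the
#'   silhouette.
#' @return An `evaluation_report`: list with `acc`, `nmi`, `ari`, `f1`,
#'   `precision`, `recall`, `s_score` (`NA` + `s_score_error = TRUE` when
#'   undefined), and `mapping`.
#' @export
compute_report <- function(pred, truth, embedding = NULL) {
  hm <- hungarian_accuracy(pred, truth)
  mapped <- unname(hm$mapping[as.character(pred)])
  classes <- levels(factor(truth))
  prf <- vapply(classes, function(cl) {
    tp <- sum(mapped == cl & truth == cl, na.rm = TRUE)
    np <- sum(mapped == cl, na.rm = TRUE)
    nt <- sum(truth == cl)
    prec <- if (np > 0) tp / np else 0
    rec <- if (nt > 0) tp / nt else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  s_score <- NA_real_
  s_err <- FALSE
  if (!is.null(embedding)) {
    if (length(unique(pred)) < 2L) {
      s_err <- TRUE
    } else {
      sil <- cluster::silhouette(as.integer(factor(pred)),
                                 dist(t(as_dense(embedding))))
      s_score <- mean(sil[, "sil_width"])
    }
  }
  structure(
    list(acc = hm$acc,
         nmi = nmi_score(pred, truth),
         ari = ari_score(pred, truth),
         precision = mean(prf[1, ]),
         recall = mean(prf[2, ]),
         f1 = mean(prf[3, ]),
         s_score = s_score,
         s_score_error = s_err,
         mapping = hm$mapping),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> ACC %.4f | NMI %.4f | ARI %.4f | F1 %.4f | P %.4f | R %.4f | S %s\n",
    x$acc, x$nmi, x$ari, x$f1, x$precision, x$recall,
    if (is.na(x$s_score)) "undefined" else sprintf("%.4f", x$s_score)))
  invisible(x)
}

# JSON-serialisable view of a report (mapping as a named list).
report_as_list <- function(report) {
  list(acc = report$acc, nmi = report$nmi, ari = report$ari,
       f1 = report$f1, precision = report$precision, recall = report$recall,
       s_score = if (report$s_score_error) "undefined" else report$s_score,
       mapping = as.list(report$mapping))
}
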