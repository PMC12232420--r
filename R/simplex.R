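#' Euclidean projection of matrix columns onto the probability simplex
#'
#' Every anchor graph in the model is constrained column-wise to
#' `{z >= 0, sum(z) = 1}`. This routine maps each column of `M` to its
#' nearest point on that simplex (sort-and-threshold water-filling: find the
#' largest support whose shifted entries stay positive, subtract the common
#' threshold, clamp at zero).
#'
#' @param M numeric matrix (or a single vector) with finite entries.
#' @return Matrix of the same shape with non-negative columns summing to 1.
#' @export
project_columns_to_simplex <- function(M) {
  vec_in <- is.null(dim(M))
  if (vec_in) M <- matrix(M, ncol = 1L)
  check_finite(M, "simplex projection input")
  m <- nrow(M)
  out <- apply(M, 2L, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    j <- seq_len(m)
    rho <- max(which(u + (1 - css) / j > 0))
    tau <- (css[rho] - 1) / rho
    pmax(v - tau, 0)
  })
  out <- matrix(out, nrow = m)
  if (vec_in) drop(out) else out
}
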