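#' Connectivity matrix of one factorization run
#'
#' Each sample is assigned to the metagene on which its mixture coefficient
#' is largest (ties broken toward the lowest row index); the connectivity
#' matrix has a 1 wherever two samples share an assignment. It is symmetric
#' with a unit diagonal and is block-diagonal under some sample permutation.
#'
#' @param H r x n nonnegative coefficient matrix, or an `nmf_fit`.
#' @return n x n binary matrix.
#' @export
connectivity_matrix <- function(H) {
  if (inherits(H, "nmf_fit")) H <- H$H
  if (!is.matrix(H) || any(H < 0)) stop("H must be a nonnegative matrix", call. = FALSE)
  if (any(colSums(H) == 0))
    warning("all-zero coefficient column(s) assigned to metagene 1", call. = FALSE)
  a <- max.col(t(H), ties.method = "first")
  C <- outer(a, a, "==") + 0
  dimnames(C) <- list(colnames(H), colnames(H))
  C
}

#' Consensus matrix over restarts
#'
#' Elementwise mean of connectivity matrices from independent restarts; the
#' entry (j, k) estimates the probability that samples j and k co-cluster.
#'
#' @param runs list of n x n connectivity matrices.
#' @return n x n matrix with entries in `[0, 1]` and unit diagonal.
#' @export
consensus_matrix <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L)
    stop("runs must be a non-empty list of connectivity matrices", call. = FALSE)
  n <- nrow(runs[[1L]])
  if (!all(vapply(runs, function(m) is.matrix(m) && all(dim(m) == n), logical(1))))
    stop("all connectivity matrices must be square with matching size", call. = FALSE)
  C <- Reduce(`+`, runs) / length(runs)
  diag(C) <- 1
  C
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Measures how tree-like the consensus is: the samples are hierarchically
#' clustered (average linkage by default) on the dissimilarity `1 - C`, and
#' the Pearson correlation between the original dissimilarities and the
#' cophenetic (ultrametric) distances of the dendrogram is returned. Values
#' near 1 indicate stable clustering across restarts; an exactly
#' block-structured binary consensus attains 1.
#'
#' When every off-diagonal entry of `C` is equal the correlation is
#' undefined; `NA` is returned with attribute `undefined = TRUE` so that rank
#' surveys over degenerate ranks can still complete.
#'
#' @param C consensus matrix (n >= 3).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return correlation in `[-1, 1]`, or flagged `NA` when undefined.
#' @export
cophenetic_coefficient <- function(C, linkage = "average") {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("C must be a square matrix", call. = FALSE)
  if (nrow(C) < 3L)
    stop("cophenetic correlation needs at least 3 samples", call. = FALSE)
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0)
    return(structure(NA_real_, undefined = TRUE))
  hc <- stats::hclust(d, method = linkage)
  stats::cor(as.vector(d), as.vector(stats::cophenetic(hc)))
}
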