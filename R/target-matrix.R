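#' Validate a target matrix for factorization
#'
#' A target matrix is a labeled nonnegative numeric matrix with features
#' (genes or mutation types) in rows and samples in columns. Validation
#' rejects anything a multiplicative-update factorization cannot digest:
#' negative or non-finite entries, all-zero rows or columns (these make the
#' update rules degenerate and are removed by preprocessing, never patched
#' silently), and duplicated labels.
#'
#' @param x numeric matrix, preferably with row and column names.
#' @param name label used in error messages.
#' @return the validated matrix, invisibly unchanged except that missing
#'   dimnames are filled in with `f1..fm` / `s1..sn`.
#' @export
validate_target_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop(name, " must have at least one row and one column", call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(x))
    stop(name, " contains a non-finite entry at (", idx[1L], ",", idx[2L], ")",
         call. = FALSE)
  }
  bad <- which(x < 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(x))
    stop(name, " contains a negative entry at (", idx[1L], ",", idx[2L],
         "): nonnegativity is required", call. = FALSE)
  }
  zr <- which(rowSums(x) == 0)
  if (length(zr))
    stop(name, " has all-zero row(s): ", paste(utils::head(zr, 5L), collapse = ", "),
         call. = FALSE)
  zc <- which(colSums(x) == 0)
  if (length(zc))
    stop(name, " has all-zero column(s): ", paste(utils::head(zc, 5L), collapse = ", "),
         call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop(name, " has duplicated row labels", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(name, " has duplicated column labels", call. = FALSE)
  x
}

# rank admissibility shared by fit/init/survey entry points
check_rank <- function(r, m, n) {
  if (!is.numeric(r) || length(r) != 1L || r != round(r) || r < 1L)
    stop("rank must be a positive integer", call. = FALSE)
  if (r > min(m, n))
    stop("rank ", r, " exceeds min(dim) = ", min(m, n), call. = FALSE)
  as.integer(r)
}

# deterministic per-(rank, restart) seed stream; keeps every derived seed
# well inside 32-bit range so set.seed() accepts it
derive_seed <- function(base, rank = 0L, run = 0L) {
  as.integer((as.double(base) %% 2147483647 + rank * 100003 + run * 7919) %% 2147483647)
}
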