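#' Read a labeled nonnegative matrix
#'
#' TSV/CSV files carry feature labels in the first column and sample labels
#' in the header; MatrixMarket files (`.mtx`) carry labels in sidecar files
#' `<path>.rows` and `<path>.cols`, one label per line. The matrix is
#' validated on read: negative entries, all-zero rows/columns and duplicate
#' labels are rejected.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the file
#'   extension by default.
#' @param transpose transpose after reading (for files stored samples x
#'   features).
#' @return validated numeric matrix with dimnames.
#' @export
read_target_matrix <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format of ", path,
                          "; pass format=", call. = FALSE))
  x <- switch(format,
    tsv = ,
    csv = {
      sep <- if (format == "csv") "," else "\t"
      df <- utils::read.table(path, sep = sep, header = TRUE,
                              row.names = 1L, check.names = FALSE)
      if (!all(vapply(df, is.numeric, logical(1))))
        stop("malformed table: non-numeric data column in ", path, call. = FALSE)
      as.matrix(df)
    },
    mtx = {
      m <- as.matrix(Matrix::readMM(path))
      rows_f <- paste0(path, ".rows"); cols_f <- paste0(path, ".cols")
      if (!file.exists(rows_f) || !file.exists(cols_f))
        stop("missing label sidecar(s) ", rows_f, " / ", cols_f, call. = FALSE)
      rn <- readLines(rows_f); cn <- readLines(cols_f)
      if (length(rn) != nrow(m) || length(cn) != ncol(m))
        stop("sidecar label counts do not match matrix dimensions", call. = FALSE)
      dimnames(m) <- list(rn, cn)
      m
    },
    stop("unknown format: ", format, call. = FALSE))
  if (transpose) x <- t(x)
  validate_target_matrix(x, path)
}

#' Write a labeled matrix
#'
#' Inverse of [read_target_matrix()]; for `"mtx"` the label sidecars
#' `<path>.rows` / `<path>.cols` are written alongside.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_target_matrix <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format of ", path,
                          "; pass format=", call. = FALSE))
  switch(format,
    tsv = ,
    csv = {
      sep <- if (format == "csv") "," else "\t"
      utils::write.table(x, path, sep = sep, quote = FALSE, col.names = NA)
    },
    mtx = {
      Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
      writeLines(rownames(x), paste0(path, ".rows"))
      writeLines(colnames(x), paste0(path, ".cols"))
    },
    stop("unknown format: ", format, call. = FALSE))
  invisible(path)
}

#' Preprocess an expression or count matrix before factorization
#'
#' Steps are applied in a fixed order (they do not commute):
#' \enumerate{
#'   \item drop features whose total across samples is below
#'     `min_total_count` (low-quality features with inadequate reads);
#'   \item `log2(x + pseudo_count)` when `log_transform`;
#'   \item per-sample normalization against the column mean: `"divide"`
#'     rescales each column by its mean (keeps entries nonnegative, the
#'     default), `"subtract"` centers and clamps at zero with a warning —
#'     NMF requires a nonnegative target;
#'   \item keep the `variance_filter_keep` features of highest variance.
#' }
#' Each active step reports the number of features retained.
#'
#' @param V nonnegative numeric matrix (features x samples).
#' @param min_total_count feature-total filter threshold; 0 disables.
#' @param log_transform apply the log step.
#' @param pseudo_count offset inside the log.
#' @param normalize_samples apply the per-sample normalization.
#' @param normalize_mode `"divide"` or `"subtract"`.
#' @param variance_filter_keep number of top-variance features to keep;
#'   `NULL` disables.
#' @param verbose emit one message per active step.
#' @return the processed matrix. Note that the result may contain all-zero
#'   rows (e.g. a constant feature after log of pseudo-counts); validation
#'   for factorization happens at fit time.
#' @export
preprocess_matrix <- function(V, min_total_count = 0, log_transform = FALSE,
                              pseudo_count = 1, normalize_samples = FALSE,
                              normalize_mode = c("divide", "subtract"),
                              variance_filter_keep = NULL, verbose = TRUE) {
  normalize_mode <- match.arg(normalize_mode)
  if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(V)) || any(V < 0))
    stop("V must be finite and nonnegative", call. = FALSE)
  if (pseudo_count < 0) stop("pseudo_count must be >= 0", call. = FALSE)
  say <- function(...) if (verbose) message("preprocess: ", ...)

  if (min_total_count > 0) {
    keep <- rowSums(V) >= min_total_count
    if (!any(keep)) stop("all features removed by the total-count filter", call. = FALSE)
    V <- V[keep, , drop = FALSE]
    say(sum(keep), " features pass total >= ", min_total_count)
  }
  if (log_transform) {
    V <- log2(V + pseudo_count)
    say("log2(x + ", pseudo_count, ") applied")
  }
  if (normalize_samples) {
    mu <- colMeans(V)
    if (any(mu == 0)) stop("cannot normalize: sample with zero mean", call. = FALSE)
    if (normalize_mode == "divide") {
      V <- sweep(V, 2L, mu, "/")
      say("columns divided by their means")
    } else {
      V <- sweep(V, 2L, mu, "-")
      if (any(V < 0)) {
        warning("subtract-normalization produced negative entries; clamped at 0",
                call. = FALSE)
        V[V < 0] <- 0
      }
      say("columns centered (clamped at 0)")
    }
  }
  if (!is.null(variance_filter_keep)) {
    k <- as.integer(variance_filter_keep)
    if (k < 1L || k > nrow(V))
      stop("variance_filter_keep must be in [1, ", nrow(V), "]", call. = FALSE)
    v <- apply(V, 1L, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(k)]
    V <- V[sort(keep), , drop = FALSE]
    say(k, " top-variance features kept")
  }
  V
}
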