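#' Rank survey: multi-restart NMF over a grid of candidate ranks
#'
#' For each candidate rank, `nrun` factorizations are fitted from
#' independent seeded initializations. The survey records, per rank, the best
#' (minimum) residual sum of squares over restarts — one RSS value per rank,
#' the curve the knee estimator consumes — together with the consensus matrix
#' of the restarts' connectivity matrices and its cophenetic correlation
#' coefficient, the comparator stability metric.
#'
#' Restart seeds are derived deterministically from `(seed, rank, run)`, so
#' the survey is reproducible, independent of execution order, and the
#' restarts for `nrun = k` are a subset of those for any larger `nrun`.
#'
#' @param V nonnegative target matrix (features x samples).
#' @param ranks strictly increasing candidate ranks, all `>= 2` (a rank-1
#'   consensus is degenerate for the cophenetic metric) and
#'   `<= min(dim(V))`.
#' @param nrun restarts per rank.
#' @param algorithm,theta,max_iter,conn_stall,conn_interval,eps passed to
#'   [nmf()].
#' @param seed base seed governing all restarts.
#' @param keep_consensus keep the per-rank consensus matrices in the result.
#' @return object of class `nmf_survey`: `ranks`, `rss_curve` (best-of-runs),
#'   `cophenetic_curve` (`NA` where undefined), `consensus` (list, or `NULL`),
#'   `best_fits` (the best `nmf_fit` per rank), `nrun`, `algorithm`, `seed`.
#' @seealso [select_rank()], [uiknmf()]
#' @export
nmf_rank_survey <- function(V, ranks, nrun = 10L,
                            algorithm = c("brunet", "lee", "nsnmf"),
                            theta = 0.5, max_iter = 2000L, conn_stall = 40L,
                            conn_interval = 10L, eps = .Machine$double.eps,
                            seed = 1L, keep_consensus = TRUE) {
  algorithm <- match.arg(algorithm)
  V <- validate_target_matrix(V, "V")
  if (length(ranks) == 0L) stop("ranks must be non-empty", call. = FALSE)
  ranks <- as.integer(ranks)
  if (any(diff(ranks) <= 0)) stop("ranks must be strictly increasing", call. = FALSE)
  if (any(ranks < 2L))
    stop("ranks below 2 are rejected: single-metagene consensus is degenerate",
         call. = FALSE)
  if (any(ranks > min(dim(V))))
    stop("rank(s) exceed min(dim(V)) = ", min(dim(V)), call. = FALSE)
  if (nrun < 1L) stop("nrun must be >= 1", call. = FALSE)

  nr <- length(ranks)
  rss_curve <- numeric(nr)
  coph <- rep(NA_real_, nr)
  coph_undef <- logical(nr)
  consensus <- if (keep_consensus) vector("list", nr) else NULL
  best_fits <- vector("list", nr)

  for (k in seq_len(nr)) {
    r <- ranks[k]
    conns <- vector("list", nrun)
    best <- NULL
    for (j in seq_len(nrun)) {
      fit <- nmf(V, r, algorithm = algorithm, theta = theta,
                 max_iter = max_iter, conn_stall = conn_stall,
                 conn_interval = conn_interval, eps = eps,
                 seed = derive_seed(seed, r, j))
      conns[[j]] <- connectivity_matrix(fit$H)
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
    rss_curve[k] <- best$rss
    best_fits[[k]] <- best
    cm <- consensus_matrix(conns)
    if (keep_consensus) consensus[[k]] <- cm
    cc <- cophenetic_coefficient(cm)
    coph[k] <- as.numeric(cc)
    coph_undef[k] <- isTRUE(attr(cc, "undefined"))
  }

  structure(list(
    ranks = ranks, rss_curve = rss_curve, cophenetic_curve = coph,
    cophenetic_undefined = coph_undef, consensus = consensus,
    best_fits = best_fits, nrun = as.integer(nrun), algorithm = algorithm,
    theta = if (algorithm == "nsnmf") theta else NA_real_,
    seed = as.integer(seed), dims = dim(V)), class = "nmf_survey")
}

#' @export
#' @method print nmf_survey
print.nmf_survey <- function(x, ...) {
  cat("NMF rank survey (", x$algorithm, ", ", x$nrun, " restarts/rank, target ",
      x$dims[1L], "x", x$dims[2L], ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.nmf_survey <- function(x, ...) {
  data.frame(rank = x$ranks, rss = x$rss_curve,
             cophenetic = x$cophenetic_curve, n_run = x$nrun)
}

#' Write a survey table as TSV
#'
#' Columns `rank`, `rss`, `cophenetic`, `n_run`; undefined cophenetic values
#' are written as `NA`.
#'
#' @param survey an `nmf_survey`.
#' @param path output file.
#' @param consensus_dir optional directory; when given, each rank's consensus
#'   matrix is written as `consensus_rank<r>.tsv` inside it.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path, consensus_dir = NULL) {
  utils::write.table(as.data.frame(survey), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(consensus_dir) && !is.null(survey$consensus)) {
    dir.create(consensus_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(survey$ranks))
      utils::write.table(survey$consensus[[k]],
                         file.path(consensus_dir,
                                   sprintf("consensus_rank%d.tsv", survey$ranks[k])),
                         sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Plot a rank survey
#'
#' Two panels: best-of-restarts RSS versus rank, and the cophenetic
#' correlation coefficient versus rank. When a knee estimate is supplied the
#' knee-point range and the selected rank are marked on the RSS panel.
#'
#' @param x an `nmf_survey`.
#' @param knee optional `knee_estimate` (e.g. from [select_rank()]).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nmf_survey <- function(x, knee = NULL, ...) {
  op <- graphics::par(mfrow = c(1L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$ranks, x$rss_curve, type = "b", pch = 19,
                 xlab = "rank", ylab = "RSS (best of restarts)",
                 main = "RSS survey", ...)
  if (!is.null(knee)) {
    graphics::abline(v = c(knee$knee_start, knee$knee_end),
                     lty = 3, col = "grey40")
    graphics::abline(v = knee$selected, lty = 2, col = "red3")
    graphics::mtext(paste("selected rank", knee$selected), side = 3,
                    line = 0, col = "red3", cex = 0.8)
  }
  graphics::plot(x$ranks, x$cophenetic_curve, type = "b", pch = 19,
                 xlab = "rank", ylab = "cophenetic coefficient",
                 main = "Consensus stability", ...)
  invisible(x)
}
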