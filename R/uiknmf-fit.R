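#' Fit NMF and select the optimal rank by the unit-invariant knee
#'
#' The full estimator: runs a multi-restart rank survey over `ranks`, locates
#' the knee of the best-RSS curve with the unit-invariant knee (extremum
#' chord-distance) estimator, and retains the best factorization at the
#' selected rank. The cophenetic-consensus curve is computed alongside as the
#' comparator stability metric.
#'
#' @param V nonnegative numeric matrix, features (genes or mutation types) x
#'   samples; or a `synthetic_catalog`, whose `counts` are used.
#' @param ranks candidate ranks (at least 4 for knee detection); default
#'   `2:15`.
#' @param nrun random restarts per rank.
#' @param algorithm `"brunet"` (KL, default), `"lee"` (Frobenius) or
#'   `"nsnmf"` (nonsmooth).
#' @param theta nsNMF smoothing weight.
#' @param seed base seed; every restart seed derives from it.
#' @param ... further control arguments passed to [nmf_rank_survey()].
#' @return object of class `uiknmf` with components `survey`
#'   (an `nmf_survey`), `knee` (a `knee_estimate`), `rank` (the selected
#'   rank), `fit` (the best `nmf_fit` at that rank), `V`, `call`.
#' @examples
#' \donttest{
#' cat10 <- simulate_catalog(n_processes = 4, n_genomes = 30, seed = 1)
#' mod <- uiknmf(cat10, ranks = 2:8, nrun = 3, seed = 1)
#' mod$rank
#' }
#' @export
uiknmf <- function(V, ranks = 2:15, nrun = 10L,
                   algorithm = c("brunet", "lee", "nsnmf"), theta = 0.5,
                   seed = 1L, ...) {
  cl <- match.call()
  algorithm <- match.arg(algorithm)
  if (inherits(V, "synthetic_catalog")) V <- V$counts
  V <- validate_target_matrix(V, "V")
  survey <- nmf_rank_survey(V, ranks, nrun = nrun, algorithm = algorithm,
                            theta = theta, seed = seed, ...)
  knee <- select_rank(survey)
  k <- match(knee$selected, survey$ranks)
  structure(list(survey = survey, knee = knee,
                 rank = as.integer(knee$selected),
                 fit = survey$best_fits[[k]], V = V, call = cl),
            class = "uiknmf")
}

#' @export
#' @method print uiknmf
print.uiknmf <- function(x, ...) {
  cat("uikNMF rank selection (", x$survey$algorithm, ")\n", sep = "")
  cat("  target: ", nrow(x$V), " features x ", ncol(x$V), " samples\n", sep = "")
  cat("  ranks surveyed: ", min(x$survey$ranks), "-", max(x$survey$ranks),
      " (", x$survey$nrun, " restarts each)\n", sep = "")
  cat("  knee points: ", format(x$knee$knee_start), " to ",
      format(x$knee$knee_end), "\n", sep = "")
  cat("  selected rank: ", x$rank, "  (RSS ", format(x$fit$rss), ")\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary uiknmf
summary.uiknmf <- function(object, ...) {
  out <- list(table = as.data.frame(object$survey), knee = object$knee,
              rank = object$rank, algorithm = object$survey$algorithm,
              dims = dim(object$V), rss = object$fit$rss)
  class(out) <- "summary.uiknmf"
  out
}

#' @export
#' @method print summary.uiknmf
print.summary.uiknmf <- function(x, ...) {
  cat("uikNMF rank survey (", x$algorithm, ") on ", x$dims[1L], " x ",
      x$dims[2L], " target\n\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("\nknee of the RSS curve: start ", format(x$knee$knee_start),
      ", end ", format(x$knee$knee_end),
      "; selected rank ", x$rank, "\n", sep = "")
  invisible(x)
}

#' @export
coef.uiknmf <- function(object, ...) object$fit$H

#' @export
basis.uiknmf <- function(object, ...) object$fit$W

#' @export
fitted.uiknmf <- function(object, ...) {
  WH <- reconstruct_wh(object$fit)
  dimnames(WH) <- dimnames(object$V)
  WH
}

#' @export
residuals.uiknmf <- function(object, ...) object$V - fitted(object)

#' Project samples onto a fitted basis
#'
#' With `newdata` absent, returns the fitted reconstruction. Otherwise the
#' basis `W` is held fixed and the coefficient updates of the fitting
#' algorithm are iterated on the new samples, yielding their mixture
#' coefficients over the learned metagenes/signatures.
#'
#' @param object a `uiknmf` model.
#' @param newdata nonnegative matrix with the same features (rows) as the
#'   training matrix.
#' @param iter number of coefficient updates.
#' @param what `"coef"` returns the projected coefficients, `"fitted"` their
#'   reconstruction.
#' @param ... unused.
#' @return matrix of coefficients (rank x new samples) or reconstructions.
#' @export
predict.uiknmf <- function(object, newdata = NULL, iter = 500L,
                           what = c("coef", "fitted"), ...) {
  what <- match.arg(what)
  if (is.null(newdata))
    return(if (what == "coef") coef(object) else fitted(object))
  if (!is.matrix(newdata) || nrow(newdata) != nrow(object$V))
    stop("newdata must be a matrix with ", nrow(object$V), " rows", call. = FALSE)
  if (any(newdata < 0)) stop("newdata must be nonnegative", call. = FALSE)
  fit <- object$fit
  W <- if (is.null(fit$S)) fit$W else fit$W %*% fit$S
  eps <- .Machine$double.eps
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(fit$seed, fit$rank, 0L))
  H <- matrix(1 - stats::runif(fit$rank * ncol(newdata)), fit$rank, ncol(newdata)) *
    max(newdata)
  kl <- fit$algorithm %in% c("brunet", "nsnmf")
  for (i in seq_len(iter)) {
    H <- if (kl)
      H * crossprod(W, newdata / (W %*% H + eps)) / (colSums(W) + eps)
    else
      H * crossprod(W, newdata) / (crossprod(W, W %*% H) + eps)
  }
  dimnames(H) <- list(rownames(fit$H), colnames(newdata))
  if (what == "coef") H else W %*% H
}

#' Simulate count matrices from a fitted model
#'
#' Draws entrywise Poisson matrices with mean equal to the fitted
#' reconstruction — the natural parametric bootstrap for count catalogs
#' (mutation counts, UMI counts).
#'
#' @param object a `uiknmf` model.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` matrices shaped like the training matrix.
#' @export
simulate.uiknmf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lam <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    x <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    dimnames(x) <- dimnames(lam)
    x
  })
}

#' @export
plot.uiknmf <- function(x, ...) {
  plot(x$survey, knee = x$knee, ...)
  invisible(x)
}
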