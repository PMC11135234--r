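#' Random initialization for multiplicative-update NMF
#'
#' Entries of both factors are drawn i.i.d. uniform on `(0, scale]`; strictly
#' positive starting values are required because multiplicative updates
#' preserve zeros forever.
#'
#' @param m,n target matrix dimensions.
#' @param r factorization rank, at most `min(m, n)`.
#' @param seed integer seed; identical `(seed, m, n, r)` give identical output.
#' @param scale upper bound of the uniform draw; a common choice is `max(V)`.
#' @return list with components `W` (m x r) and `H` (r x n).
#' @export
nmf_init <- function(m, n, r, seed, scale = 1) {
  r <- check_rank(r, m, n)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  # 1 - runif maps [0,1) to (0,1] so no entry can start at exactly zero
  W <- matrix((1 - stats::runif(m * r)) * scale, m, r)
  H <- matrix((1 - stats::runif(r * n)) * scale, r, n)
  list(W = W, H = H)
}

check_conform <- function(V, W, H) {
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H))
    stop("dimension mismatch: V is ", nrow(V), "x", ncol(V), ", W is ",
         nrow(W), "x", ncol(W), ", H is ", nrow(H), "x", ncol(H), call. = FALSE)
  invisible(TRUE)
}

#' One multiplicative update step for the Frobenius objective
#'
#' Applies the coefficient step
#' \eqn{H \gets H \odot W^T V / (W^T W H + \epsilon)} followed by the basis
#' step \eqn{W \gets W \odot V H^T / (W H H^T + \epsilon)}. The squared
#' Frobenius error \eqn{\|V - WH\|_F^2} is non-increasing along these steps.
#'
#' @param V nonnegative target matrix.
#' @param W,H current factors.
#' @param eps denominator guard against division by zero.
#' @return list with updated `W` and `H`.
#' @export
nmf_update_frobenius <- function(V, W, H, eps = .Machine$double.eps) {
  check_conform(V, W, H)
  # denominators associate as t(W) %*% (W %*% H) so that the masked variant
  # with an all-ones mask is bit-identical
  H <- H * crossprod(W, V) / (crossprod(W, W %*% H) + eps)
  W <- W * tcrossprod(V, H) / (tcrossprod(W %*% H, H) + eps)
  list(W = W, H = H)
}

#' One multiplicative update step for the Kullback-Leibler objective
#'
#' The divergence steps of the classical KL-NMF algorithm:
#' \eqn{H_{aj} \gets H_{aj} \sum_i W_{ia} V_{ij}/(WH)_{ij} / \sum_i W_{ia}},
#' then the analogous basis step against the refreshed reconstruction.
#' The generalized KL divergence \eqn{D(V \| WH)} is non-increasing.
#'
#' @inheritParams nmf_update_frobenius
#' @return list with updated `W` and `H`.
#' @export
nmf_update_kl <- function(V, W, H, eps = .Machine$double.eps) {
  check_conform(V, W, H)
  H <- H * crossprod(W, V / (W %*% H + eps)) / (colSums(W) + eps)
  W <- W * tcrossprod(V / (W %*% H + eps), H) / rep(rowSums(H) + eps, each = nrow(W))
  list(W = W, H = H)
}

#' Smoothing matrix for nonsmooth NMF
#'
#' \eqn{S(\theta) = (1-\theta) I + (\theta/r) \mathbf{1}\mathbf{1}^T}:
#' symmetric, doubly stochastic, the identity at `theta = 0` and the uniform
#' averager at `theta = 1`. Interposing it between the factors
#' (\eqn{V \approx W S H}) spreads mass across components, which forces
#' sparseness into the fitted factors.
#'
#' @param r rank (matrix dimension).
#' @param theta smoothing weight in `[0, 1]`.
#' @return an `r` x `r` matrix.
#' @export
smoothing_matrix <- function(r, theta) {
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r))
    stop("r must be a positive integer", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  (1 - theta) * diag(r) + theta / r * matrix(1, r, r)
}

kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

rss_wh <- function(V, WH) sum((V - WH)^2)

#' Residual sum of squares of a factorization
#'
#' \eqn{\sum_{ij} (V_{ij} - (WH)_{ij})^2}, the quantity plotted against rank
#' in a rank survey. Zero exactly when the reconstruction is exact.
#'
#' @param V target matrix.
#' @param fit an `nmf_fit` object (or a list with `W`, `H` and optional `S`).
#' @return nonnegative scalar.
#' @export
rss <- function(V, fit) {
  WH <- reconstruct_wh(fit)
  if (nrow(WH) != nrow(V) || ncol(WH) != ncol(V))
    stop("dimension mismatch between V and the factorization", call. = FALSE)
  rss_wh(V, WH)
}

reconstruct_wh <- function(fit) {
  if (is.null(fit$S)) fit$W %*% fit$H else fit$W %*% fit$S %*% fit$H
}

#' Fit a nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix `V` (features x samples) as
#' \eqn{V \approx W H} with `W` (m x r, the metagene/signature basis) and `H`
#' (r x n, per-sample mixture coefficients), starting from a seeded random
#' initialization and iterating the multiplicative rule of the chosen
#' algorithm:
#' \describe{
#'   \item{`"brunet"`}{Kullback-Leibler divergence updates (the default for
#'     count-like data such as mutation catalogs).}
#'   \item{`"lee"`}{Frobenius (least-squares) updates.}
#'   \item{`"nsnmf"`}{nonsmooth NMF: KL updates with the smoothing matrix
#'     \eqn{S(\theta)} interposed, \eqn{V \approx W S H}.}
#' }
#' Iteration stops when the sample clustering implied by `H` (the
#' connectivity partition) has not changed for `conn_stall` consecutive
#' checks, performed every `conn_interval` iterations, or at `max_iter`.
#'
#' @param V nonnegative numeric matrix; validated before fitting.
#' @param rank factorization rank r, `2 <= r <= min(dim(V))` is typical;
#'   r = 1 is allowed for a single fit.
#' @param algorithm `"brunet"`, `"lee"` or `"nsnmf"`.
#' @param theta smoothing weight for `"nsnmf"`, ignored otherwise.
#' @param max_iter iteration cap.
#' @param conn_stall consecutive unchanged connectivity checks that declare
#'   convergence.
#' @param conn_interval iterations between connectivity checks.
#' @param eps denominator guard.
#' @param seed integer seed for the random initialization.
#' @param init_scale upper bound of the uniform initialization; defaults to
#'   `max(V)`.
#' @return an object of class `nmf_fit`: components `W`, `H`, `S` (non-`NULL`
#'   only for nsNMF), `rank`, `algorithm`, `theta`, `n_iter`,
#'   `objective_trace` (objective recorded at every connectivity check),
#'   `rss`, `converged`, `seed`.
#' @seealso [uiknmf()] for the full survey-and-select estimator.
#' @examples
#' V <- outer(1:4, c(2, 1, 3)) + 1
#' f <- nmf(V, rank = 2, algorithm = "lee", seed = 1)
#' f$rss
#' @export
nmf <- function(V, rank, algorithm = c("brunet", "lee", "nsnmf"),
                theta = 0.5, max_iter = 2000L, conn_stall = 40L,
                conn_interval = 10L, eps = .Machine$double.eps,
                seed = 1L, init_scale = NULL) {
  algorithm <- match.arg(algorithm)
  V <- validate_target_matrix(V, "V")
  m <- nrow(V); n <- ncol(V)
  rank <- check_rank(rank, m, n)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (is.null(init_scale)) init_scale <- max(V)
  init <- nmf_init(m, n, rank, seed = seed, scale = init_scale)
  W <- init$W; H <- init$H
  S <- if (algorithm == "nsnmf") smoothing_matrix(rank, theta) else NULL

  objective <- switch(algorithm,
    lee = function(W, H) rss_wh(V, W %*% H),
    brunet = function(W, H) kl_divergence(V, W %*% H + eps),
    nsnmf = function(W, H) kl_divergence(V, W %*% S %*% H + eps))
  step <- switch(algorithm,
    lee = function(W, H) nmf_update_frobenius(V, W, H, eps),
    brunet = function(W, H) nmf_update_kl(V, W, H, eps),
    nsnmf = function(W, H) {
      # smoothness is imposed by updating H against the smoothed basis W S
      # and W against the smoothed coefficients S H
      Ws <- W %*% S
      H <- H * crossprod(Ws, V / (Ws %*% H + eps)) / (colSums(Ws) + eps)
      Hs <- S %*% H
      W <- W * tcrossprod(V / (W %*% Hs + eps), Hs) /
        rep(rowSums(Hs) + eps, each = nrow(W))
      list(W = W, H = H)
    })

  trace <- numeric(0)
  stall <- 0L
  prev_part <- NULL
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    upd <- step(W, H)
    W <- upd$W; H <- upd$H
    it <- it + 1L
    if (it %% conn_interval == 0L || it == max_iter) {
      trace <- c(trace, objective(W, H))
      part <- cluster_partition(H)
      if (!is.null(prev_part) && identical(part, prev_part)) {
        stall <- stall + 1L
        if (stall >= conn_stall) { converged <- TRUE; break }
      } else stall <- 0L
      prev_part <- part
    }
  }
  if (length(trace) == 0L) trace <- objective(W, H)

  fit <- structure(list(
    W = W, H = H, S = S, rank = rank, algorithm = algorithm,
    theta = if (algorithm == "nsnmf") theta else NA_real_,
    n_iter = it, objective_trace = trace, converged = converged,
    seed = as.integer(seed), dims = c(m = m, n = n),
    row_labels = rownames(V), col_labels = colnames(V)), class = "nmf_fit")
  fit$rss <- rss_wh(V, reconstruct_wh(fit))
  dimnames(fit$W) <- list(rownames(V), paste0("k", seq_len(rank)))
  dimnames(fit$H) <- list(paste0("k", seq_len(rank)), colnames(V))
  fit
}

# canonical labeling of the argmax partition of H's columns, so that
# relabeled but identical clusterings compare equal
cluster_partition <- function(H) {
  a <- max.col(t(H), ties.method = "first")
  match(a, unique(a))
}

#' @export
#' @method print nmf_fit
print.nmf_fit <- function(x, ...) {
  cat("Nonnegative matrix factorization (", x$algorithm, ")\n", sep = "")
  cat("  target: ", x$dims["m"], " features x ", x$dims["n"], " samples, rank ",
      x$rank, "\n", sep = "")
  cat("  iterations: ", x$n_iter,
      if (x$converged) " (connectivity converged)" else " (max_iter reached)",
      "\n", sep = "")
  cat("  RSS: ", format(x$rss), "\n", sep = "")
  invisible(x)
}

#' @export
coef.nmf_fit <- function(object, ...) object$H

#' Basis (metagenes / signatures) of a factorization
#' @param object a fitted object.
#' @param ... unused.
#' @return the basis matrix `W` (features x rank).
#' @export
basis <- function(object, ...) UseMethod("basis")

#' @export
basis.nmf_fit <- function(object, ...) object$W

#' @export
fitted.nmf_fit <- function(object, ...) {
  WH <- reconstruct_wh(object)
  dimnames(WH) <- list(object$row_labels, object$col_labels)
  WH
}
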