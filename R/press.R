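#' Masked (entry-holdout) NMF fit
#'
#' Fits `V ~ W H` by multiplicative updates in which held-out entries carry
#' zero weight: the update numerators and denominators use the elementwise
#' products `mask * V` and `mask * (W H)`, so masked entries exert no
#' gradient and the fitted product imputes them. With an all-ones mask the
#' Frobenius ("lee") trajectory is identical to [nmf()] given the same seed.
#'
#' @param V nonnegative target matrix.
#' @param mask binary matrix of `V`'s shape; 1 = observed, 0 = held out.
#'   Every row and every column must retain at least `rank` observed entries.
#' @param rank factorization rank.
#' @param algorithm `"lee"` (masked Frobenius) or `"brunet"` (masked KL).
#' @param max_iter,conn_stall,conn_interval,eps,seed,init_scale as in [nmf()].
#' @return an `nmf_fit`; its `rss` and `objective_trace` are computed over
#'   observed entries only.
#' @export
nmf_masked <- function(V, mask, rank, algorithm = c("lee", "brunet"),
                       max_iter = 2000L, conn_stall = 40L,
                       conn_interval = 10L, eps = .Machine$double.eps,
                       seed = 1L, init_scale = NULL) {
  algorithm <- match.arg(algorithm)
  V <- validate_target_matrix(V, "V")
  if (!is.matrix(mask) || !all(dim(mask) == dim(V)))
    stop("mask must be a matrix with the shape of V", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask entries must be 0 or 1", call. = FALSE)
  m <- nrow(V); n <- ncol(V)
  rank <- check_rank(rank, m, n)
  bad_r <- which(rowSums(mask) < rank)
  if (length(bad_r))
    stop("holdout scheme leaves row ", bad_r[1L], " with fewer than ", rank,
         " observed entries", call. = FALSE)
  bad_c <- which(colSums(mask) < rank)
  if (length(bad_c))
    stop("holdout scheme leaves column ", bad_c[1L], " with fewer than ", rank,
         " observed entries", call. = FALSE)
  if (is.null(init_scale)) init_scale <- max(V)
  init <- nmf_init(m, n, rank, seed = seed, scale = init_scale)
  W <- init$W; H <- init$H
  MV <- mask * V

  trace <- numeric(0)
  stall <- 0L; prev_part <- NULL; it <- 0L; converged <- FALSE
  while (it < max_iter) {
    if (algorithm == "lee") {
      H <- H * crossprod(W, MV) / (crossprod(W, mask * (W %*% H)) + eps)
      W <- W * tcrossprod(MV, H) / (tcrossprod(mask * (W %*% H), H) + eps)
    } else {
      H <- H * crossprod(W, MV / (W %*% H + eps)) / (crossprod(W, mask) + eps)
      W <- W * tcrossprod(MV / (W %*% H + eps), H) / (tcrossprod(mask, H) + eps)
    }
    it <- it + 1L
    if (it %% conn_interval == 0L || it == max_iter) {
      WH <- W %*% H
      obj <- if (algorithm == "lee") sum(mask * (V - WH)^2)
             else kl_divergence(MV, mask * WH + eps)
      trace <- c(trace, obj)
      part <- cluster_partition(H)
      if (!is.null(prev_part) && identical(part, prev_part)) {
        stall <- stall + 1L
        if (stall >= conn_stall) { converged <- TRUE; break }
      } else stall <- 0L
      prev_part <- part
    }
  }

  fit <- structure(list(
    W = W, H = H, S = NULL, rank = rank, algorithm = algorithm,
    theta = NA_real_, n_iter = it, objective_trace = trace,
    converged = converged, seed = as.integer(seed), dims = c(m = m, n = n),
    row_labels = rownames(V), col_labels = colnames(V)), class = "nmf_fit")
  fit$rss <- sum(mask * (V - W %*% H)^2)
  fit
}

#' Entry-holdout scheme for PRESS cross-validation
#'
#' @param mode `"random_fraction"` (default: each fold holds out a random
#'   fraction of entries), `"loo_full"` (every entry, one at a time — m*n
#'   fits, exact but expensive) or `"bootstrap"` (entries resampled with
#'   replacement per fold, duplicates collapsed).
#' @param fraction holdout proportion per fold, in `(0, 0.5]`.
#' @param n_repeats number of folds (ignored for `loo_full`).
#' @param seed integer governing fold membership.
#' @return a `holdout_scheme` list.
#' @export
holdout_scheme <- function(mode = c("random_fraction", "loo_full", "bootstrap"),
                           fraction = 0.05, n_repeats = 5L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "loo_full" && (fraction <= 0 || fraction > 0.5))
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  structure(list(mode = mode, fraction = fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "holdout_scheme")
}

# draw one fold's held-out entry indices: entries are visited in seeded
# random order and accepted greedily while every row keeps >= max_rank of
# its n observed entries and every column >= max_rank of its m, so the fold
# is always admissible for the whole rank sweep
draw_fold <- function(dims, scheme, fold, max_rank) {
  m <- dims[1L]; n <- dims[2L]
  total <- m * n
  row_cap <- n - max_rank
  col_cap <- m - max_rank
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(scheme$seed, 0L, fold))
  k <- max(1L, floor(scheme$fraction * total))
  pool <- switch(scheme$mode,
    random_fraction = sample.int(total, total),
    bootstrap = unique(sample.int(total, k, replace = TRUE)))
  if (row_cap < 1L || col_cap < 1L)
    stop("holdout infeasible: every row/column must retain ", max_rank,
         " observed entries", call. = FALSE)
  row_used <- integer(m); col_used <- integer(n)
  idx <- integer(0)
  for (e in pool) {
    if (length(idx) >= k) break
    i <- ((e - 1L) %% m) + 1L
    j <- ((e - 1L) %/% m) + 1L
    if (row_used[i] < row_cap && col_used[j] < col_cap) {
      idx <- c(idx, e)
      row_used[i] <- row_used[i] + 1L
      col_used[j] <- col_used[j] + 1L
    }
  }
  if (length(idx) == 0L)
    stop("could not draw a holdout fold satisfying the per-row/column ",
         "observed-entry constraint", call. = FALSE)
  idx
}

#' PRESS: predicted residual sum of squares at one rank
#'
#' For each fold of the scheme, the designated entries are masked, a masked
#' factorization is fitted, and the squared prediction error
#' \eqn{(V_{ab} - (WH)_{ab})^2} is accumulated over the held-out entries.
#' The value returned is normalized per held-out entry so that schemes with
#' different fold sizes are comparable; the raw sum is attached as attribute
#' `raw_sum`.
#'
#' @param V nonnegative target matrix.
#' @param rank candidate rank.
#' @param scheme a [holdout_scheme()].
#' @param algorithm,max_iter,conn_stall,conn_interval,eps as in [nmf_masked()].
#'   Unlike a clustering-oriented fit, a PRESS fold needs reconstruction
#'   convergence, so by default the connectivity-stall early stop is disabled,
#'   every fold runs the full iteration budget, and that budget is deeper
#'   (5000) than a survey fit's; this keeps the convergence floor small and
#'   comparable across ranks, which the tie handling of
#'   [select_rank_press()] relies on.
#' @param max_rank largest rank for which the fold draw must stay feasible
#'   (so that folds are shared across a rank sweep); defaults to `rank`.
#' @return mean squared prediction error over held-out entries.
#' @export
nmf_press <- function(V, rank, scheme = holdout_scheme(),
                      algorithm = c("lee", "brunet"), max_iter = 5000L,
                      conn_stall = .Machine$integer.max, conn_interval = 10L,
                      eps = .Machine$double.eps, max_rank = rank) {
  algorithm <- match.arg(algorithm)
  V <- validate_target_matrix(V, "V")
  m <- nrow(V); n <- ncol(V)
  rank <- check_rank(rank, m, n)
  folds <- if (scheme$mode == "loo_full") seq_len(m * n)
           else seq_len(scheme$n_repeats)
  total_err <- 0; total_count <- 0L
  for (f in folds) {
    idx <- if (scheme$mode == "loo_full") f
           else draw_fold(c(m, n), scheme, f, max_rank)
    mask <- matrix(1, m, n)
    mask[idx] <- 0
    fit <- nmf_masked(V, mask, rank, algorithm = algorithm,
                      max_iter = max_iter, conn_stall = conn_stall,
                      conn_interval = conn_interval, eps = eps,
                      seed = derive_seed(scheme$seed, rank, f))
    WH <- fit$W %*% fit$H
    total_err <- total_err + sum((V[idx] - WH[idx])^2)
    total_count <- total_count + length(idx)
  }
  if (total_count == 0L) stop("holdout scheme held out no entries", call. = FALSE)
  structure(total_err / total_count, raw_sum = total_err,
            n_heldout = total_count)
}

#' Rank selection by minimizing PRESS
#'
#' Computes the PRESS criterion over a grid of candidate ranks using shared
#' folds and selects the rank at which the prediction error is minimal.
#' Ties break toward the smaller rank, for parsimony, and "tie" is judged
#' numerically: on (near-)noiseless targets every rank at or above the true
#' rank imputes held-out entries essentially exactly, leaving a flat curve
#' whose literal argmin is decided by convergence-floor noise. Ranks whose
#' PRESS exceeds the minimum by at most `tie_tol` times the curve's range
#' are therefore treated as tied with it.
#'
#' @param V nonnegative target matrix.
#' @param ranks at least two candidate ranks.
#' @param scheme a [holdout_scheme()].
#' @param tie_tol relative (to the PRESS curve's range) tolerance within
#'   which ranks count as tied with the minimum.
#' @param ... passed to [nmf_press()].
#' @return object of class `nmf_press`: `ranks`, `press_curve`, `optimal`,
#'   `scheme`.
#' @export
select_rank_press <- function(V, ranks, scheme = holdout_scheme(),
                              tie_tol = 1e-3, ...) {
  if (length(ranks) < 2L)
    stop("PRESS rank selection needs at least 2 candidate ranks", call. = FALSE)
  ranks <- as.integer(ranks)
  if (any(diff(ranks) <= 0)) stop("ranks must be strictly increasing", call. = FALSE)
  curve <- vapply(ranks, function(r)
    as.numeric(nmf_press(V, r, scheme, max_rank = max(ranks), ...)), numeric(1))
  thresh <- min(curve) + tie_tol * diff(range(curve))
  structure(list(ranks = ranks, press_curve = curve,
                 optimal = ranks[which(curve <= thresh)[1L]], scheme = scheme),
            class = "nmf_press")
}

#' @export
#' @method print nmf_press
print.nmf_press <- function(x, ...) {
  cat("PRESS rank selection (", x$scheme$mode, ")\n", sep = "")
  print(data.frame(rank = x$ranks, press = x$press_curve), row.names = FALSE)
  cat("optimal rank:", x$optimal, "\n")
  invisible(x)
}
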