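# Straight-loop reference implementations used as independent oracles.
# Deliberately naive (elementwise loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementation.

ref_frobenius_step <- function(V, W, H, eps = .Machine$double.eps) {
  m <- nrow(V); n <- ncol(V); r <- ncol(W)
  Hn <- H
  for (a in seq_len(r)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (i in seq_len(m)) {
      num <- num + W[i, a] * V[i, j]
      wh <- 0
      for (b in seq_len(r)) wh <- wh + W[i, b] * H[b, j]
      den <- den + W[i, a] * wh
    }
    Hn[a, j] <- H[a, j] * num / (den + eps)
  }
  Wn <- W
  for (i in seq_len(m)) for (a in seq_len(r)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      num <- num + V[i, j] * Hn[a, j]
      wh <- 0
      for (b in seq_len(r)) wh <- wh + W[i, b] * Hn[b, j]
      den <- den + wh * Hn[a, j]
    }
    Wn[i, a] <- W[i, a] * num / (den + eps)
  }
  list(W = Wn, H = Hn)
}

ref_kl_step <- function(V, W, H, eps = .Machine$double.eps) {
  m <- nrow(V); n <- ncol(V); r <- ncol(W)
  Hn <- H
  for (a in seq_len(r)) for (j in seq_len(n)) {
    num <- 0
    for (i in seq_len(m)) {
      wh <- 0
      for (b in seq_len(r)) wh <- wh + W[i, b] * H[b, j]
      num <- num + W[i, a] * V[i, j] / (wh + eps)
    }
    Hn[a, j] <- H[a, j] * num / (sum(W[, a]) + eps)
  }
  Wn <- W
  for (i in seq_len(m)) for (a in seq_len(r)) {
    num <- 0
    for (j in seq_len(n)) {
      wh <- 0
      for (b in seq_len(r)) wh <- wh + W[i, b] * Hn[b, j]
      num <- num + V[i, j] * Hn[a, j] / (wh + eps)
    }
    Wn[i, a] <- W[i, a] * num / (sum(Hn[a, ]) + eps)
  }
  list(W = Wn, H = Hn)
}

ref_rss <- function(V, W, H) {
  total <- 0
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    wh <- 0
    for (b in seq_len(ncol(W))) wh <- wh + W[i, b] * H[b, j]
    total <- total + (V[i, j] - wh)^2
  }
  total
}

ref_chord_profile <- function(x, y) {
  n <- length(x)
  slope <- (y[n] - y[1]) / (x[n] - x[1])
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- abs(y[i] - (y[1] + slope * (x[i] - x[1])))
  d[c(1, n)] <- 0
  d
}

ref_mean_consensus <- function(runs) {
  n <- nrow(runs[[1]])
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (b in seq_along(runs)) s <- s + runs[[b]][i, j]
    C[i, j] <- s / length(runs)
  }
  diag(C) <- 1
  C
}

# textbook average-linkage agglomeration on a small dissimilarity matrix,
# returning the cophenetic distance matrix
ref_avg_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      ds <- c()
      for (i in clusters[[a]]) for (j in clusters[[b]]) ds <- c(ds, D[i, j])
      if (mean(ds) < bestd) { bestd <- mean(ds); best <- c(a, b) }
    }
    for (i in clusters[[best[1]]]) for (j in clusters[[best[2]]]) {
      coph[i, j] <- bestd; coph[j, i] <- bestd
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

ref_cophenetic_coefficient <- function(C) {
  D <- 1 - C
  coph <- ref_avg_linkage_cophenetic(D)
  ut <- upper.tri(D)
  stats::cor(D[ut], coph[ut])
}

# random strictly convex decreasing curve: slopes negative, increasing
# toward zero
random_convex_decreasing <- function(n, seed) {
  set.seed(seed)
  slopes <- -sort(rexp(n - 1, rate = 1), decreasing = TRUE)
  x <- seq_len(n)
  y <- 10 + cumsum(c(0, slopes))
  list(x = x, y = y)
}
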