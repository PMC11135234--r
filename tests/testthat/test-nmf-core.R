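test_that("random initialization honors shape, range, determinism and rank bounds", {
  init <- nmf_init(2, 2, 1, seed = 7, scale = 1)
  expect_equal(dim(init$W), c(2L, 1L))
  expect_equal(dim(init$H), c(1L, 2L))
  expect_true(all(init$W > 0 & init$W <= 1))
  expect_true(all(init$H > 0 & init$H <= 1))
  expect_identical(init, nmf_init(2, 2, 1, seed = 7, scale = 1))
  expect_false(identical(init, nmf_init(2, 2, 1, seed = 8, scale = 1)))
  expect_error(nmf_init(3, 4, 5, seed = 1), "rank")
  expect_error(nmf_init(3, 4, 2, seed = 1, scale = 0), "scale")
})

test_that("one Frobenius step matches the hand-computed 1x1 example", {
  up <- nmf_update_frobenius(matrix(1), matrix(1), matrix(2))
  expect_equal(up$H, matrix(1), tolerance = 1e-12)
  expect_equal(up$W, matrix(1), tolerance = 1e-12)
  expect_equal(sum((1 - up$W %*% up$H)^2), 0, tolerance = 1e-12)
})

test_that("one KL step matches the hand-computed 1x1 example", {
  up <- nmf_update_kl(matrix(2), matrix(1), matrix(1))
  expect_equal(up$H, matrix(2), tolerance = 1e-12)
})

test_that("an exact positive factorization is a fixed point of both rules", {
  set.seed(42)
  W <- matrix(runif(6, 0.5, 2), 3, 2)
  H <- matrix(runif(8, 0.5, 2), 2, 4)
  V <- W %*% H
  for (f in list(nmf_update_frobenius, nmf_update_kl)) {
    up <- f(V, W, H)
    expect_equal(up$H, H, tolerance = 1e-12)
    expect_equal(up$W, W, tolerance = 1e-12)
  }
})

test_that("update steps reject mismatched shapes", {
  expect_error(nmf_update_frobenius(matrix(1, 3, 3), matrix(1, 3, 2), matrix(1, 2, 4)),
               "dimension")
  expect_error(nmf_update_kl(matrix(1, 2, 2), matrix(1, 3, 1), matrix(1, 1, 2)),
               "dimension")
})

test_that("vectorized updates agree with the straight-loop reference to 1e-10", {
  set.seed(11)
  V <- matrix(runif(20, 0.1, 3), 5, 4)
  cur <- ref <- nmf_init(5, 4, 2, seed = 3, scale = max(V))
  for (step in 1:200) {
    cur <- nmf_update_frobenius(V, cur$W, cur$H)
    ref <- ref_frobenius_step(V, ref$W, ref$H)
    if (step %% 50 == 0) {
      expect_equal(cur$W, ref$W, tolerance = 1e-10)
      expect_equal(cur$H, ref$H, tolerance = 1e-10)
    }
  }
  set.seed(12)
  V <- matrix(runif(30, 0.1, 3), 6, 5)
  cur <- ref <- nmf_init(6, 5, 2, seed = 4, scale = max(V))
  for (step in 1:200) {
    cur <- nmf_update_kl(V, cur$W, cur$H)
    ref <- ref_kl_step(V, ref$W, ref$H)
    if (step %% 50 == 0) {
      expect_equal(cur$W, ref$W, tolerance = 1e-10)
      expect_equal(cur$H, ref$H, tolerance = 1e-10)
    }
  }
})

test_that("smoothing matrix is doubly stochastic and matches closed forms", {
  expect_identical(smoothing_matrix(3, 0), diag(3))
  expect_equal(smoothing_matrix(2, 1), matrix(0.5, 2, 2))
  expect_equal(smoothing_matrix(2, 0.5),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2))
  S <- smoothing_matrix(5, 0.3)
  expect_equal(rowSums(S), rep(1, 5))
  expect_equal(colSums(S), rep(1, 5))
  expect_equal(S, t(S))
  expect_error(smoothing_matrix(2, 1.2), "theta")
})

test_that("fit recovers an exact rank-1 product and keeps factors nonnegative", {
  V <- outer(c(1, 2), c(3, 4))
  f <- nmf(V, 1, algorithm = "lee", seed = 5, conn_stall = 200L)
  expect_lt(f$rss, 1e-8)
  expect_gte(min(f$W), 0)
  expect_gte(min(f$H), 0)
  f2 <- nmf(V, 1, algorithm = "lee", seed = 5, conn_stall = 200L)
  expect_identical(f$rss, f2$rss)
  expect_error(nmf(V, 3), "rank")
  expect_error(nmf(matrix(c(1, -1, 2, 3), 2, 2), 1), "negative")
})

test_that("objective traces never increase beyond 1e-9 relative (both rules)", {
  set.seed(99)
  for (inst in 1:5) {
    V <- matrix(runif(80, 0.05, 4), 10, 8)
    st <- nmf_init(10, 8, 3, seed = inst, scale = max(V))
    frob <- kl <- st
    tf <- tk <- numeric(200)
    for (i in 1:200) {
      frob <- nmf_update_frobenius(V, frob$W, frob$H)
      tf[i] <- sum((V - frob$W %*% frob$H)^2)
      kl <- nmf_update_kl(V, kl$W, kl$H)
      WH <- kl$W %*% kl$H
      tk[i] <- sum(V * log(V / WH)) - sum(V) + sum(WH)
    }
    expect_true(all(diff(tf) <= 1e-9 * pmax(abs(tf[-length(tf)]), 1)))
    expect_true(all(diff(tk) <= 1e-9 * pmax(abs(tk[-length(tk)]), 1)))
    expect_gte(min(frob$W, frob$H, kl$W, kl$H), 0)
  }
})

test_that("rss matches the brute-force elementwise oracle and hand sums", {
  expect_equal(rss(diag(2) + 0, list(W = matrix(0, 2, 1), H = matrix(0, 1, 2))), 2)
  set.seed(21)
  V <- matrix(runif(35, 0, 2), 7, 5)
  W <- matrix(runif(21), 7, 3); H <- matrix(runif(15), 3, 5)
  expect_equal(rss(V, list(W = W, H = H)), ref_rss(V, W, H), tolerance = 1e-12)
  expect_equal(rss(W %*% H, list(W = W, H = H)), 0)
  expect_error(rss(V, list(W = matrix(1, 3, 2), H = matrix(1, 2, 5))), "dimension")
})

test_that("rescaling the target rescales the Frobenius RSS quadratically", {
  V <- lowrank_matrix(12, 9, 3, noise_sd = 0.05, seed = 8)
  base <- nmf(V, 3, algorithm = "lee", seed = 2)
  for (cc in c(0.1, 7)) {
    sc <- nmf(cc * V, 3, algorithm = "lee", seed = 2)
    expect_equal(sc$rss, cc^2 * base$rss, tolerance = 1e-6)
  }
})

test_that("best-of-restarts reaches near-exact recovery on an exact product", {
  V <- lowrank_matrix(20, 15, 3, noise_sd = 0, seed = 13)
  best <- min(vapply(1:10, function(j)
    nmf(V, 3, algorithm = "lee", seed = j)$rss, numeric(1)))
  expect_lt(best, 1e-6 * sum(V^2))
})

test_that("nsNMF fit interposes the smoothing matrix and stays nonnegative", {
  V <- lowrank_matrix(15, 10, 3, noise_sd = 0.1, seed = 3)
  f <- nmf(V, 3, algorithm = "nsnmf", theta = 0.5, seed = 1)
  expect_equal(f$S, smoothing_matrix(3, 0.5))
  expect_gte(min(f$W), 0)
  expect_gte(min(f$H), 0)
  expect_equal(f$rss, sum((V - f$W %*% f$S %*% f$H)^2), tolerance = 1e-12)
  # KL objective trace non-increasing for the smoothed model too
  tr <- f$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
})
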