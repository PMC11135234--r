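test_that("an all-ones mask reproduces the unmasked Frobenius fit bit for bit", {
  V <- lowrank_matrix(12, 9, 3, noise_sd = 0.2, seed = 14)
  plain <- nmf(V, 3, algorithm = "lee", seed = 77)
  masked <- nmf_masked(V, matrix(1, 12, 9), 3, algorithm = "lee", seed = 77)
  expect_identical(plain$W, masked$W, ignore_attr = TRUE)
  expect_identical(plain$H, masked$H, ignore_attr = TRUE)
  expect_identical(plain$n_iter, masked$n_iter)
})

test_that("masked fit imputes a held-out entry of a rank-1 product", {
  V <- outer(c(1, 2, 3), c(1, 2))
  mask <- matrix(1, 3, 2); mask[2, 2] <- 0
  fit <- nmf_masked(V, mask, 1, algorithm = "lee", seed = 3,
                    conn_stall = 500L, max_iter = 5000L)
  imputed <- (fit$W %*% fit$H)[2, 2]
  expect_equal(imputed, 4, tolerance = 1e-4)
})

test_that("masked objective traces never increase beyond 1e-9 relative", {
  set.seed(23)
  for (i in 1:5) {
    V <- matrix(runif(54, 0.1, 3), 9, 6)
    mask <- matrix(rbinom(54, 1, 0.9), 9, 6)
    mask[rowSums(mask) < 3, ] <- 1
    fit <- nmf_masked(V, mask, 2, algorithm = "lee", seed = i, max_iter = 300L)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("masked fit rejects schemes starving a row or column", {
  V <- lowrank_matrix(5, 4, 2, seed = 1)
  mask <- matrix(1, 5, 4); mask[2, ] <- 0
  expect_error(nmf_masked(V, mask, 2, seed = 1), "row 2")
  mask <- matrix(1, 5, 4); mask[, 3] <- c(1, 0, 0, 0, 0)
  expect_error(nmf_masked(V, mask, 2, seed = 1), "column 3")
  expect_error(nmf_masked(V, matrix(2, 5, 4), 2), "0 or 1")
})

test_that("PRESS is deterministic and prefers the true rank strongly", {
  V <- lowrank_matrix(40, 15, 2, noise_sd = 0, seed = 44)
  scheme <- holdout_scheme("random_fraction", fraction = 0.05,
                           n_repeats = 3, seed = 10)
  p2 <- nmf_press(V, 2, scheme, algorithm = "lee")
  p1 <- nmf_press(V, 1, scheme, algorithm = "lee")
  expect_gt(as.numeric(p1) / as.numeric(p2), 10)
  expect_identical(as.numeric(nmf_press(V, 2, scheme, algorithm = "lee")),
                   as.numeric(p2))
})

test_that("holding out more entries does not break exact completion at the true rank", {
  V <- lowrank_matrix(30, 12, 2, noise_sd = 0, seed = 8)
  small <- nmf_press(V, 2, holdout_scheme(fraction = 0.05, n_repeats = 2, seed = 5),
                     algorithm = "lee")
  large <- nmf_press(V, 2, holdout_scheme(fraction = 0.25, n_repeats = 2, seed = 5),
                     algorithm = "lee")
  expect_gte(as.numeric(large), as.numeric(small) - 1e-3)
  expect_lt(as.numeric(large), 1e-3)
})

test_that("PRESS shows an overfitting penalty on noisy low-rank data", {
  cc <- simulate_catalog(n_processes = 5, n_genomes = 12, exposure_scale = 500,
                         seed = 19)
  V <- preprocess_matrix(cc$counts, min_total_count = 1, verbose = FALSE)
  scheme <- holdout_scheme(fraction = 0.05, n_repeats = 2, seed = 3)
  at_true <- nmf_press(V, 5, scheme, algorithm = "lee", max_rank = 11)
  at_max <- nmf_press(V, 11, scheme, algorithm = "lee", max_rank = 11)
  expect_gt(as.numeric(at_max), as.numeric(at_true))
})

test_that("scheme construction validates its arguments", {
  expect_error(holdout_scheme(fraction = 0.7), "fraction")
  expect_error(holdout_scheme(n_repeats = 0), "n_repeats")
  expect_error(select_rank_press(lowrank_matrix(6, 5, 2, seed = 1), ranks = 3),
               "at least 2")
})
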