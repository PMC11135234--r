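test_that("connectivity follows the argmax assignment with low-index ties", {
  expect_equal(connectivity_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)),
               diag(2), ignore_attr = TRUE)
  expect_equal(connectivity_matrix(matrix(c(1, 0.5, 1, 0.5), 2, 2)),
               matrix(1, 2, 2), ignore_attr = TRUE)
  # tied column goes to the first metagene, matching sample 1's assignment
  H <- matrix(c(0.5, 0.5, 0.9, 0.1), 2, 2)
  C <- connectivity_matrix(H)
  expect_equal(C, matrix(1, 2, 2), ignore_attr = TRUE)
  expect_warning(connectivity_matrix(matrix(c(0, 0, 1, 2), 2, 2)), "all-zero")
})

test_that("connectivity matrices are symmetric block relations", {
  set.seed(5)
  for (i in 1:10) {
    H <- matrix(runif(4 * 9), 4, 9)
    C <- connectivity_matrix(H)
    expect_identical(C, t(C))
    expect_equal(diag(C), rep(1, 9), ignore_attr = TRUE)
    expect_true(all(C %in% c(0, 1)))
    # transitivity: C[i,j] = 1 and C[j,k] = 1 imply C[i,k] = 1
    expect_true(all((C %*% C > 0) == (C == 1)))
  }
})

test_that("consensus is the elementwise mean and is idempotent for duplicates", {
  C1 <- connectivity_matrix(matrix(c(0.9, 0.1, 0.1, 0.9, 0.8, 0.2), 2, 3))
  expect_equal(consensus_matrix(list(C1, C1, C1)), C1, ignore_attr = TRUE)
  C2 <- connectivity_matrix(matrix(c(0.9, 0.1, 0.1, 0.9, 0.1, 0.9), 2, 3))
  cons <- consensus_matrix(list(C1, C2))
  expect_equal(cons[2, 3], 0.5)
  set.seed(7)
  runs <- lapply(1:10, function(i) connectivity_matrix(matrix(runif(3 * 8), 3, 8)))
  expect_equal(consensus_matrix(runs), ref_mean_consensus(runs),
               tolerance = 1e-15, ignore_attr = TRUE)
  # duplicating the whole run list never changes the mean
  expect_equal(consensus_matrix(c(runs, runs)), consensus_matrix(runs))
  expect_error(consensus_matrix(list()), "non-empty")
})

test_that("perfect two-block consensus has cophenetic coefficient exactly 1", {
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1
  expect_equal(as.numeric(cophenetic_coefficient(C)), 1, tolerance = 1e-12)
})

test_that("nested ultrametric block consensus also attains 1", {
  C <- matrix(0.1, 8, 8)               # across halves: distance 0.9
  C[1:4, 1:4] <- 0.5; C[5:8, 5:8] <- 0.5
  C[1:2, 1:2] <- 0.8; C[3:4, 3:4] <- 0.8
  C[5:6, 5:6] <- 0.8; C[7:8, 7:8] <- 0.8
  diag(C) <- 1
  expect_equal(as.numeric(cophenetic_coefficient(C)), 1, tolerance = 1e-12)
})

test_that("uniform consensus yields a flagged undefined value, not zero", {
  C <- matrix(0.4, 5, 5); diag(C) <- 1
  out <- cophenetic_coefficient(C)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  expect_error(cophenetic_coefficient(matrix(1, 2, 2)), "at least 3")
})

test_that("coefficient matches a manual average-linkage computation on 4 samples", {
  set.seed(31)
  for (i in 1:5) {
    M <- matrix(runif(16, 0, 1), 4, 4)
    C <- (M + t(M)) / 2
    diag(C) <- 1
    expect_equal(as.numeric(cophenetic_coefficient(C)),
                 ref_cophenetic_coefficient(C), tolerance = 1e-12)
  }
})

test_that("permuting samples leaves the cophenetic coefficient unchanged", {
  set.seed(17)
  M <- matrix(runif(64), 8, 8)
  C <- (M + t(M)) / 2
  diag(C) <- 1
  base <- as.numeric(cophenetic_coefficient(C))
  for (i in 1:5) {
    p <- sample(8)
    expect_equal(as.numeric(cophenetic_coefficient(C[p, p])), base,
                 tolerance = 1e-12)
  }
})
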