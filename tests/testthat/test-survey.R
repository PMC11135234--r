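test_that("survey RSS collapses at the true rank of an exact product", {
  V <- lowrank_matrix(30, 20, 3, noise_sd = 0, seed = 9)
  sv <- nmf_rank_survey(V, 2:6, nrun = 5, algorithm = "lee", seed = 4,
                        conn_stall = 1e9)
  expect_length(sv$rss_curve, 5L)
  expect_length(sv$cophenetic_curve, 5L)
  expect_true(all(sv$rss_curve >= 0))
  # orders-of-magnitude drop entering the true rank, then a floor that is
  # negligible against the matrix scale (multiplicative updates approach
  # exact recovery only in the iteration limit)
  expect_gt(sv$rss_curve[1] / sv$rss_curve[2], 100)
  expect_true(all(sv$rss_curve[2:5] < 1e-4 * sum(V^2)))
})

test_that("surveys are deterministic and reject invalid rank grids", {
  V <- lowrank_matrix(12, 8, 2, noise_sd = 0.05, seed = 2)
  s1 <- nmf_rank_survey(V, 2:4, nrun = 3, algorithm = "brunet", seed = 11)
  s2 <- nmf_rank_survey(V, 2:4, nrun = 3, algorithm = "brunet", seed = 11)
  expect_identical(s1$rss_curve, s2$rss_curve)
  expect_identical(s1$cophenetic_curve, s2$cophenetic_curve)
  expect_error(nmf_rank_survey(V, integer(0), nrun = 2), "non-empty")
  expect_error(nmf_rank_survey(V, c(2, 9), nrun = 2), "exceed")
  expect_error(nmf_rank_survey(V, 1:4, nrun = 2), "below 2")
  expect_error(nmf_rank_survey(V, c(3, 3, 4), nrun = 2), "increasing")
})

test_that("single-run consensus is binary so its cophenetic entry is 1 or flagged", {
  V <- lowrank_matrix(15, 10, 2, noise_sd = 0.1, seed = 6)
  sv <- nmf_rank_survey(V, 2:4, nrun = 1, algorithm = "lee", seed = 3)
  for (k in seq_along(sv$ranks)) {
    expect_true(all(sv$consensus[[k]] %in% c(0, 1)))
    expect_true(is.na(sv$cophenetic_curve[k]) ||
                  abs(sv$cophenetic_curve[k] - 1) < 1e-12)
  }
})

test_that("best-of-restart RSS is near-monotone in rank and improves with restarts", {
  V <- matrix(runif(50 * 30, 0.1, 5), 50, 30)
  rownames(V) <- paste0("g", 1:50); colnames(V) <- paste0("s", 1:30)
  s10 <- nmf_rank_survey(V, 2:8, nrun = 10, algorithm = "lee", seed = 20,
                         keep_consensus = FALSE)
  # non-increasing up to 1% relative slack per step
  steps <- diff(s10$rss_curve)
  expect_true(all(steps <= 0.01 * s10$rss_curve[-length(s10$rss_curve)]))
  # restart seeds nest: more restarts can only lower the best RSS
  s5 <- nmf_rank_survey(V, 2:8, nrun = 5, algorithm = "lee", seed = 20,
                        keep_consensus = FALSE)
  expect_true(all(s10$rss_curve <= s5$rss_curve + 1e-9))
})

test_that("survey tables round-trip through TSV", {
  V <- lowrank_matrix(12, 9, 2, noise_sd = 0.1, seed = 5)
  sv <- nmf_rank_survey(V, 2:4, nrun = 2, algorithm = "lee", seed = 1)
  tmp <- tempfile(fileext = ".tsv")
  cdir <- tempfile()
  write_survey(sv, tmp, consensus_dir = cdir)
  tab <- read.delim(tmp)
  expect_equal(tab$rank, sv$ranks)
  expect_equal(tab$rss, sv$rss_curve, tolerance = 1e-12)
  expect_true(file.exists(file.path(cdir, "consensus_rank3.tsv")))
})

test_that("survey plot renders to a graphics device", {
  V <- lowrank_matrix(10, 8, 2, noise_sd = 0.1, seed = 5)
  sv <- nmf_rank_survey(V, 2:5, nrun = 2, algorithm = "lee", seed = 1)
  f <- tempfile(fileext = ".pdf")
  pdf(f)
  expect_no_error(plot(sv, knee = select_rank(sv)))
  dev.off()
  expect_true(file.size(f) > 0)
})
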