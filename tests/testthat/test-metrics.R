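test_that("rmse matches hand computations", {
  a <- matrix(0.5, 2, 2)
  expect_identical(rmse(a, a), 0)
  expect_equal(rmse(a, a + 0.1), 0.1, tolerance = 1e-12)
  ref <- matrix(c(0.2, 0.4, 0.1, 0.3), 2, 2)
  tst <- ref + matrix(c(0.1, 0.3, 0, 0), 2, 2)
  expect_equal(rmse(ref, tst), sqrt((0.01 + 0.09) / 4), tolerance = 1e-9)
  expect_equal(rmse(ref, tst), 0.1581, tolerance = 1e-4)
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("snr_db matches closed forms and handles edge cases", {
  ref <- matrix(runif(64), 8, 8)
  expect_equal(as.numeric(snr_db(ref, ref + ref)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(snr_db(ref, ref + ref / 10)), 20, tolerance = 1e-9)
  expect_identical(as.numeric(snr_db(ref, ref)), Inf)
  expect_error(snr_db(matrix(0, 2, 2), matrix(1, 2, 2)), "all-zero")
})

test_that("snr decreases as independent noise grows", {
  set.seed(1)
  ref <- matrix(runif(400), 20, 20)
  snrs <- vapply(c(0.01, 0.05, 0.2), function(s) {
    as.numeric(snr_db(ref, ref + matrix(rnorm(400, sd = s), 20, 20)))
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("rmse and snr are invariant to simultaneous spatial permutation", {
  set.seed(2)
  ref <- matrix(runif(36), 6, 6)
  tst <- ref + matrix(rnorm(36, sd = 0.05), 6, 6)
  p <- sample(36)
  rp <- matrix(ref[p], 6, 6)
  tp <- matrix(tst[p], 6, 6)
  expect_equal(rmse(ref, tst), rmse(rp, tp), tolerance = 1e-12)
  expect_equal(as.numeric(snr_db(ref, tst)), as.numeric(snr_db(rp, tp)),
               tolerance = 1e-12)
})

test_that("ccc matches its closed-form examples", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_warning(out <- ccc(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_true(is.na(out))
  expect_error(ccc(1:3, 1:4), "equal length")
})

test_that("ccc is bounded by Pearson correlation in magnitude", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30) + runif(1, -1, 1)
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    expect_equal(ccc(x, x), 1, tolerance = 1e-12)
  }
})

test_that("categorize_ccc uses the printed half-open bins", {
  f <- categorize_ccc(c(0.64, 0.65, 0.85))
  expect_equal(unname(f), c(1, 1, 1) / 3)
  expect_equal(unname(categorize_ccc(c(1, 1))), c(0, 0, 1))
  expect_equal(unname(categorize_ccc(c(0.5, 0.7, 0.9, 0.95))),
               c(0.25, 0.25, 0.5))
  expect_equal(sum(categorize_ccc(runif(50, -1, 1))), 1)
})

test_that("mean_ccc_ci is seeded and degenerates to a point for constants", {
  v <- rep(0.8, 10)
  ci <- mean_ccc_ci(v, n_boot = 500, seed = 1)
  expect_equal(unname(ci), c(0.8, 0.8, 0.8))
  set.seed(99)
  v <- runif(40, 0.6, 1)
  a <- mean_ccc_ci(v, n_boot = 500, seed = 7)
  b <- mean_ccc_ci(v, n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_lte(a["lo"], a["mean"])
  expect_gte(a["hi"], a["mean"])
  expect_warning(mean_ccc_ci(v, n_boot = 50, seed = 1), "unstable")
})

test_that("bootstrap interval covers the true mean at nominal-ish rate", {
  true_mean <- 0.85
  cover <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    set.seed(1000 + i)
    v <- true_mean + rnorm(90, sd = 0.08)
    ci <- mean_ccc_ci(v, n_boot = 400, seed = i)
    if (ci["lo"] <= true_mean && true_mean <= ci["hi"]) cover <- cover + 1
  }
  expect_gte(cover / n_sim, 0.90)
})

test_that("rank-sum comparison matches brute-force enumeration at small n", {
  set.seed(4)
  for (i in 1:10) {
    a <- round(runif(5), 3)
    b <- round(runif(6), 3)
    res <- compare_ccc_distributions(a, b)
    # statistic is the literal rank sum
    expect_equal(res$statistic, sum(rank(c(a, b))[1:5]))
    # p-value close to the exact permutation p
    expect_equal(res$p_value, exact_ranksum_p(a, b), tolerance = 0.06)
    # and close to R's reference implementation of the same approximation
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-9)
    expect_equal(res$u, unname(wt$statistic), tolerance = 1e-9)
  }
})

test_that("rank-sum extremes and degenerate cases behave", {
  res <- compare_ccc_distributions(rep(0.9, 20) + (1:20) * 1e-4,
                                   rep(0.1, 20) + (1:20) * 1e-4)
  expect_lt(res$p_value, 1e-6)
  same <- compare_ccc_distributions(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_gt(same$p_value, 0.9)
  expect_warning(out <- compare_ccc_distributions(rep(1, 3), rep(1, 3)),
                 "degenerate")
  expect_true(is.na(out$p_value))
})

test_that("ccc_cdf is a right-continuous step function ending at 1", {
  cdf <- ccc_cdf(c(0.2, 0.4, 0.4, 0.8))
  expect_equal(cdf$cdf[cdf$value == 0.4], 0.75)
  expect_equal(cdf$cdf[length(cdf$cdf)], 1)
  expect_true(all(diff(cdf$cdf) > 0))
  one <- ccc_cdf(0.5)
  expect_identical(one$value, 0.5)
  expect_identical(one$cdf, 1)
})
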