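test_that("clamp/rescale clips to the labelled range and maps to [0,1]", {
  expect_equal(clamp_rescale(12, 2, 10), 1)
  expect_equal(clamp_rescale(6, 2, 10), 0.5)
  expect_equal(clamp_rescale(2, 2, 10), 0)
  expect_equal(clamp_rescale(c(-5, NA, 11), 2, 10), c(0, NA, 1))
  expect_error(clamp_rescale(1, 3, 3), "zero range")
})

test_that("MAD profile is per-column with expected degenerate behaviour", {
  m <- loglr_matrix_fixture(cbind(c(1, 2, 3), c(5, 5, 5)))
  mads <- mad_profile(m)
  expect_equal(mads[2], 0)
  expect_equal(mads[1], mad(c(1, 2, 3)))
  expect_equal(mad(c(1, 2, 3), constant = 1), 1) # median |x - 2| = 1
  one_row <- loglr_matrix_fixture(matrix(rnorm(5), nrow = 1))
  expect_equal(mad_profile(one_row), rep(0, 5))
})

test_that("adaptive lambda follows the display formula", {
  expect_equal(adaptive_lambda(c(1, 2, 1)),
               c(0.176777, 0.353553, 0.176777), tolerance = 1e-5)
  expect_equal(adaptive_lambda(c(2, 2, 2, 2)), rep(0, 4))
  expect_equal(adaptive_lambda(rep(0, 6)), rep(0, 6))
  # invariant to uniform rescaling of the MADs (hence to the MAD constant)
  set.seed(7)
  mads <- abs(rnorm(50))
  for (c in c(1 / 1.4826, 3, 100)) {
    expect_equal(adaptive_lambda(c * mads), adaptive_lambda(mads))
  }
})

test_that("shrinkage contracts columns toward zero by 1/(1+lambda)", {
  v <- matrix(c(2, -2, 4, -4), nrow = 2)
  m <- loglr_matrix_fixture(v)
  expect_identical(shrink_loglr(m, c(0, 0))$values, v)
  shr <- shrink_loglr(m, c(1, 3))$values
  expect_equal(shr, cbind(c(1, -1), c(1, -1)))
  expect_true(all(abs(shr) <= abs(v)))
  expect_error(shrink_loglr(m, c(-1, 0)), "non-negative")
})

test_that("monotonicity direction follows the Spearman sign", {
  up <- loglr_matrix_fixture(rbind(c(-1, 0, 1), c(-1, 0, 1)))
  down <- loglr_matrix_fixture(rbind(c(1, 0, -1), c(1, 0, -1)))
  flat <- loglr_matrix_fixture(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(direction_of_monotonicity(up), 1)
  expect_equal(direction_of_monotonicity(down), -1)
  expect_error(direction_of_monotonicity(flat), "undefined")
})

test_that("isotonic regression pools violators and is idempotent", {
  m <- loglr_matrix_fixture(matrix(c(0, 1, 0.5), nrow = 1))
  expect_equal(monotonize(m, 1)$values[1, ], c(0, 0.75, 0.75))
  mono <- matrix(c(-2, 0, 0, 3), nrow = 1)
  expect_equal(monotonize(loglr_matrix_fixture(mono), 1)$values, mono)
  # decreasing direction mirrors the increasing fit
  expect_equal(
    monotonize(loglr_matrix_fixture(matrix(c(0.5, 1, 0), nrow = 1)),
               -1)$values[1, ],
    c(0.75, 0.75, 0)
  )
})

test_that("row-wise isotonic fits match the max-min closed-form oracle", {
  set.seed(19)
  for (i in 1:40) {
    len <- sample(2:6, 1)
    y <- rnorm(len)
    fit <- monotonize(loglr_matrix_fixture(matrix(y, nrow = 1)), 1)
    expect_equal(fit$values[1, ], isotonic_oracle(y), tolerance = 1e-10)
  }
})

test_that("sign-test CI ranks invert the exact binomial", {
  expect_equal(sign_test_ci_ranks(10, 0.95), c(lo = 2, hi = 9))
  # exhaustive-scan oracle over n, plus the resampling default n = 1000
  for (n in c(6:50, 1000)) {
    ranks <- sign_test_ci_ranks(n, 0.95)
    alpha <- 0.025
    ks <- 1:n
    admissible <- ks[pbinom(ks - 1, n, 0.5) <= alpha]
    expect_equal(unname(ranks[["lo"]]), max(admissible))
    expect_equal(ranks[["hi"]], n + 1 - ranks[["lo"]])
    coverage <- 1 - 2 * pbinom(ranks[["lo"]] - 1, n, 0.5)
    expect_gte(coverage, 0.95)
  }
  expect_error(sign_test_ci_ranks(5, 0.95), "too small")
})

test_that("curve summary takes medians and order-statistic bounds", {
  # identical monotone rows: median and both bounds equal the row
  row <- sort(rnorm(20))
  m <- loglr_matrix_fixture(matrix(rep(row, 10), nrow = 10, byrow = TRUE))
  cv <- summarize_curve(m, 1, calibration_config(n_resamples = 10))
  expect_equal(cv$median_loglr, row)
  expect_equal(cv$lower_loglr, row)
  expect_equal(cv$upper_loglr, row)

  # a column holding a permutation of 1..1000 across monotone rows
  set.seed(3)
  base <- sample(1:1000)
  m2 <- loglr_matrix_fixture(cbind(base, base + 1, base + 2))
  cv2 <- summarize_curve(m2, 1, calibration_config(n_resamples = 1000))
  ranks <- sign_test_ci_ranks(1000, 0.95)
  expect_equal(cv2$median_loglr[1], 500.5)
  expect_equal(cv2$lower_loglr[1], ranks[["lo"]])
  expect_equal(cv2$upper_loglr[1], ranks[["hi"]])
  expect_true(all(cv2$lower_loglr <= cv2$median_loglr &
                    cv2$median_loglr <= cv2$upper_loglr))
})

test_that("scores map to nearest grid index with ties toward the lower", {
  curve <- curve_fixture(median = c(0, 1, 2), lower = c(-1, 0, 1),
                         upper = c(1, 2, 3))
  tr <- map_to_scores(curve, c(0, 0.5, 1))
  expect_equal(tr$lr, exp(c(0, 1, 2)))
  expect_equal(tr$lr_lower, exp(c(-1, 0, 1)))
  # exact midpoint between nodes 1 and 2 resolves to the lower index
  mid <- map_to_scores(curve, 0.25)
  expect_equal(mid$lr, exp(0))
  # equal scores get identical triples; monotone curve gives monotone LRs
  two <- map_to_scores(curve, c(0.7, 0.7))
  expect_identical(two[1, ], two[2, ])
  set.seed(8)
  s <- sort(runif(50))
  expect_true(all(diff(map_to_scores(curve, s)$lr) >= 0))
  expect_error(map_to_scores(curve, 1.2), "\\[0, 1\\]")
})

test_that("identical class distributions give near-zero median log-LRs", {
  ts <- null_truthset(n = 25)
  truthset <- validate_truthset(ts, "score", "class")
  m <- compute_loglr_matrix(truthset, quick_config())
  med <- apply(m$values, 2, median)
  interior <- m$grid > 0.2 & m$grid < 0.8
  expect_lt(max(abs(med[interior])), 0.6)
  expect_equal(dim(m$values), c(50, 256))
})

test_that("the log-LR matrix is bit-identical for a fixed seed", {
  truthset <- validate_truthset(separated_truthset(), "score", "class")
  m1 <- compute_loglr_matrix(truthset, quick_config())
  m2 <- compute_loglr_matrix(truthset, quick_config())
  expect_identical(m1$values, m2$values)
  m3 <- compute_loglr_matrix(truthset, quick_config(seed = 999L))
  expect_false(identical(m1$values, m3$values))
})

test_that("median log-LR tracks the analytic Gaussian density ratio", {
  spec <- separated_spec(n = 200L, seed = 41L)
  ts <- generate_truthset(spec)
  loglr_fn <- attr(ts, "loglr_fn")
  truthset <- validate_truthset(ts, "score", "class")
  cfg <- calibration_config(n_resamples = 200L, seed = 181L)
  m <- compute_loglr_matrix(truthset, cfg)
  med <- apply(m$values, 2, median)
  # compare where both class densities have effective sample support
  # (between the class means); further out the benign kernel tail and
  # the density floor dominate and the comparison is not meaningful
  for (x0 in c(0.5, 0.55, 0.6)) {
    g_at <- clamp_rescale(x0, truthset$labelled_min,
                          truthset$labelled_max)
    idx <- which.min(abs(m$grid - g_at))
    expect_lt(abs(med[idx] - loglr_fn(x0)), 0.5)
  }
})
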