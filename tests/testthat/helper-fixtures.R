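# shared fixtures: small synthetic truthsets and reduced configs so the
# default test run stays fast; full-scale parameters are exercised only in
# the acceptance tests

quick_config <- function(...) {
  args <- modifyList(
    list(n_resamples = 50L, grid_size = 256L, seed = 181L),
    list(...)
  )
  do.call(calibration_config, args)
}

# well-separated Gaussian classes, direction +1 (high score = pathogenic)
separated_spec <- function(n = 20L, n_unlabelled = 0L, seed = 3L) {
  truthset_spec(
    benign = dist_gaussian(0.3, 0.1),
    pathogenic = dist_gaussian(0.7, 0.1),
    n_benign = n, n_pathogenic = n, n_unlabelled = n_unlabelled,
    seed = seed
  )
}

separated_truthset <- function(n = 20L, n_unlabelled = 0L, seed = 3L) {
  generate_truthset(separated_spec(n, n_unlabelled, seed))
}

# both classes share one distribution: no signal, analytic log-LR = 0
null_truthset <- function(n = 25L, seed = 11L) {
  generate_truthset(truthset_spec(
    benign = dist_gaussian(0, 1), pathogenic = dist_gaussian(0, 1),
    n_benign = n, n_pathogenic = n, seed = seed
  ))
}

# independent isotonic-regression oracle: the max-min closed form
# yhat_i = max_{a<=i} min_{b>=i} mean(y[a..b])
isotonic_oracle <- function(y) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  segmean <- function(a, b) (cs[b + 1] - cs[a]) / (b - a + 1)
  vapply(seq_len(n), function(i) {
    max(vapply(seq_len(i), function(a) {
      min(vapply(i:n, function(b) segmean(a, b), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# independent BCV objective for the dense-grid bandwidth oracle
bcv_oracle_objective <- function(h, x) {
  n <- length(x)
  d <- outer(x, x, "-")
  d2 <- d[upper.tri(d)]^2
  delta <- d2 / h^2
  term <- exp(-delta / 4) * (delta^2 - 12 * delta + 12)
  1 / (2 * n * h * sqrt(pi)) + 2 * sum(term) / (64 * n^2 * h * sqrt(pi))
}

loglr_matrix_fixture <- function(values, grid = NULL) {
  if (is.null(grid)) grid <- seq(0, 1, length.out = ncol(values))
  structure(
    list(values = values, grid = grid,
         n_pathogenic = 10L, n_benign = 10L),
    class = "loglr_matrix"
  )
}

curve_fixture <- function(median, lower = median, upper = median,
                          direction = 1, grid = NULL) {
  if (is.null(grid)) grid <- seq(0, 1, length.out = length(median))
  structure(
    list(grid = grid, median_loglr = median, lower_loglr = lower,
         upper_loglr = upper, direction = direction),
    class = "calibration_curve"
  )
}
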