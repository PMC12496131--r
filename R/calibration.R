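#' Calibration configuration
#'
#' Bundles the tunable parameters of the bootstrapped log-likelihood-ratio
#' pipeline. Defaults reproduce the standard run: 1000 bootstrap resamples,
#' a 1024-point common grid on \[0, 1\], biased cross-validation bandwidths
#' re-selected per class per resample, 95% sign-test confidence bounds for
#' the median, and a fixed seed so repeated runs are identical.
#'
#' @param n_resamples Number of bootstrap resamples, default 1000.
#' @param grid_size Number of equidistant common-grid points, default 1024.
#' @param selector Bandwidth selector, see [bw_select()]; default `"bcv"`.
#' @param ci_level Two-sided confidence level for the median, default 0.95.
#' @param seed Integer seed for the resampling stream; fixed default.
#' @param prior Prior probability of pathogenicity, default 0.1.
#' @param density_floor Floor applied to projected densities before taking
#'   logs, so grid regions without support in one class yield large but
#'   finite log-LRs; default 1e-10.
#' @param kde_cut KDE grid extension in bandwidth units, default 3.
#' @param bw_per_resample Re-select the bandwidth for every resample
#'   (default `TRUE`); `FALSE` selects once per class on the full labelled
#'   sets, which is faster and usually very close.
#' @param rounding Rounding convention for the very-strong likelihood
#'   point, see [very_strong_threshold()].
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(n_resamples = 1000L, grid_size = 1024L,
                               selector = c("bcv", "nrd0", "sj", "ucv"),
                               ci_level = 0.95, seed = 181L, prior = 0.1,
                               density_floor = 1e-10, kde_cut = 3,
                               bw_per_resample = TRUE,
                               rounding = c("floor", "nearest")) {
  selector <- match.arg(selector)
  rounding <- match.arg(rounding)
  if (n_resamples < 2) abort("`n_resamples` must be at least 2.")
  if (grid_size < 2) abort("`grid_size` must be at least 2.")
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  check_prior(prior)
  if (density_floor <= 0) abort("`density_floor` must be positive.")
  structure(
    list(
      n_resamples = as.integer(n_resamples),
      grid_size = as.integer(grid_size),
      selector = selector, ci_level = ci_level, seed = as.integer(seed),
      prior = prior, density_floor = density_floor, kde_cut = kde_cut,
      bw_per_resample = isTRUE(bw_per_resample), rounding = rounding
    ),
    class = "calibration_config"
  )
}

#' Clamp scores to the labelled range and rescale to the unit interval
#'
#' Scores are clipped into `[labelled_min, labelled_max]` (so likelihood
#' ratios are never extrapolated beyond the observed truthset range) and
#' mapped affinely onto \[0, 1\], which makes the pipeline invariant to the
#' scale and offset of the input scores.
#'
#' @param scores Numeric scores in original units; `NA` passes through.
#' @param labelled_min,labelled_max Range of the labelled truthset scores.
#' @return Scores in \[0, 1\].
#' @export
clamp_rescale <- function(scores, labelled_min, labelled_max) {
  if (!is.finite(labelled_min) || !is.finite(labelled_max) ||
      labelled_max <= labelled_min) {
    abort("Degenerate truthset: labelled scores span a zero range.")
  }
  s <- pmin(pmax(scores, labelled_min), labelled_max)
  (s - labelled_min) / (labelled_max - labelled_min)
}

#' Bootstrapped log likelihood-ratio matrix
#'
#' The resampling core of the calibration. For each of
#' `config$n_resamples` resamples, the rescaled pathogenic and benign
#' truthset scores are resampled with replacement (preserving class sizes),
#' a bandwidth is selected per class, each class density is estimated on
#' its own `grid_size`-point grid and projected onto the common equidistant
#' grid on \[0, 1\], densities are floored at `config$density_floor`, and
#' the row is the difference of class log-densities. The default
#' configuration therefore yields a 1000 x 1024 matrix of log-LRs.
#'
#' Resamples on which bandwidth selection fails (e.g. a resample that
#' collapses onto a single value) are redrawn; more than 1% redraws is an
#' error. A fixed seed in `config` makes the matrix fully reproducible.
#'
#' @param truthset A `truthset_scores` object from [validate_truthset()].
#' @param config A [calibration_config()].
#' @return A list of class `loglr_matrix` with elements `values`
#'   (`n_resamples` x `grid_size` matrix), `grid` (common grid on \[0, 1\])
#'   and `n_pathogenic`, `n_benign`.
#' @export
compute_loglr_matrix <- function(truthset, config = calibration_config()) {
  stopifnot(inherits(truthset, "truthset_scores"))
  p <- clamp_rescale(truthset$pathogenic, truthset$labelled_min,
                     truthset$labelled_max)
  b <- clamp_rescale(truthset$benign, truthset$labelled_min,
                     truthset$labelled_max)
  np <- length(p)
  nb <- length(b)
  grid <- common_grid(config$grid_size)
  values <- matrix(NA_real_, nrow = config$n_resamples,
                   ncol = config$grid_size)

  # root seed spawns one substream seed per resample, so row r does not
  # depend on how earlier rows consumed the stream
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  substreams <- sample.int(.Machine$integer.max - 1L, config$n_resamples)

  fixed_bw <- NULL
  if (!config$bw_per_resample) {
    fixed_bw <- list(p = bw_select(p, config$selector),
                     b = bw_select(b, config$selector))
  }

  max_redraws <- max(1, ceiling(0.01 * config$n_resamples))
  redraws <- 0L
  for (r in seq_len(config$n_resamples)) {
    set.seed(substreams[r])
    repeat {
      rp <- p[sample.int(np, np, replace = TRUE)]
      rb <- b[sample.int(nb, nb, replace = TRUE)]
      bw <- if (is.null(fixed_bw)) {
        tryCatch(
          list(p = bw_select(rp, config$selector),
               b = bw_select(rb, config$selector)),
          error = function(e) NULL
        )
      } else {
        fixed_bw
      }
      if (!is.null(bw)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        abort(paste0(
          "More than 1% of resamples required redrawing (", redraws,
          " redraws); the truthset is too degenerate to calibrate."
        ))
      }
    }
    dp <- project_to_common_grid(
      kde_on_grid(rp, bw$p, config$grid_size, config$kde_cut), grid
    )
    db <- project_to_common_grid(
      kde_on_grid(rb, bw$b, config$grid_size, config$kde_cut), grid
    )
    values[r, ] <- log(pmax(dp, config$density_floor)) -
      log(pmax(db, config$density_floor))
  }
  if (redraws > 0) {
    inform(paste0(redraws, " resample(s) redrawn after bandwidth failure."))
  }
  structure(
    list(values = values, grid = grid, n_pathogenic = np, n_benign = nb),
    class = "loglr_matrix"
  )
}

common_grid <- function(grid_size) {
  seq(0, 1, length.out = grid_size)
}

#' Per-grid-point spread and adaptive regularization weights
#'
#' `mad_profile()` returns the median absolute deviation of the log-LRs at
#' each grid index (normal-consistency constant 1.4826; the weights below
#' are invariant to this choice). `adaptive_lambda()` converts the MAD
#' profile into shrinkage weights
#' \deqn{\lambda_i = \frac{\mathrm{MAD}_i}{\max_j \mathrm{MAD}_j} \cdot
#'   \frac{\sqrt{\sum_j (\mathrm{MAD}_{j+1} - \mathrm{MAD}_j)^2}}
#'        {\sum_j \mathrm{MAD}_j}}
#' whose first factor targets the locally most variable grid regions and
#' whose second factor, a root-sum-of-squares roughness penalty over lagged
#' differences, scales the whole profile by how erratic the spread is
#' across the score range. A flat MAD profile gives all-zero weights.
#'
#' @param m A `loglr_matrix`.
#' @return `mad_profile()`: non-negative vector, one value per grid point.
#' @export
mad_profile <- function(m) {
  stopifnot(inherits(m, "loglr_matrix"))
  apply(m$values, 2, stats::mad)
}

#' @rdname mad_profile
#' @param mads Non-negative MAD values, one per grid point.
#' @return `adaptive_lambda()`: non-negative weights, one per grid point.
#' @export
adaptive_lambda <- function(mads) {
  if (length(mads) < 2 || any(mads < 0) || any(!is.finite(mads))) {
    abort("`mads` must be at least 2 finite non-negative values.")
  }
  if (max(mads) == 0) {
    return(rep(0, length(mads)))
  }
  (mads / max(mads)) * sqrt(sum(diff(mads)^2)) / sum(mads)
}

#' Shrink log-LRs toward zero with per-column weights
#'
#' Multiplies column `i` of the log-LR matrix by `1 / (1 + lambda[i])`,
#' shrinking unstable estimates toward log-LR = 0 (likelihood ratio 1)
#' while leaving columns with `lambda = 0` untouched.
#'
#' @param m A `loglr_matrix`.
#' @param lambda Non-negative weights from [adaptive_lambda()].
#' @return A `loglr_matrix` with shrunken values.
#' @export
shrink_loglr <- function(m, lambda) {
  stopifnot(inherits(m, "loglr_matrix"))
  if (length(lambda) != ncol(m$values)) {
    abort("`lambda` must have one value per grid point.")
  }
  if (any(lambda < 0)) abort("`lambda` must be non-negative.")
  m$values <- m$values * rep(1 / (1 + lambda), each = nrow(m$values))
  m
}

#' Direction of the score-evidence relationship
#'
#' Sign of the Spearman rank correlation between the column-wise mean
#' log-LR and the common-grid coordinate: `+1` when higher scores carry
#' more pathogenic evidence, `-1` when lower scores do. An exactly zero
#' (or undefined) correlation is an error: the truthset carries no usable
#' direction and should be inspected.
#'
#' @param m A `loglr_matrix`.
#' @return `+1` or `-1`.
#' @export
direction_of_monotonicity <- function(m) {
  stopifnot(inherits(m, "loglr_matrix"))
  cm <- colMeans(m$values)
  rho <- suppressWarnings(stats::cor(cm, m$grid, method = "spearman"))
  if (is.na(rho) || rho == 0) {
    abort(paste(
      "Monotonicity direction is undefined (zero Spearman correlation",
      "between mean log-LRs and scores); inspect the truthset."
    ))
  }
  if (rho > 0) 1 else -1
}

#' Enforce monotone log-LRs by isotonic regression
#'
#' Replaces every resample row by its least-squares monotone fit in the
#' given direction (pool-adjacent-violators, uniform weights, via
#' [stats::isoreg()]). Rows that are already monotone are unchanged.
#'
#' @param m A `loglr_matrix`.
#' @param direction `+1` (non-decreasing) or `-1` (non-increasing).
#' @return A `loglr_matrix` with monotone rows.
#' @export
monotonize <- function(m, direction) {
  stopifnot(inherits(m, "loglr_matrix"))
  if (!direction %in% c(-1, 1)) abort("`direction` must be +1 or -1.")
  v <- m$values
  for (r in seq_len(nrow(v))) {
    if (direction == 1) {
      v[r, ] <- stats::isoreg(v[r, ])$yf
    } else {
      v[r, ] <- rev(stats::isoreg(rev(v[r, ]))$yf)
    }
  }
  m$values <- v
  m
}

#' Order-statistic ranks of the sign-test confidence interval
#'
#' Inverts the sign test for the population median: with `n` resamples the
#' two-sided level-`level` interval runs from the `lo`-th to the `hi`-th
#' order statistic, where `lo` is the largest rank `k` with
#' `P(Binomial(n, 1/2) <= k - 1) <= (1 - level) / 2` and `hi = n + 1 - lo`.
#' The exact binomial construction guarantees coverage of at least `level`.
#'
#' @param n Number of resamples (at least 6 for a 95% interval).
#' @param level Two-sided confidence level, default 0.95.
#' @return Integer vector `c(lo, hi)` of 1-based ranks.
#' @examples
#' sign_test_ci_ranks(10, 0.95) # c(2, 9)
#' @export
sign_test_ci_ranks <- function(n, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  alpha <- (1 - level) / 2
  k <- stats::qbinom(alpha, n, 0.5) # close to the answer; adjust exactly
  while (k >= 1 && stats::pbinom(k - 1, n, 0.5) > alpha) k <- k - 1
  while (stats::pbinom(k, n, 0.5) <= alpha) k <- k + 1
  lo <- k
  if (lo < 1) {
    abort(paste0("n = ", n, " is too small for a ", level,
                 " sign-test interval."))
  }
  c(lo = lo, hi = n + 1L - lo)
}

#' Summarise a monotone log-LR matrix into a calibration curve
#'
#' Per grid point: the median log-LR across resamples, with lower/upper
#' confidence bounds at the sign-test order-statistic ranks of the sorted
#' column. Because every row is monotone and order statistics preserve
#' elementwise order, all three curves are monotone in the stated
#' direction; this is asserted, not assumed.
#'
#' @param m A monotonized `loglr_matrix`.
#' @param direction `+1` or `-1`, from [direction_of_monotonicity()].
#' @param config A [calibration_config()] (uses `ci_level`).
#' @return A list of class `calibration_curve` with elements `grid`,
#'   `median_loglr`, `lower_loglr`, `upper_loglr`, `direction`.
#' @export
summarize_curve <- function(m, direction, config = calibration_config()) {
  stopifnot(inherits(m, "loglr_matrix"))
  n <- nrow(m$values)
  ranks <- sign_test_ci_ranks(n, config$ci_level)
  sorted <- unname(apply(m$values, 2, sort))
  med <- if (n %% 2 == 1) {
    sorted[(n + 1) / 2, ]
  } else {
    (sorted[n / 2, ] + sorted[n / 2 + 1, ]) / 2
  }
  lower <- sorted[ranks[["lo"]], ]
  upper <- sorted[ranks[["hi"]], ]
  for (curve in list(med, lower, upper)) {
    if (any(direction * diff(curve) < -1e-12)) {
      abort("Internal error: summarised curve is not monotone.")
    }
  }
  structure(
    list(grid = m$grid, median_loglr = med, lower_loglr = lower,
         upper_loglr = upper, direction = direction),
    class = "calibration_curve"
  )
}

#' @describeIn summarize_curve Tidy a calibration curve into a tibble with
#'   columns `grid`, `median_loglr`, `lower_loglr`, `upper_loglr`.
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    grid = x$grid, median_loglr = x$median_loglr,
    lower_loglr = x$lower_loglr, upper_loglr = x$upper_loglr
  )
}

#' Map a calibration curve back onto variant scores
#'
#' Each rescaled score is assigned the nearest common-grid index (exact
#' midpoints resolve toward the lower index) and receives the exponentiated
#' (lower, median, upper) log-LR at that index. `NA` scores yield `NA`
#' triples.
#'
#' @param curve A `calibration_curve`.
#' @param rescaled_scores Scores on \[0, 1\] (clamped and rescaled).
#' @return A tibble with columns `lr_lower`, `lr`, `lr_upper`.
#' @export
map_to_scores <- function(curve, rescaled_scores) {
  stopifnot(inherits(curve, "calibration_curve"))
  s <- rescaled_scores
  bad <- !is.na(s) & (s < 0 | s > 1)
  if (any(bad)) {
    abort("Rescaled scores must lie in [0, 1]; clamp upstream.")
  }
  g <- length(curve$grid)
  idx <- pmin(pmax(ceiling(s * (g - 1) - 0.5), 0), g - 1) + 1
  tibble::tibble(
    lr_lower = exp(curve$lower_loglr[idx]),
    lr = exp(curve$median_loglr[idx]),
    lr_upper = exp(curve$upper_loglr[idx])
  )
}
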