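#' Gaussian kernel density on an evaluation grid
#'
#' Evaluates the Gaussian-kernel density estimate of a sample at `n_grid`
#' equidistant points spanning `[min(x) - cut * bw, max(x) + cut * bw]`
#' (the convention of [stats::density()], which performs the computation).
#'
#' @param x Numeric sample (at least one finite value).
#' @param bw Positive kernel bandwidth.
#' @param n_grid Number of equidistant evaluation points, default 1024.
#' @param cut Grid extension beyond the data range in bandwidth units.
#' @return A list of class `density_on_grid` with elements `grid`
#'   (strictly increasing) and `density` (non-negative, same length).
#' @examples
#' d <- kde_on_grid(rnorm(50), bw = 0.3)
#' @export
kde_on_grid <- function(x, bw, n_grid = 1024L, cut = 3) {
  if (length(x) < 1 || any(!is.finite(x))) {
    abort("`x` must contain at least one finite value.")
  }
  if (!is.numeric(bw) || length(bw) != 1 || !is.finite(bw) || bw <= 0) {
    abort("`bw` must be a single positive number.")
  }
  if (n_grid < 2) abort("`n_grid` must be at least 2.")
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = n_grid, cut = cut)
  structure(list(grid = d$x, density = pmax(d$y, 0)),
            class = "density_on_grid")
}

#' Project a density estimate onto a common grid
#'
#' Linear interpolation of a `density_on_grid` at new positions; positions
#' outside the span of the source grid map to zero (no extrapolation).
#'
#' @param d A `density_on_grid`, e.g. from [kde_on_grid()].
#' @param grid Strictly increasing numeric vector of target positions.
#' @return Non-negative densities at `grid`.
#' @export
project_to_common_grid <- function(d, grid) {
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  y <- stats::approx(d$grid, d$density, xout = grid,
                     yleft = 0, yright = 0, ties = "ordered")$y
  pmax(y, 0)
}
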