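#' ACMG/AMP combining rules as posterior-probability criteria
#'
#' Enumerates the 14 pathogenic (P) and likely-pathogenic (LP) combining rules
#' of the ACMG/AMP framework at their minimal satisfying evidence combination.
#' Under the exponential evidence model, a combination of evidence maps to a
#' combined likelihood ratio `X^exponent`, where `X` is the very-strong
#' likelihood point and the exponent is the sum of the evidence weights
#' (supporting = 1/8, moderate = 1/4, strong = 1/2, very strong = 1).
#' Each rule demands a posterior probability of pathogenicity of at least
#' 0.99 (P rules) or 0.90 (LP rules).
#'
#' The likely-pathogenic criteria are lower bounds only: no upper posterior
#' bound is imposed on LP combinations, and the benign-side combining rules
#' are not evaluated (constraining P and LP preserves a near-identical
#' relationship between prior and threshold).
#'
#' @return A tibble with one row per rule and columns `name`, `category`
#'   (`"P"` or `"LP"`), `exponent` (a multiple of 1/8) and `posterior_floor`.
#' @examples
#' combining_rules()
#' @export
combining_rules <- function() {
  tibble::tibble(
    name = c(
      "P_i_a", "P_i_b", "P_i_c", "P_i_d",
      "P_ii",
      "P_iii_a", "P_iii_b", "P_iii_c",
      "LP_i", "LP_ii", "LP_iii", "LP_iv", "LP_v", "LP_vi"
    ),
    category = rep(c("P", "LP"), c(8L, 6L)),
    # minimal satisfying combinations, as summed evidence weights:
    #   P_i_a  VS + St            P_i_b  VS + 2 M
    #   P_i_c  VS + M + Su        P_i_d  VS + 2 Su
    #   P_ii   2 St
    #   P_iii_a St + 3 M          P_iii_b St + 2 M + 2 Su
    #   P_iii_c St + M + 4 Su
    #   LP_i   VS + M             LP_ii  St + M
    #   LP_iii St + 2 Su          LP_iv  3 M
    #   LP_v   2 M + 2 Su         LP_vi  M + 4 Su
    exponent = c(
      3 / 2, 3 / 2, 11 / 8, 5 / 4,
      1,
      5 / 4, 5 / 4, 5 / 4,
      5 / 4, 3 / 4, 3 / 4, 3 / 4, 3 / 4, 3 / 4
    ),
    posterior_floor = rep(c(0.99, 0.90), c(8L, 6L))
  )
}

#' Posterior probability of pathogenicity from a likelihood ratio
#'
#' Bayesian odds update: `posterior = lr * prior / (lr * prior + 1 - prior)`.
#'
#' @param lr Positive likelihood ratio(s) of pathogenicity.
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @return Posterior probabilities in (0, 1), same length as `lr`.
#' @examples
#' posterior_probability(350, prior = 0.1)
#' @export
posterior_probability <- function(lr, prior) {
  check_prior(prior)
  if (length(lr) == 0 || any(!is.finite(lr)) || any(lr <= 0)) {
    abort("`lr` must be finite and positive.")
  }
  lr * prior / (lr * prior + 1 - prior)
}

#' Count combining-rule posterior criteria satisfied by a candidate point
#'
#' For a candidate very-strong likelihood point `x`, counts how many of the
#' 14 combining rules reach their posterior floor, i.e. how many rules have
#' `posterior_probability(x^exponent, prior) >= posterior_floor`.
#' The count is non-decreasing in `x` for a fixed prior.
#'
#' @param x Candidate very-strong likelihood point, > 1. Vectorised.
#' @inheritParams posterior_probability
#' @param rules Rule table, defaults to [combining_rules()].
#' @return Integer count(s) in 0..14.
#' @examples
#' criteria_satisfied(351, prior = 0.1)
#' @export
criteria_satisfied <- function(x, prior, rules = combining_rules()) {
  check_prior(prior)
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 1)) {
    abort("`x` must be finite and > 1.")
  }
  vapply(x, function(xi) {
    post <- posterior_probability(xi^rules$exponent, prior)
    sum(post >= rules$posterior_floor)
  }, integer(1))
}

#' Very-strong likelihood point under a prior
#'
#' Finds the smallest likelihood ratio `X` whose exponentially scaled
#' evidence combinations satisfy at least 13 of the 14 P/LP combining-rule
#' posterior criteria under the given prior. The 13-of-14 tolerance absorbs
#' the internal inconsistency of the `P_ii` rule (two strong), whose
#' posterior stays below 0.99 at the solution. The continuous infimum is
#' located by bisection and reported at integer resolution.
#'
#' @inheritParams posterior_probability
#' @param rounding How the continuous solution is reported: `"floor"`
#'   (default) or `"nearest"`.
#' @param min_satisfied Number of criteria that must hold, default 13.
#' @param continuous If `TRUE`, return the continuous solution un-rounded.
#' @param tol Bisection tolerance on `x`, default 1e-7.
#' @return The very-strong likelihood point (numeric scalar).
#' @examples
#' very_strong_threshold(0.1)    # 350
#' very_strong_threshold(0.0441) # 1131
#' @export
very_strong_threshold <- function(prior, rounding = c("floor", "nearest"),
                                  min_satisfied = 13L, continuous = FALSE,
                                  tol = 1e-7) {
  check_prior(prior)
  rounding <- match.arg(rounding)
  rules <- combining_rules()
  ok <- function(x) criteria_satisfied(x, prior, rules) >= min_satisfied

  lo <- 1 + 1e-12
  hi <- 2
  while (!ok(hi)) {
    lo <- hi
    hi <- hi * 4
    if (hi > 1e18) abort("No satisfying likelihood point found.")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  xstar <- hi
  if (continuous) {
    return(xstar)
  }
  switch(rounding, floor = floor(xstar), nearest = round(xstar))
}

#' Likelihood points for the ACMG/AMP evidence ladder
#'
#' Expands a very-strong likelihood point `X` into the full exponential
#' evidence scale: strong = `X^(1/2)`, moderate = `X^(1/4)`, supporting =
#' `X^(1/8)`, with benign points the reciprocals of the pathogenic points.
#'
#' @param very_strong Very-strong likelihood point, > 1. Defaults to the
#'   combining-rule solution for `prior` via [very_strong_threshold()].
#' @inheritParams posterior_probability
#' @return An object of class `evidence_scale`: a list with elements
#'   `prior`, `very_strong`, `strong`, `moderate`, `supporting`,
#'   `benign_supporting`, `benign_moderate`, `benign_strong`,
#'   `benign_very_strong`.
#' @examples
#' evidence_scale(prior = 0.1)
#' @export
evidence_scale <- function(prior = 0.1,
                           very_strong = very_strong_threshold(prior)) {
  check_prior(prior)
  if (!is.numeric(very_strong) || length(very_strong) != 1 ||
      !is.finite(very_strong) || very_strong <= 1) {
    abort("`very_strong` must be a single finite value > 1.")
  }
  x <- very_strong
  structure(
    list(
      prior = prior,
      very_strong = x,
      strong = x^(1 / 2),
      moderate = x^(1 / 4),
      supporting = x^(1 / 8),
      benign_supporting = x^(-1 / 8),
      benign_moderate = x^(-1 / 4),
      benign_strong = x^(-1 / 2),
      benign_very_strong = 1 / x
    ),
    class = "evidence_scale"
  )
}

#' @rdname evidence_scale
#' @param x Very-strong likelihood point.
#' @export
likelihood_points <- function(x, prior = 0.1) {
  evidence_scale(prior = prior, very_strong = x)
}

#' @export
print.evidence_scale <- function(x, ...) {
  cat("<evidence_scale> prior =", format(x$prior), "\n")
  pts <- unlist(x[setdiff(names(x), "prior")])
  print(round(pts, 4))
  invisible(x)
}

#' @describeIn evidence_scale Tidy the scale into a tibble with one row per
#'   evidence level (`level`, `lr_point`).
#' @param ... Unused.
#' @export
tidy.evidence_scale <- function(x, ...) {
  lv <- c(
    "pathogenic_very_strong", "pathogenic_strong", "pathogenic_moderate",
    "pathogenic_supporting", "benign_supporting", "benign_moderate",
    "benign_strong", "benign_very_strong"
  )
  tibble::tibble(
    level = lv,
    lr_point = c(
      x$very_strong, x$strong, x$moderate, x$supporting,
      x$benign_supporting, x$benign_moderate, x$benign_strong,
      x$benign_very_strong
    )
  )
}

check_prior <- function(prior) {
  if (!is.numeric(prior) || length(prior) != 1 || !is.finite(prior) ||
      prior <= 0 || prior >= 1) {
    abort("`prior` must be a single probability strictly inside (0, 1).")
  }
  invisible(prior)
}

# factor levels of the evidence ladder, benign to pathogenic
evidence_levels <- function() {
  c(
    "benign_very_strong", "benign_strong", "benign_moderate",
    "benign_supporting", "indeterminate", "pathogenic_supporting",
    "pathogenic_moderate", "pathogenic_strong", "pathogenic_very_strong"
  )
}
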