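#' Distribution descriptors for synthetic truthsets
#'
#' Small constructors for the class-conditional score distributions used by
#' [generate_truthset()]: a Gaussian, a Gaussian mixture (for bimodal score
#' sets), and a skewed (shifted, optionally reflected gamma) family. Each
#' descriptor knows how to draw samples and evaluate its density, so the
#' analytic log density ratio between the pathogenic and benign classes is
#' available as an oracle for the KDE-based pipeline.
#'
#' @param mean,sd Gaussian parameters.
#' @return A list of class `score_dist`.
#' @export
dist_gaussian <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(family = "gaussian", mean = mean, sd = sd),
            class = "score_dist")
}

#' @rdname dist_gaussian
#' @param means,sds,weights Component parameters; `weights` must sum to 1.
#' @export
dist_gaussian_mixture <- function(means, sds, weights) {
  stopifnot(length(means) == length(sds), length(sds) == length(weights),
            all(sds > 0), all(weights > 0),
            abs(sum(weights) - 1) < 1e-8)
  structure(list(family = "gaussian-mixture", means = means, sds = sds,
                 weights = weights), class = "score_dist")
}

#' @rdname dist_gaussian
#' @param shape,rate Gamma parameters of the skewed family.
#' @param shift Location shift added to the gamma draw.
#' @param reflect If `TRUE`, the distribution is reflected (left-skewed).
#' @export
dist_skewed <- function(shape = 2, rate = 4, shift = 0, reflect = FALSE) {
  stopifnot(shape > 0, rate > 0, is.finite(shift))
  structure(list(family = "skewed", shape = shape, rate = rate,
                 shift = shift, reflect = isTRUE(reflect)),
            class = "score_dist")
}

dist_draw <- function(d, n) {
  switch(d$family,
    gaussian = rnorm(n, d$mean, d$sd),
    "gaussian-mixture" = {
      k <- sample.int(length(d$weights), n, replace = TRUE,
                      prob = d$weights)
      rnorm(n, d$means[k], d$sds[k])
    },
    skewed = {
      z <- rgamma(n, shape = d$shape, rate = d$rate)
      if (d$reflect) d$shift - z else d$shift + z
    }
  )
}

dist_density <- function(d, x) {
  switch(d$family,
    gaussian = dnorm(x, d$mean, d$sd),
    "gaussian-mixture" = {
      rowSums(vapply(seq_along(d$weights), function(k) {
        d$weights[k] * dnorm(x, d$means[k], d$sds[k])
      }, numeric(length(x))))
    },
    skewed = {
      z <- if (d$reflect) d$shift - x else x - d$shift
      dgamma(z, shape = d$shape, rate = d$rate)
    }
  )
}

#' Specify and generate a synthetic labelled truthset
#'
#' `truthset_spec()` bundles the class-conditional score distributions and
#' sample sizes; `generate_truthset()` draws the table. Unlabelled variants
#' are drawn from an even mixture of the two classes. The returned table
#' carries the analytic log density ratio (pathogenic over benign) as the
#' `"loglr_fn"` attribute, for use as an oracle against the KDE pipeline.
#'
#' @param benign,pathogenic `score_dist` descriptors, see [dist_gaussian()].
#' @param n_benign,n_pathogenic,n_unlabelled Row counts per class.
#' @param seed Integer seed making the draw deterministic.
#' @return `truthset_spec()`: a list of class `truthset_spec`.
#' @examples
#' spec <- truthset_spec(
#'   benign = dist_gaussian(0.3, 0.1),
#'   pathogenic = dist_gaussian(0.7, 0.1),
#'   n_benign = 20, n_pathogenic = 20, n_unlabelled = 5, seed = 1
#' )
#' head(generate_truthset(spec))
#' @export
truthset_spec <- function(benign, pathogenic, n_benign = 10L,
                          n_pathogenic = 10L, n_unlabelled = 0L,
                          seed = 1L) {
  stopifnot(inherits(benign, "score_dist"),
            inherits(pathogenic, "score_dist"),
            n_benign >= 0, n_pathogenic >= 0, n_unlabelled >= 0)
  structure(
    list(benign = benign, pathogenic = pathogenic,
         n_benign = as.integer(n_benign),
         n_pathogenic = as.integer(n_pathogenic),
         n_unlabelled = as.integer(n_unlabelled),
         seed = as.integer(seed)),
    class = "truthset_spec"
  )
}

#' @rdname truthset_spec
#' @param spec A `truthset_spec`.
#' @return `generate_truthset()`: a tibble with columns `score` and
#'   `class` (`'P'`, `'B'`, or `'VUS'` for unlabelled rows).
#' @export
generate_truthset <- function(spec) {
  stopifnot(inherits(spec, "truthset_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  b <- dist_draw(spec$benign, spec$n_benign)
  p <- dist_draw(spec$pathogenic, spec$n_pathogenic)
  u <- if (spec$n_unlabelled > 0) {
    from_p <- runif(spec$n_unlabelled) < 0.5
    ifelse(from_p, dist_draw(spec$pathogenic, spec$n_unlabelled),
           dist_draw(spec$benign, spec$n_unlabelled))
  } else {
    numeric(0)
  }
  out <- tibble::tibble(
    score = c(p, b, u),
    class = rep(c("P", "B", "VUS"),
                c(spec$n_pathogenic, spec$n_benign, spec$n_unlabelled))
  )
  attr(out, "loglr_fn") <- function(x) {
    log(dist_density(spec$pathogenic, x)) - log(dist_density(spec$benign, x))
  }
  out
}

#' Observed likelihood ratio of an evidence bin
#'
#' Cross-validation statistic: the held-out pathogenic-to-benign ratio
#' inside one evidence bin, divided by the held-out background
#' pathogenic-to-benign ratio. A bin with no benign variants has an
#' undefined (infinite) observed LR and is flagged rather than corrected.
#'
#' @param p_bin,b_bin Held-out pathogenic/benign counts in the bin.
#' @param background_p,background_b Held-out class totals (> 0).
#' @return Non-negative ratio; `Inf` when `b_bin` is 0 and `p_bin` > 0.
#' @examples
#' observed_lr(8, 2, 40, 60) # 6
#' @export
observed_lr <- function(p_bin, b_bin, background_p, background_b) {
  if (background_p <= 0 || background_b <= 0) {
    abort("Background counts must be positive.")
  }
  if (b_bin == 0) {
    return(if (p_bin == 0) NaN else Inf)
  }
  (p_bin / b_bin) / (background_p / background_b)
}

#' Monte-Carlo cross-validation of the minimum truthset size
#'
#' Repeatedly samples a small calibration truthset (default 10 pathogenic
#' and 10 benign variants, without replacement) from a labelled pool,
#' calibrates it, bins the held-out labelled variants by their assigned
#' evidence strength, and computes the observed LR of each bin against the
#' held-out background composition. Bins with zero held-out benign
#' variants are flagged `undefined`.
#'
#' @param pool Labelled data frame with columns `score` and `class`.
#' @param trials Number of Monte-Carlo trials.
#' @param per_class_train Truthset size per class, default 10.
#' @param prior Prior probability of pathogenicity.
#' @param config A [calibration_config()]; use reduced `n_resamples`
#'   for desk-scale runs.
#' @param seed Seed for the trial-level sampling stream.
#' @return A tibble with columns `trial`, `level`, `n_pathogenic`,
#'   `n_benign`, `observed_lr`, `undefined`.
#' @export
mc_cross_validation <- function(pool, trials = 50L, per_class_train = 10L,
                                prior = 0.1,
                                config = calibration_config(
                                  n_resamples = 100L
                                ),
                                seed = 1L) {
  stopifnot(is.data.frame(pool),
            all(c("score", "class") %in% names(pool)))
  ip <- which(pool$class == "P")
  ib <- which(pool$class == "B")
  if (length(ip) < 2 * per_class_train || length(ib) < 2 * per_class_train) {
    abort("Pool must hold at least twice `per_class_train` per class.")
  }
  scale <- evidence_scale(prior = prior,
                          very_strong = very_strong_threshold(prior))
  config$prior <- prior
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, trials)

  purrr::map_dfr(seq_len(trials), function(t) {
    set.seed(trial_seeds[t])
    train_p <- sample(ip, per_class_train)
    train_b <- sample(ib, per_class_train)
    train <- pool[c(train_p, train_b), c("score", "class")]
    heldout <- pool[setdiff(c(ip, ib), c(train_p, train_b)), ]
    fit <- tryCatch(
      {
        truthset <- validate_truthset(train, "score", "class")
        calibrate_one(truthset, config, scale)
      },
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        trial = t, level = NA_character_, n_pathogenic = NA_integer_,
        n_benign = NA_integer_, observed_lr = NA_real_, undefined = NA
      ))
    }
    rescaled <- clamp_rescale(heldout$score, min(train$score),
                              max(train$score))
    lrs <- map_to_scores(fit$curve, rescaled)
    ev <- assign_evidence(lrs$lr_lower, lrs$lr, lrs$lr_upper, scale)
    bg_p <- sum(heldout$class == "P")
    bg_b <- sum(heldout$class == "B")
    tab <- tibble::tibble(level = as.character(ev), class = heldout$class)
    dplyr::reframe(
      dplyr::group_by(tab, .data$level),
      trial = t,
      n_pathogenic = sum(.data$class == "P"),
      n_benign = sum(.data$class == "B"),
      observed_lr = observed_lr(.data$n_pathogenic[1], .data$n_benign[1],
                                bg_p, bg_b),
      undefined = .data$n_benign[1] == 0
    )
  })
}

#' Compare bandwidth selectors by confidence-interval width
#'
#' Runs the full calibration once per bandwidth selector and reports the
#' mean width of the LR confidence interval over the labelled truthset
#' variants (those that drive the density estimates). Narrower is more
#' stable. Selectors that fail on the data are reported with `NA`.
#'
#' @param df Labelled data frame.
#' @param score_col,class_col Column names, defaults `"score"`/`"class"`.
#' @param selectors Selectors to compare, see [bw_select()].
#' @param prior Prior probability of pathogenicity.
#' @param config Base [calibration_config()]; the selector field is
#'   overridden per run.
#' @return A tibble with columns `selector` and `mean_ci_width`.
#' @export
selector_ci_width <- function(df, score_col = "score",
                              class_col = "class",
                              selectors = c("nrd0", "bcv", "sj", "ucv"),
                              prior = 0.1,
                              config = calibration_config(
                                n_resamples = 100L
                              )) {
  truthset <- validate_truthset(df, score_col, class_col)
  scale <- evidence_scale(prior = prior,
                          very_strong = very_strong_threshold(prior))
  config$prior <- prior
  labelled <- truthset$labels %in% c("P", "B") &
    is.finite(truthset$scores)
  purrr::map_dfr(selectors, function(sel) {
    cfg <- config
    cfg$selector <- sel
    width <- tryCatch(
      {
        fit <- calibrate_one(truthset, cfg, scale)
        mean(fit$lrs$lr_upper[labelled] - fit$lrs$lr_lower[labelled])
      },
      error = function(e) NA_real_
    )
    tibble::tibble(selector = sel, mean_ci_width = width)
  })
}
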