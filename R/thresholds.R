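#' Assign ACMG/AMP evidence strengths from LR triples
#'
#' Classification uses the conservative bound: when the point estimate
#' exceeds 1, a variant earns the strongest pathogenic level whose
#' likelihood point is reached by the *lower* confidence bound; when it
#' falls below 1, the strongest benign level whose likelihood point is
#' reached by the *upper* bound. Equality counts as reaching the point.
#' A point estimate of exactly 1, or bounds that reach no level, yield
#' `indeterminate`.
#'
#' @param lr_lower,lr,lr_upper Positive likelihood-ratio triples
#'   (vectorised; `NA` yields `NA`).
#' @param scale An [evidence_scale()].
#' @return An ordered factor over the nine evidence levels, from
#'   `benign_very_strong` to `pathogenic_very_strong`.
#' @export
assign_evidence <- function(lr_lower, lr, lr_upper, scale) {
  stopifnot(inherits(scale, "evidence_scale"))
  ok <- !is.na(lr_lower) & !is.na(lr) & !is.na(lr_upper)
  if (any(c(lr_lower[ok], lr[ok], lr_upper[ok]) <= 0)) {
    abort("Likelihood ratios must be positive.")
  }
  if (any(lr_lower[ok] > lr[ok] | lr[ok] > lr_upper[ok])) {
    abort("Expected lr_lower <= lr <= lr_upper.")
  }
  path_points <- c(scale$supporting, scale$moderate, scale$strong,
                   scale$very_strong)
  path_names <- c("pathogenic_supporting", "pathogenic_moderate",
                  "pathogenic_strong", "pathogenic_very_strong")
  ben_points <- c(scale$benign_supporting, scale$benign_moderate,
                  scale$benign_strong, scale$benign_very_strong)
  ben_names <- c("benign_supporting", "benign_moderate", "benign_strong",
                 "benign_very_strong")
  out <- rep(NA_character_, length(lr))
  for (i in which(ok)) {
    out[i] <- if (lr[i] > 1) {
      hit <- which(lr_lower[i] >= path_points)
      if (length(hit)) path_names[max(hit)] else "indeterminate"
    } else if (lr[i] < 1) {
      hit <- which(lr_upper[i] <= ben_points)
      if (length(hit)) ben_names[max(hit)] else "indeterminate"
    } else {
      "indeterminate"
    }
  }
  factor(out, levels = evidence_levels(), ordered = TRUE)
}

#' Score thresholds for each evidence level
#'
#' Converts a calibration curve into per-level score intervals in original
#' score units. For each pathogenic level the crossing of the *lower*
#' confidence-bound curve with the level's likelihood point is located by
#' linear interpolation in log-LR space on the common grid coordinates; for
#' benign levels the *upper* bound curve is used. Where the bound curve
#' exactly equals the point over a plateau of grid nodes, the node on the
#' stronger-evidence side of the plateau is taken (the smallest region of
#' stronger evidence). Levels whose bound curve never reaches the point
#' are absent from the output. The resulting intervals tile the labelled
#' score range without overlap, ordered along the score axis according to
#' the curve's direction.
#'
#' @param curve A `calibration_curve` from [summarize_curve()].
#' @param scale An [evidence_scale()].
#' @param labelled_min,labelled_max Labelled score range in original units.
#' @return A tibble with columns `level`, `score_lower`, `score_upper`,
#'   one row per attained evidence level (including `indeterminate`).
#' @export
score_thresholds <- function(curve, scale, labelled_min, labelled_max) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(scale, "evidence_scale"))
  if (labelled_max <= labelled_min) {
    abort("`labelled_max` must exceed `labelled_min`.")
  }
  g <- curve$grid
  lower <- curve$lower_loglr
  upper <- curve$upper_loglr
  if (any(curve$direction * diff(curve$median_loglr) < -1e-12)) {
    abort("`curve` must be monotone.")
  }
  # orient so evidence for pathogenicity increases with the grid coordinate
  flipped <- curve$direction == -1
  if (flipped) {
    lower <- rev(lower)
    upper <- rev(upper)
  }

  path_levels <- c("pathogenic_supporting", "pathogenic_moderate",
                   "pathogenic_strong", "pathogenic_very_strong")
  ben_levels <- c("benign_supporting", "benign_moderate", "benign_strong",
                  "benign_very_strong")
  logp <- log(c(scale$supporting, scale$moderate, scale$strong,
                scale$very_strong))

  # crossing coordinates on the oriented grid; NA = level never attained
  cp <- vapply(logp, function(t) crossing_up(g, lower, t), numeric(1))
  cb <- vapply(logp, function(t) crossing_down(g, upper, -t), numeric(1))

  rows <- list()
  # benign ladder: strongest levels at the low-coordinate end
  prev <- 0
  for (k in 4:1) {
    if (!is.na(cb[k])) {
      rows[[ben_levels[k]]] <- c(prev, cb[k])
      prev <- cb[k]
    }
  }
  ind_lo <- prev
  ind_hi <- if (!is.na(cp[1])) cp[1] else 1
  if (ind_hi > ind_lo) {
    rows[["indeterminate"]] <- c(ind_lo, ind_hi)
  }
  # pathogenic ladder: strongest levels at the high-coordinate end
  for (k in 1:4) {
    if (!is.na(cp[k])) {
      hi <- if (k < 4 && !is.na(cp[k + 1])) cp[k + 1] else 1
      rows[[path_levels[k]]] <- c(cp[k], hi)
    }
  }

  to_score <- function(coord) {
    if (flipped) coord <- 1 - coord
    coord * (labelled_max - labelled_min) + labelled_min
  }
  out <- purrr::imap_dfr(rows, function(iv, level) {
    s <- sort(to_score(iv))
    tibble::tibble(level = level, score_lower = s[1], score_upper = s[2])
  })
  out$level <- factor(out$level, levels = evidence_levels(), ordered = TRUE)
  dplyr::arrange(out, dplyr::desc(.data$level))
}

# first coordinate where the increasing-evidence bound reaches `target`
# (scanning upward); exact plateaus resolve to their last (strongest) node
crossing_up <- function(g, y, target) {
  hit <- which(y >= target)
  if (!length(hit)) {
    return(NA_real_)
  }
  i <- hit[1]
  if (y[i] == target) {
    while (i < length(y) && y[i + 1] == target) i <- i + 1
    return(g[i])
  }
  if (i == 1) {
    return(g[1])
  }
  g[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (g[i] - g[i - 1])
}

# last coordinate where the bound is still at or below `target` (benign
# side); exact plateaus resolve to their first (strongest) node
crossing_down <- function(g, y, target) {
  hit <- which(y <= target)
  if (!length(hit)) {
    return(NA_real_)
  }
  i <- hit[length(hit)]
  if (y[i] == target) {
    while (i > 1 && y[i - 1] == target) i <- i - 1
    return(g[i])
  }
  if (i == length(y)) {
    return(g[length(g)])
  }
  g[i] + (target - y[i]) / (y[i + 1] - y[i]) * (g[i + 1] - g[i])
}
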