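#' Validate a variant table into a truthset
#'
#' Checks that the score column is numeric (character columns that parse
#' cleanly as numbers are accepted), that the class column contains at
#' least 10 `'P'` (pathogenic) and 10 `'B'` (benign) labels with finite
#' scores, and that the labelled scores span a non-zero range. Labels are
#' case-sensitive: anything other than `'P'`/`'B'` (including `'p'`/`'b'`,
#' which trigger a warning) is kept as an unlabelled variant, which still
#' receives likelihood ratios downstream.
#'
#' @param df A data frame with one row per variant.
#' @param score_col Name of the numeric score column.
#' @param class_col Name of the class-label column.
#' @return A list of class `truthset_scores` with the original rows and
#'   the labelled pathogenic/benign score subsets.
#' @export
validate_truthset <- function(df, score_col, class_col) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    abort("`df` must be a non-empty data frame.")
  }
  for (col in c(score_col, class_col)) {
    if (!col %in% names(df)) {
      abort(paste0("Column '", col, "' not found in the input table."))
    }
  }
  raw <- df[[score_col]]
  if (is.character(raw) || is.factor(raw)) {
    parsed <- suppressWarnings(as.numeric(as.character(raw)))
    bad <- which(!is.na(raw) & is.na(parsed) & as.character(raw) != "")
    if (length(bad)) {
      abort(paste0(
        "Non-numeric values in score column '", score_col, "' at row(s) ",
        paste(head(bad, 10), collapse = ", "),
        if (length(bad) > 10) ", ..." else "", "."
      ))
    }
    raw <- parsed
  }
  if (!is.numeric(raw)) {
    abort(paste0("Score column '", score_col, "' must be numeric."))
  }
  scores <- as.numeric(raw)

  labels <- as.character(df[[class_col]])
  if (any(labels %in% c("p", "b"), na.rm = TRUE)) {
    warn(paste(
      "Lower-case 'p'/'b' labels found; labels are case-sensitive and",
      "these rows are treated as unlabelled."
    ))
  }
  pathogenic <- scores[!is.na(labels) & labels == "P" & is.finite(scores)]
  benign <- scores[!is.na(labels) & labels == "B" & is.finite(scores)]
  if (length(pathogenic) < 10) {
    abort(paste0("Too few pathogenic labels: ", length(pathogenic), " < 10."))
  }
  if (length(benign) < 10) {
    abort(paste0("Too few benign labels: ", length(benign), " < 10."))
  }
  labelled <- c(pathogenic, benign)
  if (max(labelled) <= min(labelled)) {
    abort("Labelled scores span a zero range; cannot calibrate.")
  }
  structure(
    list(
      data = tibble::as_tibble(df), scores = scores, labels = labels,
      pathogenic = pathogenic, benign = benign,
      labelled_min = min(labelled), labelled_max = max(labelled),
      score_col = score_col, class_col = class_col
    ),
    class = "truthset_scores"
  )
}

# the full single-truthset pipeline: resample -> regularize -> monotonize
# -> summarise -> per-variant LRs + evidence + score thresholds
calibrate_one <- function(truthset, config, scale) {
  m <- compute_loglr_matrix(truthset, config)
  lambda <- adaptive_lambda(mad_profile(m))
  m <- shrink_loglr(m, lambda)
  direction <- direction_of_monotonicity(m)
  m <- monotonize(m, direction)
  curve <- summarize_curve(m, direction, config)
  rescaled <- clamp_rescale(truthset$scores, truthset$labelled_min,
                            truthset$labelled_max)
  lrs <- map_to_scores(curve, rescaled)
  lrs$evidence <- assign_evidence(lrs$lr_lower, lrs$lr, lrs$lr_upper, scale)
  thresholds <- score_thresholds(curve, scale, truthset$labelled_min,
                                 truthset$labelled_max)
  list(lrs = lrs, curve = curve, thresholds = thresholds,
       direction = direction)
}

#' Calibrate variant-effect scores into ACMG/AMP evidence
#'
#' The main entry point. For each score column, the labelled truthset is
#' validated, scores are clamped to the labelled range and rescaled to
#' \[0, 1\], class-conditional densities are bootstrapped into a log-LR
#' matrix, adaptively shrunken, monotonized by isotonic regression, and
#' summarised into a median curve with sign-test confidence bounds. Every
#' variant (labelled or not) receives an LR triple and an evidence-strength
#' assignment under the evidence scale implied by `prior`, and per-level
#' score thresholds are derived from the confidence-bound curves.
#'
#' @param df Data frame with one row per variant.
#' @param value Score column name(s); `NULL` (default) calibrates every
#'   numeric column except `group`.
#' @param group Optional grouping column (e.g. gene). When supplied, each
#'   group is calibrated independently and a named list is returned; groups
#'   that fail validation are reported as error records without stopping
#'   the others.
#' @param class_col Class-label column, default `"class"`; labels `'P'`
#'   and `'B'` mark the truthset.
#' @param prior Prior probability of pathogenicity, default 0.1.
#' @param config A [calibration_config()]; its `prior` is overridden by
#'   the `prior` argument.
#' @return For an ungrouped call, an object of class `acmg_calibration`:
#'   a list with `likelihood_ratios` (the input tibble plus
#'   `<value>_lr_lower`, `<value>_lr`, `<value>_lr_upper`,
#'   `<value>_evidence` per score column), `score_thresholds` (tibble with
#'   `value`, `level`, `score_lower`, `score_upper`), `scale`, `curves`,
#'   and `metadata`. For a grouped call, an `acmg_calibration_set`: a named
#'   list of per-group `acmg_calibration` objects (or error records of
#'   class `acmg_calibration_error`).
#' @examples
#' set.seed(7)
#' df <- data.frame(
#'   score = c(rnorm(15, 1), rnorm(15, -1), rnorm(5)),
#'   class = rep(c("P", "B", "VUS"), c(15, 15, 5))
#' )
#' fit <- calibrate(df, value = "score",
#'                  config = calibration_config(n_resamples = 50))
#' head(tidy(fit))
#' @export
calibrate <- function(df, value = NULL, group = NULL, class_col = "class",
                      prior = 0.1, config = calibration_config()) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    abort("`df` must be a non-empty data frame.")
  }
  check_prior(prior)
  stopifnot(inherits(config, "calibration_config"))
  config$prior <- prior
  if (!class_col %in% names(df)) {
    abort(paste0("Class column '", class_col, "' not found."))
  }
  if (!is.null(group)) {
    if (!group %in% names(df)) {
      abort(paste0("Group column '", group, "' not found."))
    }
    pieces <- split(tibble::as_tibble(df), df[[group]])
    out <- purrr::imap(pieces, function(piece, name) {
      tryCatch(
        calibrate(piece, value = value, group = NULL, class_col = class_col,
                  prior = prior, config = config),
        error = function(e) {
          structure(list(group = name, message = conditionMessage(e)),
                    class = "acmg_calibration_error")
        }
      )
    })
    return(structure(out, class = "acmg_calibration_set"))
  }

  if (is.null(value)) {
    value <- names(df)[vapply(df, is.numeric, logical(1))]
    value <- setdiff(value, c(group, class_col))
    if (!length(value)) abort("No numeric score columns found.")
  }

  x <- very_strong_threshold(prior, rounding = config$rounding)
  scale <- evidence_scale(prior = prior, very_strong = x)

  result <- tibble::as_tibble(df)
  thresholds <- list()
  curves <- list()
  counts <- list()
  directions <- list()
  for (v in value) {
    truthset <- validate_truthset(df, score_col = v, class_col = class_col)
    fit <- calibrate_one(truthset, config, scale)
    result[[paste0(v, "_lr_lower")]] <- fit$lrs$lr_lower
    result[[paste0(v, "_lr")]] <- fit$lrs$lr
    result[[paste0(v, "_lr_upper")]] <- fit$lrs$lr_upper
    result[[paste0(v, "_evidence")]] <- fit$lrs$evidence
    thresholds[[v]] <- dplyr::mutate(fit$thresholds, value = v,
                                     .before = 1)
    curves[[v]] <- fit$curve
    directions[[v]] <- fit$direction
    counts[[v]] <- c(pathogenic = length(truthset$pathogenic),
                     benign = length(truthset$benign))
  }
  structure(
    list(
      likelihood_ratios = result,
      score_thresholds = dplyr::bind_rows(thresholds),
      scale = scale,
      curves = curves,
      metadata = list(
        prior = prior, very_strong = x, seed = config$seed,
        n_resamples = config$n_resamples, grid_size = config$grid_size,
        selector = config$selector, ci_level = config$ci_level,
        value = value, class_col = class_col,
        directions = unlist(directions),
        counts = counts
      )
    ),
    class = "acmg_calibration"
  )
}

#' @export
print.acmg_calibration <- function(x, ...) {
  md <- x$metadata
  cat("<acmg_calibration>\n")
  cat("  score column(s):", paste(md$value, collapse = ", "), "\n")
  cat("  prior:", md$prior, " very-strong LR point:", md$very_strong, "\n")
  cat("  resamples:", md$n_resamples, " grid:", md$grid_size,
      " selector:", md$selector, "\n")
  cat("  variants:", nrow(x$likelihood_ratios), "\n")
  invisible(x)
}

#' @export
print.acmg_calibration_set <- function(x, ...) {
  cat("<acmg_calibration_set> with", length(x), "group(s)\n")
  for (nm in names(x)) {
    if (inherits(x[[nm]], "acmg_calibration_error")) {
      cat("  ", nm, ": ERROR - ", x[[nm]]$message, "\n", sep = "")
    } else {
      cat("  ", nm, ": ", nrow(x[[nm]]$likelihood_ratios), " variants\n",
          sep = "")
    }
  }
  invisible(x)
}

#' @export
print.acmg_calibration_error <- function(x, ...) {
  cat("<acmg_calibration_error> group", x$group, ":", x$message, "\n")
  invisible(x)
}

#' Tidy a calibration result
#'
#' `tidy()` returns the per-variant likelihood-ratio table (`type =
#' "variants"`, the default) or the per-level score thresholds (`type =
#' "thresholds"`). `glance()` returns a one-row summary of the run.
#'
#' @param x An `acmg_calibration`.
#' @param type `"variants"` or `"thresholds"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.acmg_calibration <- function(x, type = c("variants", "thresholds"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
    variants = x$likelihood_ratios,
    thresholds = x$score_thresholds
  )
}

#' @rdname tidy.acmg_calibration
#' @export
glance.acmg_calibration <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    n_variants = nrow(x$likelihood_ratios),
    n_pathogenic = sum(vapply(md$counts, `[[`, numeric(1), "pathogenic")),
    n_benign = sum(vapply(md$counts, `[[`, numeric(1), "benign")),
    prior = md$prior,
    very_strong = md$very_strong,
    n_resamples = md$n_resamples,
    grid_size = md$grid_size,
    selector = md$selector,
    seed = md$seed
  )
}
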