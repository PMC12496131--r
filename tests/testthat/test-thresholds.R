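test_that("evidence assignment uses the conservative bound", {
  sc <- evidence_scale(prior = 0.1, very_strong = 350)
  ev <- function(lo, mid, hi) {
    as.character(assign_evidence(lo, mid, hi, sc))
  }
  expect_equal(ev(360, 400, 500), "pathogenic_very_strong")
  expect_equal(ev(20, 400, 500), "pathogenic_strong")
  expect_equal(ev(1, 1, 1), "indeterminate")
  expect_equal(ev(0.2, 0.3, 0.45), "benign_supporting")
  # equality counts as reaching the point, on both sides
  expect_equal(ev(sc$strong, 400, 500), "pathogenic_strong")
  expect_equal(ev(0.1, 0.3, sc$benign_supporting), "benign_supporting")
  # bounds that reach no point leave the variant indeterminate
  expect_equal(ev(1.5, 10, 20), "indeterminate")
  expect_equal(ev(0.2, 0.6, 0.9), "indeterminate")
  expect_error(assign_evidence(-1, 1, 2, sc), "positive")
  expect_error(assign_evidence(3, 2, 4, sc), "lr_lower <= lr")
  expect_true(is.na(assign_evidence(NA, NA, NA, sc)))
})

test_that("score thresholds interpolate bound crossings on the grid", {
  sc <- evidence_scale(prior = 0.1, very_strong = 350)
  g <- seq(0, 1, length.out = 513)
  # lower bound linear from 0 to log(350): the strong point (350^(1/2))
  # crosses at exactly 0.5 by the exponent ladder, supporting at 1/8 ...
  lower <- g * log(350)
  upper <- lower + 0.1
  curve <- curve_fixture(median = lower + 0.05, lower = lower,
                         upper = upper)
  th <- score_thresholds(curve, sc, labelled_min = 0, labelled_max = 1)
  get <- function(lv) th[th$level == lv, ]
  expect_equal(get("pathogenic_strong")$score_lower, 0.5,
               tolerance = 1e-9)
  expect_equal(get("pathogenic_supporting")$score_lower, 1 / 8,
               tolerance = 1e-9)
  expect_equal(get("pathogenic_moderate")$score_lower, 1 / 4,
               tolerance = 1e-9)
  expect_equal(get("pathogenic_very_strong")$score_lower, 1,
               tolerance = 1e-6)
  # intervals tile the range without overlap
  th_sorted <- th[order(th$score_lower), ]
  expect_equal(th_sorted$score_lower[-1],
               th_sorted$score_upper[-nrow(th_sorted)])
})

test_that("unattained levels are absent from the threshold table", {
  sc <- evidence_scale(prior = 0.1, very_strong = 350)
  g <- seq(0, 1, length.out = 257)
  lower <- seq(-log(2), log(100), length.out = 257) # max LR 100 < 350
  curve <- curve_fixture(median = lower, lower = lower,
                         upper = lower + 0.01)
  th <- score_thresholds(curve, sc, 0, 1)
  expect_false("pathogenic_very_strong" %in% as.character(th$level))
  expect_true("pathogenic_strong" %in% as.character(th$level))
})

test_that("threshold intervals map back to original score units", {
  sc <- evidence_scale(prior = 0.1, very_strong = 350)
  lower <- seq(-log(400), log(400), length.out = 129)
  curve <- curve_fixture(median = lower, lower = lower,
                         upper = lower + 1e-6)
  th1 <- score_thresholds(curve, sc, 0, 1)
  th2 <- score_thresholds(curve, sc, -10, 30)
  expect_equal(th2$score_lower, th1$score_lower * 40 - 10)
  expect_equal(th2$score_upper, th1$score_upper * 40 - 10)
})

test_that("a direction -1 curve mirrors the threshold ordering", {
  sc <- evidence_scale(prior = 0.1, very_strong = 350)
  lower <- seq(log(400), -log(400), length.out = 129)
  curve <- curve_fixture(median = lower, lower = lower,
                         upper = lower + 1e-6, direction = -1)
  th <- score_thresholds(curve, sc, 0, 1)
  vs <- th[th$level == "pathogenic_very_strong", ]
  bs <- th[th$level == "benign_very_strong", ]
  expect_lt(vs$score_upper, 0.5) # pathogenic evidence at low scores
  expect_gt(bs$score_lower, 0.5)
  expect_equal(min(th$score_lower), 0)
  expect_equal(max(th$score_upper), 1)
})

test_that("assignments agree with the threshold intervals on a real fit", {
  ts <- separated_truthset(n = 25, n_unlabelled = 40, seed = 29)
  cfg <- quick_config()
  fit <- calibrate(ts, value = "score", config = cfg)
  th <- fit$score_thresholds
  lr <- fit$likelihood_ratios
  lr <- lr[!is.na(lr$score_evidence), ]
  # signed strength on the ladder: benign negative, indeterminate 0
  levels9 <- c("benign_very_strong", "benign_strong", "benign_moderate",
               "benign_supporting", "indeterminate",
               "pathogenic_supporting", "pathogenic_moderate",
               "pathogenic_strong", "pathogenic_very_strong")
  srank <- function(lv) match(lv, levels9) - 5L
  # thresholds come from interpolated crossings while variants snap to
  # the nearest grid node, so "strictly inside" is buffered by one grid
  # spacing in score units
  delta <- diff(range(c(th$score_lower, th$score_upper))) /
    (cfg$grid_size - 1)
  checked <- 0L
  for (i in seq_len(nrow(lr))) {
    s <- min(max(lr$score[i], min(th$score_lower)), max(th$score_upper))
    inside <- which(th$score_lower + delta < s & s < th$score_upper - delta)
    if (length(inside) != 1) next
    v <- srank(as.character(th$level[inside]))
    a <- srank(as.character(lr$score_evidence[i]))
    if (v > 0) expect_gte(a, v)
    if (v < 0) expect_lte(a, v)
    checked <- checked + 1L
  }
  expect_gt(checked, 10)
})
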