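# acmglr

Gene-level calibration of continuous variant-effect scores — from
multiplexed assays of variant effects (MAVEs) or computational variant
effect predictors (VEPs) — into ACMG/AMP evidence strengths.

## The problem

Clinical variant classification under the ACMG/AMP framework combines
graded evidence (supporting, moderate, strong, very strong) for or against
pathogenicity. Functional scores are a rich evidence source, but raw MAVE
and VEP scores differ in range, shape and direction between genes and
assays, so they cannot be compared to evidence thresholds directly. Given
a truthset of variants labelled pathogenic (`P`) or benign (`B`), `acmglr`
estimates, for every scored variant, the positive likelihood ratio of
pathogenicity

LR(s) = f_P(s) / f_B(s),

the ratio of the class-conditional score densities, together with a 95%
confidence interval, and maps it onto the ACMG/AMP evidence ladder.

## The method

1. **Clamp and rescale.** Scores are clamped to the labelled score range
   (no extrapolation beyond observed evidence) and mapped affinely to
   [0, 1], making the pipeline invariant to scale, offset and direction.
2. **Bootstrapped KDE.** Each class is resampled with replacement 1000
   times; each resample gets a Gaussian kernel density estimate with a
   biased cross-validation (BCV) bandwidth on 1024 evaluation points,
   projected onto a common 1024-point grid. Row-wise differences of class
   log-densities give a 1000 × 1024 matrix of log-LRs.
3. **Adaptive shrinkage.** Per grid point *i*, a weight
   λ_i = (MAD_i / max_j MAD_j) · sqrt(Σ_j (MAD_{j+1} − MAD_j)²) / Σ_j MAD_j
   (MAD = median absolute deviation of the log-LRs at that point) shrinks
   unstable, erratic regions toward LR = 1 by the factor 1/(1 + λ_i).
4. **Monotonization.** Isotonic regression (pool-adjacent-violators) on
   each resample row enforces that evidence never decreases as the score
   becomes more damaging; the direction is the sign of the Spearman
   correlation between mean log-LRs and the score.
5. **Median and sign-test CI.** The curve is the per-grid-point median
   log-LR with distribution-free 95% confidence bounds for the population
   median, from the exact binomial order statistics of the sign test.
6. **Evidence scale.** Under a prior probability of pathogenicity π
   (default 0.1), the very-strong likelihood point X is the smallest LR
   satisfying at least 13 of the 14 ACMG/AMP pathogenic and
   likely-pathogenic combining-rule posterior criteria (posterior ≥ 0.99
   for P rules, ≥ 0.90 for LP rules, with combined LR X^w for summed
   evidence weights w). Lower levels scale exponentially: strong =
   X^(1/2), moderate = X^(1/4), supporting = X^(1/8); benign points are
   the reciprocals. At π = 0.1 this gives X = 350; at π = 0.0441,
   X = 1131.
7. **Classification and thresholds.** A variant is classified by the
   conservative bound (lower CI bound when its LR point estimate exceeds
   1, upper bound below 1), and per-level score thresholds are obtained by
   linearly interpolating where the bound curves cross each likelihood
   point on the grid.

## Worked example

```r
library(acmglr)

# a synthetic truthset: benign scores ~ N(0.3, 0.1), pathogenic ~ N(0.7, 0.1),
# 25 labelled variants per class plus 10 unlabelled (VUS) variants
spec <- truthset_spec(
  benign = dist_gaussian(mean = 0.3, sd = 0.1),
  pathogenic = dist_gaussian(mean = 0.7, sd = 0.1),
  n_benign = 25, n_pathogenic = 25, n_unlabelled = 10, seed = 42
)
variants <- generate_truthset(spec)

fit <- calibrate(variants, value = "score", prior = 0.1)
head(tidy(fit), 4)
#> # A tibble: 4 × 6
#>   score class score_lr_lower score_lr score_lr_upper score_evidence
#>   <dbl> <chr>          <dbl>    <dbl>          <dbl> <ord>
#> 1 0.657 P              32.3   3.41e 1        3.68e 1 pathogenic_strong
#> 2 0.674 P              54.5   5.80e 1        6.29e 1 pathogenic_strong
#> 3 0.524 P               1.03  1.07e 0        1.11e 0 indeterminate
#> 4 0.746 P             903.    1.12e10        1.35e10 pathogenic_very_strong
```

Each variant keeps its input row and gains the LR triple
(`score_lr_lower`, `score_lr`, `score_lr_upper`) and the assigned evidence
strength under the prior. Variant 1, for instance, has a median LR of 34
whose lower bound (32.3) clears the strong likelihood point 18.7 but not
the very-strong point 350, so it earns strong pathogenic evidence. The
per-level score thresholds:

```r
tidy(fit, "thresholds")
#> # A tibble: 9 × 4
#>   value level                  score_lower score_upper
#>   <chr> <ord>                        <dbl>       <dbl>
#> 1 score pathogenic_very_strong      0.729        0.844
#> 2 score pathogenic_strong           0.637        0.729
#> 3 score pathogenic_moderate         0.584        0.637
#> 4 score pathogenic_supporting       0.555        0.584
#> 5 score indeterminate               0.480        0.555
#> 6 score benign_supporting           0.439        0.480
#> 7 score benign_moderate             0.382        0.439
#> 8 score benign_strong               0.309        0.382
#> 9 score benign_very_strong          0.0344       0.309
```

i.e. any variant scoring above 0.729 in this assay reaches very strong
pathogenic evidence, and anything below 0.309 reaches strong benign
evidence. `autoplot(fit)` draws the score-versus-LR curve with its
confidence ribbon and the evidence-level lines; `glance(fit)` returns a
one-row run summary. With a `group =` column (e.g. gene), `calibrate()`
returns one result per group, and groups failing validation (fewer than
10 `P` or 10 `B` labels) are reported as error records without stopping
the rest.

A command-line wrapper is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "acmg-calibrate.R", package = "acmglr"))')" \
  --input variants.csv --score-col score --out-dir results/
```

writing `likelihood_ratios.csv`, `score_thresholds.csv` and
`metadata.json`.

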