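---
title: "How acmglr calibrates variant-effect scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How acmglr calibrates variant-effect scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmglr)
```

`acmglr` converts continuous variant-effect scores into positive
likelihood ratios (LRs) of pathogenicity with confidence bounds, and from
there into ACMG/AMP evidence strengths and per-level score thresholds.
This vignette explains the model, every tunable parameter, the numerical
choices behind the implementation, and what the synthetic-data tests do
and do not demonstrate.

## The model

Let $f_P$ and $f_B$ be the class-conditional densities of the score among
pathogenic and benign variants. The evidence a score $s$ carries is the
positive likelihood ratio $\mathrm{LR}(s) = f_P(s)/f_B(s)$; posterior odds
of pathogenicity are prior odds times $\mathrm{LR}(s)$. Neither density is
known: both are estimated from a labelled truthset of at least 10
pathogenic (`P`) and 10 benign (`B`) variants by Gaussian kernel density
estimation. Ten per class is deliberately conservative — one-dimensional
KDE is usable with fewer — and is enforced, not merely recommended,
because the whole downstream evidence assignment inherits the stability
of these two density estimates.

### Rescaling

All scores are clamped to the labelled score range and mapped affinely to
$[0,1]$. Clamping means a variant scoring beyond the most extreme
labelled variant receives that extreme's LR rather than an extrapolated
one; rescaling makes every downstream constant (bandwidth search box,
grid, density floor) independent of the assay's units. Consequences
tested as invariants: any affine transform $s \mapsto a s + b$ ($a > 0$)
of the input leaves every variant's LR triple unchanged, and a reflection
$s \mapsto -s$ flips the direction label but again leaves the per-variant
LRs unchanged.

### Bootstrapped density estimation

The truthset is resampled with replacement (per class, preserving class
sizes) `n_resamples` = 1000 times. Per resample and class, a bandwidth is
selected by biased cross-validation (BCV) and the density evaluated on
1024 equidistant points spanning the resample's range extended by
`kde_cut` = 3 bandwidths — the convention of `stats::density()`, which
performs the evaluation — then projected onto a common 1024-point grid on
$[0,1]$ by linear interpolation, with no extrapolation (zero outside the
evaluation span). Projected densities are floored at
`density_floor` = 1e-10 before taking logs, so regions where one class
has no support produce large-but-finite log-LRs instead of infinities;
the floor's value is visible only where one class density effectively
vanishes, which is also where no estimator could be trusted anyway. Each
resample contributes one row of log-LR differences, giving a
1000 × 1024 matrix.

BCV is the default selector because it produces the most stable LR
confidence intervals; `selector_ci_width()` reruns a calibration under
`nrd0`, `bcv`, `sj` and `ucv` and reports the mean CI width over truthset
variants so users can check this on their own data. The BCV objective is
the exact pairwise Scott–Terrell estimate for a Gaussian kernel,
minimised over $[0.1\,h_{max}, h_{max}]$ with
$h_{max} = 1.144\,\hat\sigma\,n^{-1/5}$. Because the objective can be
multimodal, the implementation brackets the global minimum on a 100-point
coarse scan of the search box before refining with golden-section search;
a dense-grid (10^4-point) minimisation serves as the oracle in the test
suite. `nrd0`, `sj` and `ucv` delegate to the corresponding `stats`
selectors.

### Adaptive shrinkage

With $\mathrm{MAD}_i$ the median absolute deviation of the log-LRs at grid
index $i$ (the conventional 1.4826 consistency constant, to which the
result is provably and testedly invariant),

$$\lambda_i = \frac{\mathrm{MAD}_i}{\max_j \mathrm{MAD}_j} \cdot
  \frac{\sqrt{\sum_j (\mathrm{MAD}_{j+1}-\mathrm{MAD}_j)^2}}
       {\sum_j \mathrm{MAD}_j}$$

and column $i$ of the matrix is multiplied by $1/(1+\lambda_i)$. The
first factor concentrates the penalty on the locally unstable grid
regions; the second, a root-sum-of-squares of lagged differences, scales
the whole profile by how rough the spread is across the score range, and
vanishes for a flat profile. Multiplicative shrinkage in log space was
chosen as the application rule because it shrinks toward LR = 1, is the
identity at $\lambda = 0$, and is bounded and sign-preserving; it is
isolated in `shrink_loglr()` so an alternative rule is a one-function
change. $\lambda$ is computed from the raw matrix and applied *before*
monotonization, matching the pipeline's narrative order (stabilise, then
order-restrict).

### Monotonization and summary

A more damaging score should never carry less pathogenic evidence;
non-monotonicity in the raw estimates reflects boundary effects, sampling
noise, or truthset label errors. Each resample row is replaced by its
least-squares monotone fit (pool-adjacent-violators, uniform weights,
`stats::isoreg`). The direction is the sign of the Spearman correlation
between the column-wise mean log-LR and the grid coordinate; an exactly
zero correlation raises an error rather than guessing. Monotonizing per
row (rather than the summarised curve once) guarantees by construction
that the median and both confidence bounds are monotone, since order
statistics preserve elementwise order; the pipeline still asserts this.

The curve is the per-column median with 95% confidence bounds for the
*population median* obtained by inverting the sign test: with $n$
resamples the interval runs from the $k$-th to the $(n+1-k)$-th order
statistic, $k$ the largest rank with
$P(\mathrm{Bin}(n, 1/2) \le k-1) \le 0.025$. The exact binomial
construction guarantees at least nominal coverage and needs $n \ge 6$ at
the 95% level. A median-location interval (rather than a percentile
interval of the resample distribution) matches the classification goal:
what matters is where the central LR lies.

Each variant then receives the exponentiated (lower, median, upper)
log-LR at its nearest grid node; exact midpoints between nodes resolve to
the lower index, a tie-break that matters only on a measure-zero set of
scores.

### The evidence scale

Under the exponential evidence model, supporting, moderate, strong and
very strong evidence correspond to likelihood points $X^{1/8}, X^{1/4},
X^{1/2}, X$, with benign points their reciprocals. $X$ is determined from
the prior $\pi$ by requiring that the ACMG/AMP combining rules remain
internally consistent: each of the 8 pathogenic and 6 likely-pathogenic
rules, evaluated at its minimal satisfying evidence combination with
summed weights $w$ (supporting 1/8 … very strong 1), demands posterior
$\ge 0.99$ (P) or $\ge 0.90$ (LP) at combined LR $X^w$. $X$ is the
smallest value satisfying at least 13 of the 14 criteria — the tolerance
absorbs the two-strong rule (`P_ii`), which is inconsistently weak at any
plausible $X$. The LP criteria are lower bounds only: imposing an upper
posterior bound on LP combinations would make the 13-of-14 search
infeasible at $\pi = 0.1$. The benign-side combining rules are not
separately enforced; constraining P and LP preserves a near-identical
prior–threshold relationship.

The search brackets and bisects the continuous infimum to $10^{-7}$, then
reports it rounded down (`rounding = "floor"`, configurable to
`"nearest"`; both conventions reproduce the reference anchors of 350 at
$\pi = 0.1$ and 1131 at $\pi = 0.0441$, and the continuous solutions sit
at the binding exponent-3/4 LP constraint,
$X^\ast = (\mathrm{odds}(0.9)/\mathrm{odds}(\pi))^{4/3}$). The threshold
is strictly decreasing in the prior.

### Classification and score thresholds

A variant whose LR point estimate exceeds 1 is assigned the strongest
pathogenic level whose likelihood point its *lower* confidence bound
reaches (equality counts); below 1, the strongest benign level its
*upper* bound reaches. This makes classifications robust to truthset
updates: both the point estimate and the conservative bound must clear
the threshold. A point estimate of exactly 1 is indeterminate.

Score thresholds per level are computed on the grid: the crossing of the
relevant bound curve with each level's log likelihood point is located by
linear interpolation in log-LR space between the bracketing nodes, then
mapped back to original score units. Where a bound sits exactly on a
point across a plateau of nodes, the node on the stronger-evidence side
is taken — the smallest defensible region of stronger evidence. Levels
never reached are omitted from the table (missing rows, not sentinels).
The reported intervals tile the labelled range without overlap. Because
thresholds interpolate between nodes while variants snap to the nearest
node, the assignment and the intervals can disagree within half a grid
spacing of an interval edge; at the default 1024-point grid this is below
0.1% of the score range.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `prior` | 0.1 | prior probability of pathogenicity; the only scientific parameter. Use a smaller value (e.g. 0.0441) for genome-wide settings; overestimating the prior inflates evidence. |
| `n_resamples` | 1000 | bootstrap resamples; CI resolution scales with it |
| `grid_size` | 1024 | common grid points on [0, 1] |
| `selector` | `"bcv"` | bandwidth selector per class per resample |
| `ci_level` | 0.95 | two-sided level of the median CI |
| `seed` | 181 | root seed; one substream per resample, so results are bit-reproducible |
| `density_floor` | 1e-10 | density floor before logs |
| `kde_cut` | 3 | KDE span extension in bandwidths |
| `bw_per_resample` | `TRUE` | `FALSE` selects once per class (faster, near-identical) |

## What the synthetic generator emulates — and what it does not

`truthset_spec()`/`generate_truthset()` draw class-conditional scores
from Gaussian, Gaussian-mixture or skewed (shifted/reflected gamma)
families, with unlabelled variants from an even class mixture, and carry
the analytic log density ratio as an oracle. This covers the statistical
structure the pipeline must handle — overlap, multimodality, skew,
direction, small truthsets — and enables parameter-recovery tests: at 200
labelled variants per class and 200 resamples, the median curve tracks
the analytic Gaussian log-LR over the inter-mean score region (analytic
log-LR roughly $-4..4$) with maximum absolute error below 1.0 and mean
below 0.5 in the frozen-seed test. Outside that region, where one class
has essentially no sample support, floor-based KDE necessarily
underestimates $|\log \mathrm{LR}|$; tests do not compare against the
oracle there, and users should likewise read extreme-tail LRs as "at
least this extreme" statements bounded by the truthset, not as density
ratios.

Real truthsets differ from the generator in ways no synthetic test
covers: label noise and circularity (assay-informed ClinVar labels),
non-random truthset ascertainment, within-gene heterogeneity (domains,
mechanisms), and batch structure in assay scores. Passing the synthetic
suite shows the algorithm is implemented correctly, not that a given
gene's truthset is adequate.

`mc_cross_validation()` provides the study design for the minimum
truthset size: repeatedly calibrate on 10+10 sampled without replacement
from a labelled pool, classify the held-out variants, and compare each
evidence bin's observed pathogenic:benign enrichment (over the held-out
background) to 1. On a well-separated pool, pathogenic bins sit at or
above 1 and benign bins at or below — checked at 50 trials and 100
resamples in the test suite. Bins with zero held-out benign variants have
undefined observed LRs and are flagged, not continuity-corrected.

## Numerical choices and edge cases

- **Degenerate inputs.** Constant labelled scores, fewer than 10 labels
  per class, or non-numeric score entries are errors naming the problem
  and the rows. Labels are case-sensitive (`'P'`/`'B'`); lowercase
  variants warn and are treated as unlabelled.
- **Resample degeneracy.** A resample on which bandwidth selection fails
  is redrawn; more than 1% redraws aborts, since the truthset is then too
  close to degenerate to calibrate.
- **Determinism.** A fixed root seed spawns per-resample substream seeds,
  so runs are bit-identical regardless of how many rows an earlier step
  consumed; rerunning `calibrate()` twice yields byte-identical CSV
  output.
- **Problem sizes in the tests.** Unit tests run at 50 resamples on a
  256-point grid; the full 1000 × 1024 configuration is exercised once as
  a structural contract, and the stochastic acceptance blocks use 100–200
  resamples. These sizes keep the default suite fast while the full-scale
  path stays covered.

## Known limitations

- LR confidence bounds quantify resampling variability of the median
  log-LR, not uncertainty in the ACMG/AMP posterior; they also cannot see
  truthset label error.
- The exponential evidence scale and the 13-of-14 combining-rule search
  are a deliberate simplification of the full combining-rule algebra; the
  benign rules are maintained only implicitly.
- A single global prior per run; per-group (per-gene) priors are not
  supported within one call.
- KDE with a global (per-resample) bandwidth under-resolves regions whose
  local density scale differs greatly from the bulk; adaptive-bandwidth
  estimation is out of scope.
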