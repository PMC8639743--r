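---
title: "Methods: spatial clusters of life-expectancy inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial clusters of life-expectancy inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ypllg)
```

## The problem and the outcome variable

Premature mortality is usually summarised by *years of potential life lost*
(YPLL): the years not lived relative to a fixed cutoff, here
`max(0, 75 - age at death)`. YPLL ignores everyone who outlives the cutoff,
so it smooths away half of the inequality signal. This package is built
around the signed alternative, *years of potential life lost or gained*
(YPLLG):

$$\mathrm{YPLLG}_i = a_i - \mathrm{LEB}(b_i, g_i),$$

where $a_i$ is the individual's age at death (exact day count divided by
365.25), and $\mathrm{LEB}(b, g)$ is the *cohort* life expectancy at birth
for birth year $b$ and gender $g$. Cohort LEB follows a birth cohort's
actual and forecast mortality rather than a single calendar year's
cross-section, so it is the right benchmark for "did this person live longer
than their cohort was expected to". The package treats the life table as a
strict lookup: a missing (birth year, gender) key is an error, never an
interpolation, because the cohort tables this workflow expects are gap-free
over their span and a gap signals corrupted input.

Ages are kept fractional. Published YPLLG summaries are one-decimal reals
(e.g. a median of 9.3 years), which integer ages cannot produce; dividing
the exact day count by 365.25 also makes a leap-spanning four-year interval
exactly 4.0.

## Record filtering

`filter_records()` applies the exclusion cascade in a fixed order — death
year in range; duplicates and records missing birth date, death date, or
nationality; outside the region boundary; not georeferenced; missing
gender — and logs every step in a `filter_ledger` whose telescoping
identity (`remaining[k] = remaining[k-1] - removed[k]`) is machine-checked.
Two records are duplicates when gender, both dates, and the projected
location coincide. Containment in the region polygon is
boundary-inclusive. `replay_ledger()` rebuilds a ledger from printed step
counts so published accounting can be audited without the underlying
records.

## Local Moran analysis

The spatial unit is the individual residential point in a planar metric
frame (meters). Neighborhoods are distance bands: $N(i)$ holds every other
point within 1200 m (boundary inclusive; coincident addresses are valid
neighbors at distance zero). Binary weights are row-standardized to
$1/|N(i)|$, so the spatial lag is the unweighted mean over neighbors — the
convention of the GeoDa family of tools, under which "the mean of the
variable in the neighborhood" is literally what the lag computes. Points
with an empty band are flagged neighborless and excluded from the
statistic, and the mean and second moment are computed over analyzed points
only.

With $z_i = y_i - \bar y$ and $m_2 = \sum_i z_i^2 / n$:

$$I_i = \frac{z_i}{m_2} \sum_{j \in N(i)} w_{ij} z_j .$$

The mean of the $I_i$ equals the global Moran's I under row
standardization; the test suite asserts this identity to $10^{-12}$.

**Inference.** Each point gets a conditional-permutation test: $y_i$ is held
fixed while its $|N(i)|$ neighbor slots are refilled by sampling without
replacement from the other $n - 1$ observed values, $M$ times (99,999 by
default). The pseudo p-value is $(R + 1)/(M + 1)$, where $R$ counts
permuted statistics at least as extreme as the observed one *in the tail
matching the sign of the observed* $I_i$. The sign-matched tail is a
deliberate choice: concordant low-value clusters produce *positive* $I_i$
just as concordant high clusters do, so a pure upper-tail rule would be
correct for both, but a point with negative $I_i$ (a spatial outlier) must
be referred to the lower tail to be detectable. Quadrants of the
standardized Moran scatterplot then separate the significant points:
High-High ($z > 0$, lag $> 0$), Low-Low ($z < 0$, lag $< 0$), and the two
discordant outlier types, High-Low ($z > 0$, lag $< 0$) and Low-High
($z < 0$, lag $> 0$) — labels read point-first. One consequence of the
sign-matched tail is worth knowing: under a symmetric null the pseudo
p-values satisfy $P(p \le t) \approx \min(2t, 1)$ rather than $\le t$,
because the selection of the matching tail doubles the small-$t$ mass.
Each directional test is individually valid, and the package's null
calibration checks budget for exactly this behavior, but anyone comparing
pseudo p-values to a nominal uniform scale should halve their thresholds
mentally. Significance is strict
($p <$ threshold), a point with $z$ or lag exactly zero falls back to
not-significant (a measure-zero tie), and the threshold is the Bonferroni
bound $\alpha / n$ with $\alpha = 0.1$ over all points in the run, which for
10,000 observations gives an individual level of $10^{-5}$.

**Reproducibility.** Every point draws from its own counter-based
substream keyed by (master seed, point index), so p-values are independent
of evaluation order and bit-reproducible across runs. The permutation
kernel is compiled code; its Monte-Carlo mean is checked against the exact
conditional expectation
$E[I_i^{\mathrm{perm}}] = -z_i^2 / (m_2 (n - 1))$,
which follows from the mean of the remaining $n-1$ deviations being
$-z_i/(n-1)$.

## Adjusted YPLLG

To ask how much of the spatial structure is carried by who lives where,
YPLLG is regressed on a nationality indicator, neighborhood median
household income (in 1000 CHF), and neighborhood median population age,
with a median (least-absolute-deviations) regression — the natural choice
for a response this skewed. Gender and age never enter: they already define
the individual's LEB. The *adjusted* YPLLG is the raw residual, not
re-centred, and the cluster analysis is rerun on it unchanged.

Income enters untransformed; the franc scaling only conditions the solve
and leaves residuals untouched. The LAD optimum can be a degenerate face of
the linear program (the sign counts can be off-balance by up to the number
of coefficients at no cost); the fit is canonicalized by shifting the
intercept to the point of the optimal face with zero median residual,
verified by checking that the shift leaves the objective unchanged to
$10^{-9}$ relative. This keeps the downstream analysis variable centred
without ever leaving the set of LAD optima.

Neighborhood covariates come from the (subsector, death year) cell of a
panel; the neighborhood median age is the classical grouped-data median
over 5-year bins with an open class closed at 105 years. A missing cell
borrows the value of the nearest subsector (centroid distance) with data
for the *same year* — the fallback is spatial, not temporal, because a
neighborhood gap is best proxied by its surroundings, and an equidistant
tie breaks to the smallest subsector id for determinism.

## Robustness by subset replication

Applying a Bonferroni bound of $\alpha/n$ with a permutation floor of
$1/(M+1)$ requires $M + 1 > n/\alpha$ permutations; at full-register scale
this is expensive, and point-pattern results could in principle be an
artifact of one specific configuration of addresses. The pipeline therefore
replicates the whole analysis (raw and adjusted) on $k$ independent simple
random subsets without replacement (defaults $k = 10$, $m = 10{,}000$), and
summarises, per cluster type, the count, % women, % nationals, mean of the
analysis variable, mean YPLL, mean income, and mean neighborhood age as
range / mean / sd across subsets. The median regression is refitted within
each subset so every replicate is self-contained. Tukey's HSD
(Tukey–Kramer for unequal group sizes, family level 0.05) compares all
pairs of cluster-type means. The *footprint reduction* of the concordant
cluster types is $100 (n_{\mathrm{raw}} - n_{\mathrm{adj}}) /
n_{\mathrm{raw}}$ on mean counts across subsets; it is reported as missing
when the raw count is zero.

## The synthetic-data generator

Everything above is testable without confidential mortality data because
the generator plants known structure:

* **Lifespan-deviation noise.** A negated shifted log-normal
  $D = m_0 - \mathrm{LogNormal}(\mu, \sigma)$ solved at run time to hit a
  target (mean, sd, median); the default calibration (5.19, 20.12, 9.3
  years) reproduces the negatively skewed YPLLG shape of an urban death
  register, with its long left tail of very premature deaths. The solve
  takes the left branch of the U-shaped moment equation (the mildest tail
  consistent with the moments). `median == mean` requests a Gaussian and
  `sd = 0` a constant, which the degenerate-input tests use.
* **Geometry.** Coordinates are uniform over an abstract projected
  rectangle (no real CRS); subsectors are Voronoi cells of seeded random
  centroids. Planted clusters are non-overlapping discs whose members get a
  $\pm$ shift in expected lifespan (default 15 years, the order of the
  cluster-vs-background contrast seen in real registers).
* **Covariates.** Neighborhood income has a west-to-east gradient plus
  between-subsector noise; age counts are multinomial draws around a
  subsector mean age. Individual lifespans can load on nationality, income,
  and neighborhood age; every covariate contribution is centred so the
  configured noise mean stays the population mean.
* **Consistency.** Age at death is assembled as LEB + effects + noise, the
  birth year is iterated to a fixed point against the life table, ages
  below 0 are resampled and ages capped at 105. Birth dates live on a day
  grid, so recomputing the age from the written dates agrees with the
  generator truth to $1/365.25$ years in general and to one cohort step
  (0.12 years) in the rare case of a birth date pinned at a year boundary.

What the generator does *not* emulate: real street-network address
clustering, temporal drift in covariates, cause-of-death structure, or the
actual Swiss life tables. Passing the planted-recovery tests therefore
shows the statistical machinery is correct and calibrated, not that any
particular city has the planted geography.

## Validation conditions and problem sizes

The packaged checks run at sizes chosen to finish on a laptop while keeping
each property identifiable:

* *Null calibration*: 200 replicates of 200 spatially random points
  (M = 999, Bonferroni $\alpha$ = 0.1); the family-wise false-cluster rate
  must stay within two binomial standard errors of 0.1. At this size the
  permutation floor exceeds the threshold, so the run also guards against
  any label slipping through below the attainable resolution; a second,
  non-vacuous calibration at n = 50 (threshold $2 \times 10^{-3}$ above the
  floor) exercises the rejection path.
* *Planted recovery*: 20 replicates of 1,340 points with one high and one
  low cluster of radius 2700 m (2.25 times the lag radius, so interior
  neighborhoods are pure), planted shift 8 years with Gaussian noise of
  sd 6 — the variance decomposition (45% of points in clusters) makes the
  shift exactly one population sd. Expected: at least 70% of in-cluster
  points labeled concordantly, at most 2% of far-field points (beyond
  cluster radius + lag radius) labeled HH/LL, with M = 19,999.
* *Covariate-driven shrinkage*: 20 replicates of 600 points with no planted
  clusters and a 0.25 year / 1000 CHF income effect over a 100,000 CHF
  gradient; the adjusted run must show fewer HH+LL members than the raw run
  in at least 90% of replicates.
* *Subset study*: the demonstration study runs k = 5 subsets of m = 1,000
  records from a 4,000-record stylized register (a dense 8 × 8 km region
  with one long-lived and one short-lived cluster of twice the lag radius,
  default skewed noise and covariate structure, and the register corrupted
  at realistic attrition rates before the exclusion cascade), with
  M = 19,999 permutations — the smallest M whose floor sits below the
  Bonferroni threshold $10^{-4}$ at that subset size.

## Known limitations

* The filter cascade detects duplicates by exact field equality; fuzzy
  record linkage is out of scope.
* The nearest-neighborhood covariate fallback never searches other years;
  if an entire year has no data for a variable the attachment fails loudly.
* The footprint-reduction metric is defined on mean cluster counts across
  subsets. Published reductions computed on a different basis (for
  instance, the mapped area of a single display subset) will not agree with
  the count-based figure; both the per-subset counts and the summary means
  are exposed so either basis can be computed.
* Permutation p-values are floored at $1/(M+1)$; with Bonferroni control
  the number of permutations must be chosen against the intended test
  count, and the package errs on the conservative side when it cannot
  reject.
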