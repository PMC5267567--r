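---
title: "Methods: testing Rensch's rule with mass and length data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing Rensch's rule with mass and length data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdallometry)
```

## The question and the data model

Rensch's rule is the macroevolutionary claim that sexual size dimorphism
(SSD) increases with body size among related species when males are the
larger sex, and decreases with size when females are larger. Plotting log
female size on the *x*-axis and log male size on the *y*-axis collapses
both statements into one: a slope above 1 is Rensch's rule, below 1 its
converse, and a slope indistinguishable from 1 is isometry. This axis
convention is fixed package-wide; every slope's meaning depends on it.

The data unit is a *population record*: one population of one species with
sex-paired mean sizes in up to two metrics — body mass in grams and
straight carapace length (SCL) in centimetres, the standard linear
measurement in turtles. Records carry provenance flags (`basis`: mean,
range midpoint via `midpoint_from_range()`, or maximum; `captive`) but the
package applies no filtering based on them: exclusions such as juveniles or
gravid females belong to data compilation, not analysis, and pre-filtered
inputs are assumed. The only structural rule is pair-completeness: a record
with no complete male/female pair in either metric carries no signal and is
dropped at read time, with a reported count.

Species represented by several populations contribute exactly one,
selected uniformly at random among the populations with a complete pair
for the metric in play (`select_one_population_per_species()`). The
selection seed is stored on the result, and one integer seed drives every
random step of a run — selection, polytomy resolution, permutations — so
reports are bit-reproducible.

All analyses operate on log sizes. The base is 10: slope, r², CI and the
slope = 1 test are invariant to the common base, so the choice only fixes
the intercept units, and base 10 matches conventional allometry plots.

## The dimorphism index

SSD is summarised by the Lovich–Gibbons index, (larger sex / smaller sex)
− 1, signed positive when females are larger. It is symmetric around zero
and reads as a proportional difference. The index is computed on **raw**
sizes: on that scale a value of 0.68 means "the larger sex is 68% bigger",
and family summary tables built from raw-scale ratios are self-consistent
with the printed family mean sizes. A log-scale variant is exposed
(`scale = "log"`) but shrinks the index drastically (a 68% mass difference
becomes ≈ 0.06) and is not used by the summaries. Family summaries report
the *mean of the per-species ratios*, never the ratio of the mean sizes,
so a family's largest species does not dominate its dimorphism summary.
Direction censuses call a species negligibly dimorphic below a 2%
proportional difference, applied strictly (`< 0.02`); exactly 2% counts as
dimorphic.

## SMA regression and the verdict rule

Because male and female sizes are measured with comparable error, the line
is fitted by standardized major axis (SMA) regression rather than OLS:
`b = sign(r) · s_y/s_x`. The 1−α confidence interval is
`b(√(B+1) ± √B)` with `B = F(1−α; 1, n−2)(1−r²)/(n−2)`, and the test of
slope = 1 uses the correlation between the residual axis `y − x` and the
fitted axis `y + x`, referred to `F(1, n−2)`. These two are the same
inference: the p-value drops below α exactly when 1 leaves the CI, a
property the test suite asserts by numerically inverting the test at the
CI bounds. One caveat is documented and deliberate: the statistic depends
on the data only through the axis standard deviations, so it addresses the
slope's *magnitude*. With a negative fitted slope — impossible for
male–female size data of any real clade, but reachable in small noisy
simulations — the test against +1 is not meaningful and only the CI should
be read. Verdicts (`classify_allometry()`) come solely from the CI
position relative to 1.

Clade stratification analyses the whole dataset, each suborder, and each
family with at least `min_clade_size` species (default 7). The
seven-species floor is a family-level rule; suborders are top-level strata
and are reported whenever they meet the SMA minimum of n = 3. Species in
families too small for their own row still count in the whole-order and
suborder fits.

## Phylogenetic correction

Trait resemblance among relatives inflates the effective sample size of a
naive regression. The package first quantifies that resemblance with
Blomberg's K, computed from the tip–tip shared-path-length matrix V:
`K = (MSE0/MSE) / [(tr V − n/(1ᵀV⁻¹1))/(n−1)]`, the observed ratio of
ordinary to phylogenetically-corrected mean squares divided by its
Brownian-motion expectation on the same tree. The matrix form needs no
ultrametricity, and K is invariant to shifting or positively rescaling the
trait. Significance comes from permuting tip values (statistic: variance
of the standardized contrasts, lower meaning more signal), with the
add-one convention `p = (1 + #{perm ≤ obs})/(n_perm + 1)` so p is never 0.
The permutation count defaults to 999 — a declared default, chosen as the
smallest round count that resolves p = 0.001.

Independent contrasts follow the Felsenstein pruning algorithm
(`pic_contrasts()`), implemented directly and cross-checked against the
`ape` reference in the test suite. Polytomies are first broken into
uniformly random dichotomies with zero-length inserted edges — tip-to-root
path lengths, and hence Brownian tip variances, are unchanged — under the
run seed. Zero-length edges are harmless to contrasts as long as no
contrast is standardized by a total branch length of zero; that
pathological case raises an error naming the node rather than propagating
NaN. Male and female contrasts for a clade are always computed on the
*same* resolved tree (one resolution per clade per seed): contrasts from
two different resolutions would not be comparable pairs. Contrast signs
are arbitrary, so the contrast-scale SMA is fitted through the origin
(`sign(Σxy)·√(Σy²/Σx²)`, df = n−1, uncentered r²); all downstream
statistics are invariant to jointly flipping any contrast pair, which the
suite asserts.

## Mass–length comparison

Whether the sexes partition growth differently between mass and length is
asked on the full population-level table (all populations retained, since
the question is about variance explained, not macroevolution): OLS of log
SCL on log mass per sex and pooled, a Chow test of one common regression
(`F = [(RSS_p − RSS_a − RSS_b)/2]/[(RSS_a + RSS_b)/(n_a + n_b − 4)]`), and
a two-group t-test on the slopes alone. The Chow implementation is
verified against the nested-model `anova` F in the suite; the pooled RSS
can never undercut the sum of the separate ones, and that nesting is
asserted rather than the (false) claim that pooled r² bounds the separate
r²s.

## What the generator emulates — and what it does not

`simulate_study()` builds: a pure-birth (Yule) tree conditioned on the tip
count; female log10 size by Brownian motion (rate `sigma_f`, default 0.25
log10 units per unit √branch length — sizes spanning roughly 2–3 orders of
magnitude on a unit-depth tree, as turtle masses do) from a root of
log10(1000 g), mid-scale for turtles and affecting intercepts only; male
log10 size as `alpha_intercept + beta · female + e` with `e` an
independent Brownian deviation (rate `sigma_e`); one to k populations per
species with mean-zero normal jitter on the log scale (`population_cv`,
lognormal on the raw scale so sizes stay positive); and SCL attached by
`log SCL = 0.3 + (1/3)·log mass + noise`, cubic scaling putting 1 kg at
about 20 cm. Families are monophyletic groups cut from the tree, the two
root clades standing in for the suborders.

The male-size model was chosen over a correlated bivariate Brownian
process because its contrast-scale expectation has closed form: the
through-origin SMA slope converges to `√(β² + σ_e²/σ_f²)`, equal to β when
`σ_e = 0`. That gives exact recovery targets. Note the degenerate edge:
with `σ_e = 0` the male contrasts are an *exact* multiple of the female
contrasts, so recovery is exact in every replicate and the CI has width
zero — coverage calibration is only defined with `σ_e > 0`, which is how
the suite tests it (target slope 1.15 via `σ_e = σ_f/2`,
`β = √(1.15² − 0.25)`; 200 replicates at n = 100 check the mean within
±0.02 and 95% CI coverage within [0.92, 0.98]).

What the generator does **not** emulate: real turtle taxonomy or the
empirical size distribution beyond order of magnitude; non-Brownian
evolution (no Pagel's λ or OU transformations — also out of scope for the
analyses); measurement error distinct from population-level jitter;
missing-data patterns (every synthetic record is complete). Passing tests
therefore demonstrate statistical correctness and calibration of the
machinery under its own assumptions, not that real turtle data satisfy
those assumptions.

## Numerical choices and degenerate inputs

Zero variance on an axis, all-zero contrasts, fewer than 3 points (2 for
through-origin), singular phylogenetic covariance, and zero-length
standardization all raise explicit named errors rather than silent NaN.
r² is clamped at 1 to stop floating-point overshoot on exact lines from
producing a negative CI half-width. p-values are kept at full double
precision internally; printed output rounds to 3 significant figures.
Name matching between dataset and tree is exact after underscore/space
normalization and case folding — fuzzy matching is deliberately excluded.

Test problem sizes were chosen to make Monte-Carlo noise small relative to
the asserted tolerances while keeping the default suite around twenty
seconds: 1000 randomized inputs for the SMA closed form, 500 Brownian
replicates on a 64-tip tree for K's calibration, 200 replicates of n = 100
for slope recovery and coverage, 1000 replicates for the Chow test's
type-I error.

## Known limitations

* The one-population-per-species step treats populations as exchangeable;
  no weighting by sample size or data quality is attempted.
* Only the Chow test and slope t-test compare groups; no common-slope SMA
  tests across multiple clades are provided.
* K's permutation test and the contrast machinery require a resolved
  (binary) tree; the seeded random resolution makes family-level results
  depend (weakly) on the seed, which is reported in every output for that
  reason.
* The slope = 1 test's magnitude caveat above.
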