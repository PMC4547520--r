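---
title: "Nonparametric scaling of the NART: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric scaling of the NART: methods and design notes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mininart)
```

## The measurement problem

The National Adult Reading Test (NART) asks a respondent to pronounce 50
irregular English words and is widely used to estimate premorbid
(pre-decline) cognitive ability: irregular spelling defeats guessing, and
word reading is relatively robust to ageing and early dementia. Each item
is scored 0/1. Two measurement questions drive this package:

1. **Do the items form one unidimensional, monotone scale**, so that the
   summed score orders respondents on the underlying ability (the
   monotone homogeneity model, MHM)?
2. **Is the difficulty ordering of the items the same at every ability
   level** (invariant item ordering, IIO), so that single items — "the
   hardest word this person could read" — carry meaning, and the test can
   be administered adaptively?

Mokken scaling answers both nonparametrically, without committing to a
parametric item response function (IRF). The package implements the full
workflow — scalability coefficients, automated item selection, manifest
monotonicity, IIO with backward item elimination, the HT ordering
coefficient, Molenaar–Sijtsma reliability — together with the published
NART item statistics, regression models mapping scale scores to estimated
IQ, an adaptive administration engine, and a synthetic-response generator
used to validate every stage.

## Scalability coefficients

For an item pair ordered by sample difficulty (the item with the higher
proportion correct is *easier*; ties break by column order), a **Guttman
error** is the pattern "harder item passed, easier item failed". With
observed error count $F_{ij}$ and the count expected under marginal
independence $E_{ij} = N\,P(X_e = 0)P(X_h = 1)$,

$$H_{ij} = 1 - F_{ij}/E_{ij}, \qquad
  H_i = 1 - \frac{\sum_{j \ne i} F_{ij}}{\sum_{j \ne i} E_{ij}}, \qquad
  H = 1 - \frac{\sum\sum F_{ij}}{\sum\sum E_{ij}},$$

ratios of sums, not means of ratios. $H_{ij}$ equals the covariance ratio
$\mathrm{cov}(X_i, X_j)/\mathrm{cov}_{\max}$, an identity the test suite
verifies on a thousand random matrices. $H = 1$ exactly when the data are
a perfect Guttman scalogram; $H_i$ acts as item discrimination, $H$ as
scale strength, read against the standard bands (< 0.3 unscalable, 0.3–0.4
weak, 0.4–0.5 medium, ≥ 0.5 strong).

Zero-variance items make $E_{ij}$ vanish; they are excluded from every sum
and reported, never silently dropped. Standard errors, when requested, come
from a seeded person-resampling bootstrap (default 1000 resamples). The
bootstrap was chosen over the delta-method expressions because it covers
every statistic in the package uniformly with one auditable mechanism; the
published standard errors for the original sample are not reproducible
anyway, since the raw item responses are not deposited.

## Automated item selection (AISP)

Scales are built bottom-up: seed with the admissible pair maximizing
$H_{ij}$, then repeatedly admit the candidate that keeps every within-scale
$H_{ij}$ positive and every member's $H_i \ge c$ (default $c = 0.3$) and
maximizes the resulting scale $H$; close the scale when no candidate
qualifies and restart on the remainder; leftovers are unscalable.
Significance of $H_{ij} > 0$ uses the one-sided asymptotic normal test
$z = r\sqrt{N-1}$ on the phi coefficient, Bonferroni-corrected across the
tests of each selection step. Ties on the resulting $H$ go to the lower
column index, making the procedure fully deterministic. Membership checks
are enforced on the *whole* scale after each admission, so the partition
invariants (every $H_i \ge c$, every $H_{ij} > 0$ within a scale) hold for
the final result, not merely at admission time.

## Manifest monotonicity

For each item, persons are grouped by rest score (total over the other
items), merging adjacent values until each group reaches `minsize` —
$n/10$ for $n \ge 500$, $n/5$ for $250 \le n < 500$, otherwise
$\max(n/3, 50)$. The MHM requires the conditional proportion correct to be
non-decreasing over groups; every ordered group *pair* is compared (the
manifest-monotonicity definition, not adjacent groups only), a decrease
greater than `minvi` (default 0.03) is a violation, and each flagged
decrease carries a one-sided pooled two-proportion z statistic screened at
$\alpha = 0.05$. The 0.03 floor exists to keep trivially small dips from
rejecting the model.

## Invariant item ordering

The manifest IIO check conditions each item pair on the rest score over
the *other* $J - 2$ items and requires the overall-easier item to stay at
least as popular in every group; a reversal greater than `minvi` is a
violation, screened with the same z test. Backward elimination then
iterates: remove the item carrying the largest significant reversal,
recompute on the reduced set, stop when nothing significant remains.

Because a reversal belongs to both members of its pair, the two items of
the worst pair always *tie* on the largest violation, and the tie-break
decides everything. Breaking ties by total violation count was tried first
and proved systematically wrong: a well-discriminating item that many
crossing items share as their victim accumulates the most flags and gets
removed in their place, after which the crossing items lose their evidence
and survive. The package therefore breaks ties by the number of *distinct
harder items that significantly outperform* the item in some rest-score
group: an IRF that descends through the difficulty ordering is beaten by
many items below it, which is the signature of the true violator, whether
it crosses steeply from above (one sharp crosser among parallel items) or
sags flatly through a band of steeper ones. Remaining ties go to the lower
column index. Both planted-geometry recovery suites exercise this rule.

**HT** quantifies ordering accuracy as the H of the transposed matrix:
persons become "items", items become "respondents". Persons with all-0 or
all-1 vectors carry no ordering information (zero variance after
transposition) and are excluded — the conventional treatment, stated here
because published analyses rarely say so. HT is read against the same
strength bands as H.

## Molenaar–Sijtsma reliability

Total-score reliability needs the probability of passing the same item on
two independent replications, $\pi_{ii}$ — unobservable from one sitting.
With items ordered by decreasing popularity and $P$ the joint
pass-proportion matrix, the package estimates the diagonal by the
two-neighbour ratio $\hat\pi_{ii} = P_{i,i-1}P_{i,i+1}/P_{i-1,i+1}$; the
most popular item uses the single-neighbour success ratio
$P_{12}\,p_1/p_2$ and the least popular item the mirrored ratio on joint
*failures*, mapped back through $P(0,0) = 1 - 2p + P(1,1)$. Then

$$\mathrm{MS} = 1 - \frac{\sum_i (p_i - \hat\pi_{ii})}{\mathrm{Var}(X_+)}.$$

This scheme has three exactness properties the tests pin down: a perfect
scalogram and perfectly coherent all-0/all-1 data both give MS = 1, and
independent items give $\hat\pi_{ii} \approx p_i^2$, hence MS near 0.
Values outside [0, 1] are flagged as degenerate, never clamped. MS > 0.7
is the conventional reliability threshold.

## Estimating premorbid IQ

`mini_nart_predictor()` and `nart_predictor()` package the published
regressions of age-11 IQ on the 23-item mini-NART and the full 50-item
NART (n = 587). Their confidence intervals follow the published
convention — the slope's 95% CI applied around a fixed intercept — so the
interval collapses to the intercept at score 0 and widens linearly with
the score. `fit_predictor()` additionally keeps its underlying `lm` fit so
`predict_iq(..., interval = "prediction")` can produce a conventional 95%
prediction interval; that mode is deliberately labelled as distinct from
the published convention. Presentation rounding is two decimals for points
and intervals and nearest integer for the conversion-table IQ column,
which is what makes the scale ceilings print as 119 (mini-NART, score 23)
and 121 (full NART, score 50).

## Adaptive administration

An invariantly ordered scale can be administered from either end:
ascending (easiest word first) stopping after `stop_after` consecutive
failures with all harder items imputed failed, or descending (hardest
first) stopping after `stop_after` consecutive successes with all easier
items imputed passed — the Guttman completion that IIO licenses. The
default `stop_after = 2` is the package's own minimal confirmation rule:
the source analysis proposes adaptive use but no stopping rule, so the
parameter is exposed and the default documented as an extension. For any
respondent whose responses follow the hierarchy, the imputed total equals
the full-administration total in either direction; for probabilistic
respondents the imputation error shrinks as `stop_after` grows, which the
suite checks on Rasch-simulated sessions.

## The synthetic generator

No raw item responses are deposited for the original cohort, so the
package ships a generator instead of data. Responses follow a 2PL-form
model: trait $\theta \sim N(0,1)$, $P(X_i = 1\mid\theta) =
\mathrm{logis}(a_i(\theta - b_i))$, with $a_i = \infty$ as a deterministic
step; a two-trait variant draws correlated traits and assigns each item a
block; the criterion is $\text{intercept} + \text{slope}\cdot\theta_1 +
N(0, \sigma)$. The logistic family is the simplest one spanning everything
the checks need: any $a_i \ge 0$ satisfies the MHM, an equal-$a$ subfamily
satisfies IIO exactly (non-crossing IRFs), and unequal $a$ plants
violations on demand. All model-implied marginals use 61-node
Gauss–Hermite quadrature, giving deterministic oracles for stochastic
tests; difficulties are calibrated by root-finding against target
marginals.

Presets encode the ground truths the test suite recovers: `preset_rasch`
(equal $a$: no monotonicity or IIO violations), `preset_crossing` (one
steep item, $a = 5.5$ against 1.5, whose removal must come first),
`preset_two_trait` (two 3-item blocks, $\rho = 0$: the blocks are the
correct partition), `preset_independent` (coin flips: everything
unscalable).

`nart_like_preset()` emulates the published scale anatomy on all 50
items: difficulties calibrated so every model-implied marginal matches the
published percent-correct profile to within 0.5 points; the 23-item core
at a common $a = 3$ (IIO holds by construction); the 15 items reported to
break IIO at a near-flat $a = 0.15$, so their IRFs sag through the steep
core ones; the 3-item cluster (DRACHM, TOPIARY, PRELATE) on a second trait
at $\rho = 0.3$; and 9 RADIX-like unscalable items at $a = 0.1$. The
criterion emulates an age-11 IQ (mean 101.5, trait slope 12, residual SD
9, giving a trait–criterion correlation near 0.8). Two honest caveats.
First, the flat-violator construction was forced: with marginals pinned to
the published table, most violators sit in the 75–93% band where ceiling
compression caps any steep-versus-moderate reversal below the significance
screen at n = 600, so only near-flat IRFs produce detectably crossing
items; the "high-discrimination violator" narrative is not realizable
under these margins at this sample size. Second, exact recovery of the
23-item core by backward elimination holds at the preset's default seed
and in roughly half of generator draws; in the others the per-comparison
z screen (about 2300 comparisons among the 253 clean pairs) produces one
or two spurious significant reversals and the selection overshoots by that
many core items. A multiplicity-corrected screen would remove the
overshoot but also push the ceiling-limited violator signals (z around
2–2.4) below detectability; the per-comparison screen is the conventional
default and is kept.

## What the synthetic checks do and do not show

Passing the planted-structure suites shows the *procedures* behave as the
theory predicts on data whose truth is known: clean models come out clean,
planted crossings are found and removed, planted dimensionality is
recovered, regression parameters are re-estimated within their intervals.
It does not validate the NART itself, reproduce the original sample's
statistics (H = 0.534, HT = 0.71, MS = 0.89 and the 38/3/9 partition are
carried as reference values in the packaged tables, not recomputed), nor
capture features of real pronunciation data — rater disagreement, regional
accent effects, specialist-vocabulary dependencies — that the logistic
family cannot express.

## Numerical conventions, in one place

- Difficulty ties (equal proportions): the lower column index counts as
  easier, everywhere — errors, ordering, popularity sorts.
- Degenerate (all-0/all-1) items: excluded from H sums, MS, and pair
  scans, always with a warning; degenerate pairs report `NA`.
- Missing data: listwise deletion with a logged count at ingestion
  (complete-case, matching the design of the source analysis); a strict
  `error` policy is available.
- Problem sizes in the test suite — 5000 persons for clean-model checks,
  3000 for the crossing preset, 2000 for dimensionality, 600 for the
  NART-like preset, 200–500 for regression recovery — were chosen as the
  smallest sizes at which the planted effects are comfortably inside
  their detection margins.
- Every stochastic test fixes its seed; the generator is bit-reproducible
  given spec and seed.
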