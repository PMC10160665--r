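---
title: "Rating survey items from pairwise comparisons: the methods behind elorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating survey items from pairwise comparisons: the methods behind elorank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elorank)
library(ggplot2)
```

## The measurement problem

Rating instruments with absolute scales (Likert items) suffer from ceiling
effects and satisficing when respondents are asked to rate many items that
are all "important": most items cluster at the top of the scale and lose
discriminability. Comparative judgement sidesteps this by asking
forced-choice questions — *which of these two items is more important?* —
and aggregating many such binary outcomes into a relative scale. The cost
is combinatorial: `n` items generate `n(n-1)/2` unique pairs, far more than
any one respondent can answer. The design `elorank` supports therefore
assigns each respondent a small random subset of the full pair bank
(`all_pairs()`, `assign_questions()`) and pools everyone's answers, which
presumes a reasonable degree of shared perspective within the respondent
group: the pooled outcomes are treated as repeated noisy measurements of
one group-level preference ordering.

## The Elo engine

Every item starts at the same arbitrary rating (0). Pooled comparisons are
processed one at a time; for a comparison between items with standing
ratings $r_a$ and $r_b$, the expected score of the first is

$$E_a = \frac{1}{1 + 10^{(r_b - r_a)/s}},$$

and after the observed outcome the winner gains $k\,(1 - E_{\text{winner}})$
while the loser loses the same amount. The update is zero-sum, so the sum
of all ratings is conserved exactly — a property the test suite checks to
1e-9 over random streams.

Three constants govern the engine, all exposed in `elo_config()`:

| parameter | default | meaning |
|---|---|---|
| `start_rating` | 0 | common starting rating (arbitrary origin) |
| `k_factor` | 100 | maximum rating change from one comparison |
| `scale` | 400 | logistic spread: a 400-point gap gives the higher item an expected score of 10/11 |
| `n_sequences` | 500 | randomized processing orders averaged into mElo |

The logistic/base-10/400 form with `k = 100` and a zero start is the
configuration of the comparative-judgement literature this engine follows;
since reasonable variants exist, all three constants are configurable
rather than hard-coded.

**Order dependence and mElo.** A single sequential pass depends on the
order in which comparisons are processed (an early upset moves ratings more
than a late one). `mean_elo()` therefore reruns the pass over `n_sequences`
uniformly shuffled orders of the *same* records — outcomes are never
resampled — and averages the final ratings. 500 sequences follow the study
design this package operationalizes; the resampling loops in
`bootstrap_ci()`, `permutation_test()` and `rank_stability_curve()` default
to 20 sequences per replicate because sequence-averaging noise there is
second-order relative to resampling noise (a sensitivity check in the test
suite confirms interval widths respond to data volume, not sequence
count).

**Normalization and ranks.** `minmax_normalize()` maps mElo affinely onto
[0, 1] (n.mElo): 1 is the most and 0 the least important item, and rating
distances stay proportional to mElo differences, which makes scales
comparable across respondent groups. A table in which every mElo is equal
carries no usable signal, and the package treats it as a hard error rather
than silently emitting 0.5s. Ranks break exact ties lexicographically by
item id and flag them (`tie`), so output is reproducible.

## Consistency indices and sample-size estimation

`consistency_index()` processes the stream while maintaining running Elo
ratings. A record whose items have unequal standing ratings is *evaluated*;
it is an *upset* when the lower-rated item wins. The unweighted index is
one minus the upset fraction; the weighted index weights each evaluated
record by the absolute standing rating gap, so large upsets hurt more
(an expected-probability-margin weighting is available by argument).
Records meeting at equal ratings — including every item's first appearance
at the common start — enter neither numerator nor denominator, because no
expected winner exists. One subtlety worth knowing: "perfectly consistent"
data in the transitive sense can still register early upsets, because a
loser's rating sinks below items it has not yet met; the index equals 1
only on streams where each winner already stands at or above its opponent.
Under uniform-random outcomes both indices concentrate near 0.5.

For sample-size estimation, `plateau_curve()` recomputes the weighted
index on the pooled records of the first `r` respondents, for `r = 1..R`,
over 10 randomized inclusion orders (the study's procedure), and reports
the median per rater count. Because the index is order-dependent, the
curve's final point equals the all-data index *under that trial's
inclusion order*. `detect_plateau()` returns the smallest `r` whose whole
suffix stays strictly within a tolerance band (default 0.01) of the final
median; the suffix rule is this package's operationalization of "inspect
the plot for the plateau", and a curve that never settles before its last
point is flagged rather than silently accepted. Strict inequality at the
band edge makes boundary values unambiguous.

## Reliability metrics and their nulls

The triplet reliability test (`build_triplet_test()`) draws `3t` distinct
items, partitions them into `t` triplets (A, B, C) and asks four questions
per triplet — (A,B), (B,C), (A,C) and the reversed (B,A) — in randomized
order. From responses it computes:

- **symmetry consistency** — share of (A,B)/(B,A) pairs answered with the
  same item;
- **triplet transitivity** — share of triplets whose three outcomes admit
  a strict total order (6 of the 8 outcome patterns do, so uniform
  responding gives 0.75 per triplet);
- **test–retest stability** — share of identical answers across two
  sittings;
- **consensus rates / WMCR** — per multi-rater question, the share
  choosing the modal item, averaged with answer-count weights.

Respondent-mean and pooled-count versions of the proportions can differ
when respondents answer different numbers of questions; both are reported.

`simulate_random_null()` draws uniform binary responses (the skip option is
excluded from nulls: the published simulated medians 7/13 and 10/13 are
only consistent with two-option uniform choice) and summarizes 5,000
simulated respondents (symmetry, transitivity: median and range) or 5,000
repetitions (test–retest, WMCR: mean and range). Two computational
shortcuts are exact, not approximations: a fresh uniform answer matches any
fixed baseline answer with probability one half, so test–retest match
counts are single binomial draws; and per-question modal counts in the WMCR
null are binomial draws. The WMCR null mean has the closed form
$0.5 + \mathbb{E}\left|\mathrm{Bin}(n, \tfrac12)/n - \tfrac12\right|$
(about 0.506 at $n = 5000$), which the tests use as an independent
cross-check. The symmetry null's sample median is multi-modal by
construction — the median of 13-trial binomial proportions lands on 6/13,
0.5 or 7/13 depending on the seed — so it is checked for set membership,
not as a point value.

`compare_to_null()` runs the one-sided test of "the random-response metric
is less than the observed metric": Wilcoxon one-sample for the ordinal
per-respondent proportions, one-sample t for the approximately normal
repetition means (the default per metric, overridable). With thousands of
null samples these tests saturate quickly — an observed value above every
sample gives p far below 0.01 — which is the intended use; the p-value at
the exact null center is not meaningful at that sample size because the
Wilcoxon reacts to any slight sample asymmetry.

## Content validity

`content_validity()` computes each item's CVI as the share of expert raters
judging it quite/very relevant, flagging items with CVI strictly greater
than 0.78 (with at least three raters). Strictness matters at exactly 6
raters: 5/6 ≈ 0.833 passes and 4/6 ≈ 0.667 fails, which is the convention
the threshold is designed for. Reported CVIs are full precision; rounded
published values like 0.66 are treated as 4/6.

## Group inference

- **Bootstrap** (`bootstrap_ci()`): resamples comparison records with
  replacement (respondent-level resampling by flag), recomputes n.mElo per
  replicate, percentile intervals. The comparison is the default unit
  because the design pools comparisons; respondent resampling is offered
  for clustered designs.
- **Difference CIs** (`difference_ci()`): groups are resampled
  independently, but each group's replicate stream restarts from the same
  seed — a paired design under which a group compared with itself yields
  exactly zero differences, a useful degeneracy check.
- **Permutation test** (`permutation_test()`): group labels are permuted
  at the *respondent* level, because comparisons within a respondent share
  rater effects and are not exchangeable individually. Two-sided p-values
  use the add-one correction and are BH-adjusted across items (the
  multiple-testing rule is this package's choice; none is prescribed by
  the method it follows). Calibration under a true null is verified by
  simulation in the test suite.
- **Split-half** (`split_half()`): respondents are split into random
  halves, n.mElo computed per half, and agreement summarized by Pearson
  correlation on ratings and Kendall's Tau on ranks.
- **Rank stability** (`rank_stability_curve()`): respondents are added one
  at a time and the mean absolute rank change per step recorded; under a
  shared group perspective the curve decays toward zero.

## The synthetic cohort

`generate_cohort()` emulates exactly the structure the method assumes:
latent item-importance scores $\theta_i$ (standard normal by default)
shared by the group, with item $i$ chosen over $j$ with probability
$\mathrm{logit}^{-1}(\beta(\theta_i - \theta_j))$ — the Bradley–Terry form,
the canonical latent-score model for pairwise choice and the logistic
counterpart of the Thurstonian framing comparative judgement rests on. A
SKIP ("I do not understand") event occurs independently with probability
$\varepsilon$. Defaults mirror the study conditions this package
operationalizes: 91 items in 7 themes, 901 respondents, 50 comparisons
each, $\varepsilon = 0.0034$. The discrimination $\beta$ has no empirical
anchor in those conditions; the default of 2 produces the
"reasonable degree of shared perspective" regime (pairwise accuracy around
0.9 for typical score gaps) and is the value the recovery benchmarks use.
$\beta = 0$ gives uniform random choice — the no-signal regime under which
the pipeline correctly reports consistency near 0.5 and split-half
correlations near 0.

What the generator does *not* emulate: respondent-specific deviations from
the shared $\theta$ beyond the choice noise, pair-dependent skipping,
position bias, fatigue or memory between sittings. Passing tests on
synthetic data therefore demonstrate that the algorithms recover the
structure they assume, not that any particular real cohort satisfies those
assumptions; the reliability metrics and nulls exist precisely to check
the latter on real data. For the reliability test,
`simulate_reliability_cohort()` gives each rater internally transitive
latent preferences (from rater-specific latent item values) plus a
per-answer consistency probability, so `p_consistent = 1` is perfect on
every intra-rater metric and `p_consistent = 0.5` reproduces the
uniform-random nulls.

## Numerical choices and problem sizes

- Equal standing ratings are detected with a 1e-9 absolute tolerance; the
  rest of the engine is plain double arithmetic with no accumulation
  tricks (the zero-sum property keeps magnitudes bounded).
- Sequence shuffling runs inside the compiled loop but draws from R's RNG,
  so every result is bit-reproducible from `set.seed()`/`seed` arguments;
  all randomized functions take an explicit seed.
- The test suite and the acceptance script run at desk scale by design:
  null distributions at the published 5,000-replicate scale (they are
  vectorized binomial work and take under a second), parameter-recovery
  benchmarks at 40 respondents × 50 comparisons on 91 items over 10 seeds,
  and permutation-calibration at 500 simulated null datasets with 99
  permutations each. These sizes were chosen to make the stochastic
  assertions' tolerances comfortable (binomial error a few times smaller
  than the asserted bands).

## Known limitations

- Ratings are group-level: the design (50 comparisons per respondent over
  4,095 pairs) carries far too little per-respondent information for
  individual scales.
- The engine has no draw outcome and no adaptive pairing; pairs are
  sampled uniformly, matching the survey design it implements.
- `detect_plateau()` is a descriptive rule, not a statistical test of
  stabilization.
- The bootstrap treats comparisons as exchangeable within a group; with
  strong rater effects the respondent-level bootstrap is the safer flag.

## A compact end-to-end example

```{r example, eval = FALSE}
cohort <- generate_cohort(synthetic_config(
  n_items = 30, n_respondents = 60, m_per_respondent = 40, seed = 1
))
ratings <- elo_rate(cohort$records, cohort$items,
                    elo_config(n_sequences = 200), seed = 1)
head(tidy(ratings))
theme_medians(ratings, cohort$items)
recovery(cohort$theta, ratings)
autoplot(ratings, top = 15)

curve <- plateau_curve(filter_skips(cohort$records), cohort$items, seed = 1)
detect_plateau(curve)
autoplot(curve)
```
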