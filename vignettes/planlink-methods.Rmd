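---
title: "Linking provider directories and correlating plan quality with provider attributes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking provider directories and correlating plan quality with provider attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planlink)
```

## The analysis

`planlink` studies the relationship between health-insurance plan quality
indicators (NCQA-style 0–100 scores: overall, consumer satisfaction,
prevention, condition-specific treatment) and aggregated attributes of the
providers in each plan's network. The unit of analysis is the **plan**: for
each plan we average its member providers' attributes — patient review
rating, referral count, Castle Connolly award flag, affiliated-hospital
score and rank, relative cost — and correlate those aggregates with the
plan's scores, pooled, state by state, and within condition-specialty
subgroups.

None of the underlying sources (provider directories, review-site profiles,
hospital rankings, charge files, plan tables) share a key, so the pipeline's
first half is entity resolution; its second half is the statistical battery.
The stages are: *simulate → link → derive → aggregate → correlate → report*,
orchestrated by `run_pipeline()`.

## Record linkage

Review-site profiles are matched to directory records by a hybrid
deterministic procedure:

* **Blocking.** Candidate pairs must share a state and the first letter of
  the last name (`blocking = "last_initial_state"`). A union block on either
  first- or last-name initial (`"either_initial_state"`) is available for
  data whose name initials are unreliable, and `"none"` disables blocking
  for small inputs.
* **Per-attribute scores.** Name-like fields score
  `1 − levenshtein(a, b) / max(|a|, |b|)` after canonicalization
  (case-fold, strip punctuation, collapse whitespace); graduation year
  scores 0/1; hospital-affiliation and specialty sets score their Jaccard
  overlap. A field absent on either side is *missing evidence*: it is
  excluded and the weights are renormalized, rather than scored 0 —
  absence is not disagreement.
* **Weights and threshold.** The default weights
  (0.2, 0.05, 0.3, 0.15, 0.1, 0.05, 0.075, 0.075) over first name, middle
  name, last name, address, medical school, graduation year, hospitals,
  specialties put most mass on names. No published constants exist for
  either weights or threshold — the *procedure* is the contribution — so
  both are configuration, and `calibrate_threshold()` re-derives the
  threshold by maximizing F1 against ground-truth pairs (greedy acceptance
  is prefix-stable in descending score order, so a single greedy pass
  yields the entire precision–recall sweep).
* **Assignment.** Pairs at or above the threshold are accepted greedily in
  descending combined score, skipping pairs whose site profile is already
  matched: each site profile maps to at most one directory record. Ties are
  broken by the smaller identifier pair, which makes the output invariant
  to input row order.

Insurance-name strings are mapped to plan names with the same normalized
edit-distance similarity; the trailing two-letter state code is split off
and compared exactly, so "Aetna Life Insurance, AR" can map to
"Aetna HMO, AR" but never to a California plan.

## Derived provider attributes

* **Rating**: review-count-weighted mean over the provider's linked
  profiles, in [0, 100]; absent when the provider has no reviews.
* **Hospital score**: the provider's specialty is mapped to broad hospital
  ranking categories through a user-supplied table filtered to specialties
  with strictly more than 100 occurrences (`build_specialty_map`). A
  hospital's score for a specialty is the *mean* over its mapped
  categories; the provider's score is the *maximum* over affiliations;
  unmapped specialties yield NA.
* **Hospital rank**: ranked hospitals keep ranks 1..m; every unranked
  hospital is treated as sitting at the bottom of the list and receives the
  median of positions m+1..N, i.e. `(m + 1 + N) / 2` rounded half-up (for
  50 ranked among 1,956 this is 1004). The provider's value is the mean
  over affiliations.
* **Relative cost with respect to area**: per HCPCS code, the provider's
  (procedure-weighted) average charged amount is compared with
  same-specialty billers of that code within 30 miles — the 1,000 nearest
  by haversine distance (Earth radius 3,958.8 mi), ties at the boundary
  broken by ascending identifier, the provider always included — and
  min–max normalized to 0–100, with 100 for the most expensive and the
  degenerate max = min neighborhood defined as 100. Per-code values are
  then averaged with the provider's procedure counts as weights. The
  neighborhood is computed per code (charge panels differ by code), and
  including the provider itself makes the degenerate case graceful and the
  score 100 attainable.
* **Referrals**: raw inbound referral counts by default. The count is
  strongly specialty-dependent; a per-specialty z-score normalizer is
  available (`referral_norm = "specialty_z"`) but off by default, matching
  an analysis that used unnormalized counts.

## Aggregation and statistics

Plan aggregates are unweighted means over member providers (each provider
counts once; ratings averaged over rated members only). Plans with
incomplete core scores are excluded, as are plans with fewer than
`min_members = 5` members — single-member means are degenerate; the
count of both exclusions is reported. Correlations use listwise deletion
per variable pair and report n; p-values are two-sided throughout (Pearson
via the t transform on n − 2 df). The Wilcoxon signed-rank test drops zero
differences, mid-ranks ties, and uses the exact null distribution for up to
25 untied differences (the tie-corrected normal approximation otherwise);
the Mann-Whitney U test is exact for untied samples with size product
≤ 400. Raw p-values are reported, faithful to an analysis that applied no
multiple-testing correction; a Benjamini–Hochberg column is available
behind `bh = TRUE`.

## The synthetic world

The generator (`generate_world`) emulates the five source families with
ground truth. Where the emulated study reports empirical marginals, those
are the defaults: a 4% award rate, 42% of providers with zero referrals,
50/1,956 hospitals ranked, 213/1,264 plans with incomplete scores,
1–8 accepted insurers per provider (mean ≈ 1.7). Distributions the sources
never specify are modelled parsimoniously:

* ratings as `100 − Gamma(2.2, scale 8)` plus a state intercept, clipped to
  [0, 100] — mean ≈ 82 with the left skew (median above mean) that patient
  review scores show;
* referral counts as zero-inflated negative binomial (zero mass 0.42,
  heavy-tailed nonzero part);
* charges as log-normal per HCPCS code with specialty and state effects;
* geography as disjoint synthetic 3°×3° per-state boxes with uniform
  provider locations — sufficient for radius/nearest-neighbor logic, with
  no claim to real geography;
* review coverage `frac_reviewed = 0.3` by default: most providers have few
  or no reviews, but the plan-level mean remains estimable. The marginal
  review-count statistics of the emulated sources are mutually ambiguous
  (a mean below 1 review per provider alongside a well-populated mean
  rating), so coverage is an explicit knob rather than a fixed constant.

The site directory is a perturbed clone of the provider directory: up to
`max_edits = 2` random character edits per name-like field, field dropout
with probability 0.1, and 10% distractor profiles with no counterpart.
Edits never touch a field's first character — directory typos
overwhelmingly preserve initials — which keeps initial-based blocking sound
under the default noise; heavier perturbation models should switch to
`"either_initial_state"` blocking.

### Planted associations

Targets are Pearson correlations between plan-level aggregates and the
consumer-satisfaction score (defaults: 0.376 for mean rating, 0.031
referrals, 0.183 award ratio, −0.108 hospital rank, 0.266 relative cost),
and between condition-restricted mean specialist ratings and the six
condition treatment scores (0.135 women's health, 0.112 mental and
behavioral health, 0.112 cancer screening, −0.002 heart disease, −0.083
children and adolescents, −0.259 diabetes).

In the default `"sample"` mode the plan score is *constructed* to have
exactly the target sample correlations with the generated aggregates: with
standardized aggregate columns Z and target vector ρ, the score component
is `Z S⁻¹ρ + √(1 − ρ'S⁻¹ρ) e`, where S is the sample correlation matrix of
Z and e is fresh Gaussian noise residualized against [1, Z] and scaled to
unit sample variance — the same idea as `MASS::mvrnorm(empirical = TRUE)`.
This choice separates concerns: any deviation of the pipeline's estimate
from the target measures pipeline distortion (linkage errors, membership
mis-mapping, aggregation differences), not sampling error. A
`"population"` mode (independent Gaussian noise; targets hold in
expectation with the usual `(1 − r²)/√n` sampling spread) is available for
sampling-theory experiments. Strata too small for the joint construction
fall back to planting the first attribute alone, then to pure noise, with
warnings.

With `state_heterogeneity > 0` (default 6 score points) the targets are
planted *within each state*, and independent state intercepts are added to
provider ratings and plan scores, so the pooled correlation is attenuated
below the state-wise ones — the localization pattern the analysis is
designed to exhibit. `state_intercept_cor < 0` makes the two intercept
series discordant, depressing the pooled correlation further; with
`state_heterogeneity = 0` the targets are planted pooled.

### What the generator does not emulate

Passing tests on this world show the pipeline's mechanics are correct under
known structure; they do not validate the substantive findings on real
data. Real name noise is not uniform random edits (nicknames, transliteration,
suffixes); real plan membership is not independent popularity-weighted
sampling; real review behavior is selective, not missing at random; real
geography, specialty taxonomies and insurance-market structure are richer
than the synthetic stand-ins.

## Numerical and design notes

* Rank imputation rounds half-up; the bottom-median of positions 51..1,956
  is 1003.5 → 1004.
* The strictly-greater-than-100 occurrence filter is a boundary the tests
  pin (100 is excluded, 101 included).
* Greedy one-to-at-most-one assignment (rather than optimal bipartite
  matching) implements "at most one" with minimal machinery; an optimal
  assignment would be a drop-in extension.
* Degenerate inputs: all-missing score vectors, zero-variance correlation
  inputs, empty groups and all-zero difference vectors raise informative
  errors; empty member sets and unmapped specialties propagate NA.
* Problem sizes in the shipped experiments were chosen so each property is
  measured at realistic per-plan membership: linkage recovery at 1,000
  providers over 10 seeds; planted-correlation recovery at 400 plans /
  1,500 providers with full review coverage over 100 replicates (full
  review coverage makes the planted targets defined over every aggregated
  plan, so recovery error measures pipeline distortion alone);
  stratification at 300 plans; condition-sign recovery at 150 plans. The
  recovery experiments that probe only the aggregation/statistics stages
  run with ground-truth links (`linkage = "truth"`); the headline recovery
  experiment runs the full fuzzy linkage.

## Limitations

Beyond the synthetic-vs-real gap above: the analysis is correlational by
design (no causal claims, no confounder adjustment); referral counts are
used unnormalized by default; the relative-cost score ignores payer-specific
allowed amounts (public-payer compensation is largely fixed per procedure);
and linkage quality on real data depends on blocking assumptions that the
synthetic noise model deliberately keeps favorable.
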