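---
title: "Minimizing natural-product screening libraries by scaffold diversity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizing natural-product screening libraries by scaffold diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldpick)
```

## The model

A natural-product extract library is represented as a bipartite membership
structure: each extract $e$ carries a set $S(e)$ of *scaffolds* — connected
components of a classical molecular network, i.e. families of MS/MS spectra
grouped by fragmentation similarity, used as a proxy for shared chemical
cores. The library's *maximal scaffold diversity* is the universe
$U = \bigcup_e S(e)$, and the coverage of a sub-library
$L$ is $|\bigcup_{e \in L} S(e)| \,/\, |U|$.

Choosing the smallest $L$ with full coverage is minimum set cover, which is
NP-hard; the package implements the standard greedy maximum-coverage rule
(pick the extract with the largest marginal scaffold gain, repeat), which
carries the classical $(1 + \ln |U|)$ approximation guarantee and, more
importantly here, produces the *nested* family of libraries practitioners
actually want: the 80% library is a prefix of the 95% library, which is a
prefix of the 100% library. The test suite checks the approximation bound
against an exhaustive minimum-cover search on small random instances, and
checks the greedy trace itself against an independently coded naive rescan.

Assumptions worth making explicit:

- A scaffold is "in" an extract if any of its member spectra lists that
  extract as a source file. Abundance plays no role in selection — a trace
  detection counts as coverage.
- The universe is whatever the input node table detected. Selection cannot
  know about chemistry the instrument missed.
- Un-networked nodes (GNPS component index −1) each count as a one-molecule
  scaffold by default, since diversity is counted over all detected
  chemistry. Whether to count them is genuinely open —
  `read_node_table(drop_singletons = TRUE)` implements the other reading,
  and the two can differ materially when singletons are numerous.

## Greedy selection: numerical choices

- **Threshold semantics.** "Reach 80% diversity" is inclusive: selection
  stops at the first step where covered/$|U| \ge$ target. With the toy
  instance $A=\{s_1,s_2,s_3\}, B=\{s_2,s_3\}, C=\{s_4\}$ and target 0.75,
  the single pick $A$ suffices.
- **Tie-break.** Among extracts with equal marginal gain the
  lexicographically smallest extract ID wins (configurable to input order).
  Nothing in the method prefers one tied extract over another; a fixed rule
  is needed only so that runs are reproducible and testable.
- **Zero-gain stop.** If no remaining extract adds a new scaffold the run
  halts. With an inclusive threshold this can only happen after the target
  is met (at target 1.0), so it is a defensive guard, not a behaviour knob.
- **Rounding.** All fractions are stored at full precision and rounded only
  for presentation. `fold_reduction()` uses conventional half-up rounding
  to one decimal; note that 1439/216 = 6.662 therefore prints as 6.7, while
  truncation would print 6.6 — reports of such ratios in the literature mix
  both conventions, so the full-precision value is always available
  (`digits = NULL`).
- **Reduction baselines.** A statement like "an 85% reduction in the
  library size needed for maximal diversity" is ambiguous about its
  baseline (full library vs the random-selection mean). The tool therefore
  reports both the greedy-vs-full and greedy-vs-random-mean numbers and
  leaves the choice of headline to the analyst.

## Random baselines

Each Monte-Carlo iteration draws one uniform permutation of all extracts
and accumulates coverage along it. A permutation yields nested random
libraries of every size simultaneously, so the per-iteration "extracts
needed to reach fraction $f$" is a first-passage time along the
permutation; its mean across iterations is the reported baseline.
(Independent re-draws per library size have the same per-$k$ marginal
distribution — the permutation scheme is simply cheaper and gives
first-passage sizes for free.)

The mean coverage at size $k$ has an exact closed form: a scaffold carried
by $m_s$ of $n$ extracts is missed with probability
$\binom{n-m_s}{k}/\binom{n}{k}$, so
$\mathbb{E}[\text{coverage}(k)] = \sum_s \left(1 -
\binom{n-m_s}{k}/\binom{n}{k}\right)/|U|$. `expected_random_coverage()`
computes this, and the suite requires the Monte-Carlo mean to agree within
three standard errors at every $k$ (10,000 iterations on a 30-extract
instance).

Hit-rate quartiles for size-matched random libraries use type-7
(linear-interpolation) percentiles, R's default; the estimator choice
moves the quartiles by at most one extract's worth of hit rate at the
library sizes involved. One master seed drives a single RNG stream
consumed sequentially across iterations; identical seeds reproduce every
summary exactly.

## Quantitative-table preprocessing

The filters run in a fixed order, each attributing its removals to a
reconciled report (input = repetitive + blank + presence + retained):

1. **Repetitive m/z** (`mz_tol` 0.01 Da, `rt_tol` 0.1 min,
   `max_occurrences` 8). Features are grouped by single-linkage m/z
   proximity; within a group, members at retention times within `rt_tol`
   are merged as oversplit peaks (abundances summed, metadata from the most
   abundant member), and groups spanning more than `max_occurrences`
   distinct RT clusters are removed wholesale as chromatographic
   background. The exact tolerances behind "highly repetitive m/z with
   close retention times" are not standardized; these defaults suit
   high-resolution orbitrap data at typical 10–15 min gradients and are
   CLI-exposed, with the whole filter skippable.
2. **Fivefold blank removal** (`fold` 5). A feature is removed when its
   mean sample abundance fails to reach `fold` times its mean blank
   abundance; features absent from all blanks are always kept. The blank
   aggregation rule (mean) is a choice — `blank_stat = "max"` is the more
   conservative alternative.
3. **Minimum presence** (`min_extracts` 3, inclusive). A correlation cannot
   be estimated meaningfully from fewer than three points. Presence is a
   zero-pattern criterion evaluated on raw abundances.
4. **TIC normalization.** Each sample column is divided by its own total
   (columns sum to 1 within 1e−12 afterwards); blank columns are dropped.
   Ranks within an extract are unchanged, so Spearman correlations are
   unaffected by this step — it matters for the Pearson path and for any
   cross-extract comparison of abundances.

Running the presence filter before normalization rather than after changes
no decisions (normalization preserves zeros) and leaves the final columns
summing to exactly 1. Positive- and negative-ionization tables should be
processed as separate runs and their correlation counts summed.

## Bioactivity correlation

For each feature, Spearman's $\rho$ between abundance and the activity
score is computed as the product-moment correlation of average ranks, with
the two-sided t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$
degrees of freedom for the P value. For binary hit calls the Pearson
(point-biserial) coefficient on the 0/1 vector is used instead. P values
are adjusted by Benjamini–Hochberg across all scored features of the run
(delegated to `stats::p.adjust(method = "BH")`; the suite checks it against
a hand-rolled step-up). A feature is a *bioactive candidate* when
$\rho > 0.5$ and adjusted $P < 0.05$: P values stay two-sided, and the
one-sided $\rho$ cut supplies the directionality (only positive
correlates of activity are candidates).

Two boundary rules: features with constant abundance across the shared
extracts (or a constant activity vector) have no defined correlation and
are reported with `rho = NA`, *excluded* from the BH family size; and the
t-approximation is used at all $n$ rather than switching to an exact null
at small $n$ — the suite quantifies the approximation error against an
exhaustive permutation null at $n \le 7$ (absolute deviation below 0.09,
with $\rho$ itself exact), which is adequate because candidate calling
operates at adjusted $P < 0.05$ on the strong-signal end of the scale.

**Retention** of a candidate feature in a minimized library is defined by
presence in the quantitative table: abundance > 0 in at least one selected
extract. Defining it instead via node-table source lists gives the same
answer whenever the two tables are consistent; the quant-table definition
is used because retention is ultimately about whether the candidate can
still be *measured* in the reduced library. Retention is necessarily
monotone across the nested 80%/95%/100% libraries, and the suite asserts
this on every run.

## Cost model

With $N$ extracts, rational size $n$, LC-MS cost $c_{MS}$ per extract and
assay cost $c_a$ per extract per assay (one extract per well, single
concentration), cumulative costs after $k$ assay campaigns are
$\mathrm{full}(k) = kNc_a$ and
$\mathrm{rational}(k) = Nc_{MS} + knc_a$. The break-even count is the
smallest $k$ with $\mathrm{rational}(k) < \mathrm{full}(k)$ — strictly
cheaper, ties count as not-yet-saving — i.e. the adjusted ceiling of
$Nc_{MS} / ((N-n)c_a)$. At $N=1500$, an 80% reduction and $1.50 per well
this gives 2 assays; at a 95% reduction and $0.50 per well, 4 assays.
Labor, instrument amortization and dose–response follow-up are outside the
model.

## The synthetic-data generator

`synth_generate()` emulates the *structure* of a redundant natural-product
screening campaign, not its mass spectrometry:

- **Membership.** Extract "hub" weights are log-normal (a few extracts
  carry much of the chemistry); each scaffold's carrier count is drawn from
  a geometric law (default $1+\mathrm{Geom}(0.1)$, i.e. a typical scaffold
  occurs in ~10 of 200 extracts) and carriers are sampled
  weight-proportionally. An alternative archetype mode makes 90% of
  extracts exact copies of 10 archetype scaffold sets — the extreme
  redundancy case in which greedy selection needs barely more picks than
  there are archetypes.
- **Activity.** Base activity 45 (percent-inhibition scale) plus 15 points
  per standard deviation of rare-scaffold richness (rare = carried by ≤ 2
  extracts) plus Gaussian assay noise (SD 15), clipped to [0, 100]; hits
  exceed 75. This yields full-library hit rates around 8–10%, in the range
  typical of crude-extract phenotypic screens, and ties bioactivity to rare
  chemistry so that diversity-driven selection plausibly enriches for hits.
- **Features.** Each scaffold carries $1+\mathrm{Pois}(2)$ features with
  log-normal peak areas (meanlog 11, sdlog 1 — peak areas in the 10^4–10^6
  range typical of MZmine exports) in exactly its carrier extracts. Ten
  *planted bioactive* features have presence probability increasing with
  activity (logistic in standardized activity around a 60% base rate) and,
  where present, log-abundance affine in standardized activity (slope 1.0
  log-units/SD, noise SD 0.5) — a monotone, noisy link of the kind rank
  correlation is meant to capture. Background is planted as five m/z
  ladders (one m/z recurring at 12 retention times in every column) and 15
  medium-derived features (strong in blanks, tenfold weaker in samples),
  which the repetitive-m/z and blank filters must remove exactly.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: m/z-dependent detection efficiency,
ionization suppression, correlated noise between co-eluting features,
missing-not-at-random dropout, retention-time drift between runs, or any
disagreement between the node table and the quant table (real GNPS and
MZmine exports are produced by different tools from the same raw files and
can disagree at the margins). The generator's tables are mutually
consistent by construction.

For the parameter-recovery experiment (40 extracts, ~500 features, 10
planted, 100 replicates) the rarity–activity link is switched off
(`rarity_gain = 0`): with activity tied to rare-scaffold presence, features
on rare scaffolds are *genuinely* activity-correlated and the notion of a
false discovery loses meaning. With the link off, every non-planted feature
is a true null; the suite requires an average of at least 8 of 10 planted
features recovered and a realized false-discovery proportion within the
nominal 0.05 (BH is conservative here because of the additional
$\rho > 0.5$ requirement, so realized FDP sits well below nominal).

## Problem sizes

The suite and the acceptance script run at deliberately desk-friendly
sizes, chosen to exercise every code path while keeping the full run in
tens of seconds: 200 extracts × ~530 scaffolds for the main synthetic
workflow (with 1,000-iteration baselines, matching the customary
iteration count for randomization baselines), 30 extracts ×
10,000 iterations for the hypergeometric calibration, 100 replicates for
parameter recovery, and ≤ 12-extract instances wherever an exhaustive
oracle (full greedy re-derivation, exact minimum cover, permutation null)
is the comparator.

## Known limitations

- Selection is presence-based: an extract contributing many scaffolds only
  as trace components counts as fully covering them, though follow-up
  isolation from it may be impractical. A weighted or abundance-thresholded
  variant is deliberately out of scope.
- Coverage treats all scaffolds as equally valuable; no weighting by
  scaffold size, novelty or dereplication status.
- The correlation stack assumes one activity score per extract; replicate
  assay wells must be aggregated upstream.
- The t-approximation for Spearman P values is slightly anti-conservative
  below $n \approx 10$; with the candidate threshold at adjusted
  $P < 0.05$ and $\rho > 0.5$ this does not change calls at realistic
  library sizes, but exact small-$n$ inference is not provided.
- The cost model prices wells, not people or instruments.
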