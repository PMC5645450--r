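---
title: "Screening compounds for single-gene perturbation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening compounds for single-gene perturbation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapscreen)
```

`cmapscreen` screens a library of drug-induced expression profiles for
compounds that move a single query gene up or down, then asks which drug
targets are over-represented among the strongest movers. This vignette
explains the statistical procedure, the assumptions behind each stage, the
parameters a user might reasonably change, and the design decisions taken
where more than one defensible choice existed.

## The data model

The input corpus is a genes × samples matrix of log-scale intensities with
per-sample metadata: the treating compound (empty for controls), an
instrument batch, and a vehicle flag. Three structural assumptions are
load-bearing:

* **Every batch contains at least one vehicle-control sample.** Fold
  changes are only ever computed within a batch, so a batch without
  vehicles is rejected at load time.
* **Values are log-scale.** Fold change is then an additive difference,
  which makes the vehicle correction symmetric and exact for additive
  batch artefacts. A linear-scale matrix can be log2-transformed on load
  (`read_expression(..., linear = TRUE)`).
* **Identifiers are opaque.** Gene, sample, compound and batch ids are
  case-sensitive strings; no synonym resolution or probe-to-gene collapsing
  is attempted. The matrix is treated as already gene-level.

## From profiles to prototype signatures

Each treatment sample yields a fold-change profile
`fc(g) = x(g) − mean(x(g) over same-batch vehicles)` and then a bijective
ranking of all `G` genes, rank 1 being the most up-regulated. Because a
merged signature must not depend on incidental input ordering, every tie in
the package — equal fold changes, equal mean ranks, equal query ranks — is
broken lexicographically (C-locale radix order), never randomly.

Replicate rankings for one compound are merged into a *prototype ranked
list*: repeatedly take the pair of current lists with the smallest Spearman
footrule distance (sum of absolute rank differences) and replace it with
their Borda merge (re-rank on the mean of the two rank vectors), until one
list remains. Distance ties go to the pair appearing first in input order.
The hierarchical footrule/Borda scheme is the default because nearest-pair
merging lets concordant replicates form a consensus before discordant ones
are folded in; a single-step mean-rank Borda aggregation is exposed as
`merge = "mean-rank"` for comparison, and in our simulations the two
behave near-identically on well-behaved replicates.

Two properties of the merge are worth stating precisely:

* When all pairwise distances are distinct, the result is invariant to the
  order in which the replicate lists are supplied (property-tested on
  random inputs).
* For replicates generated as noisy perturbations of one latent ranking,
  the merged list is at least as close to the latent ranking (footrule) as
  the median replicate — the consensus-recovery property that motivates
  merging at all. The test suite checks this across seeded trials with 5
  replicates of a 100-gene ranking at noise SD equal to half the latent
  score SD.

## Scoring and ranking compounds

A compound's score is simply the query gene's rank inside its signature.
After merging, only ranks survive — no fold-change magnitudes — so the
library ordering "by descending query-gene fold change" is implemented as
ascending query rank, its exact rank-space equivalent. The
`normalized_score = (G − query_rank)/(G − 1)` column rescales the rank to
[0, 1] for cross-library comparison; it is monotone in the rank and has no
further meaning.

## Enrichment with a matched-size permutation null

For a target set of `s` compounds inside a ranking of `N`, the running sum
starts at zero, gains `1/s` at each member and loses `1/(N − s)` otherwise;
the enrichment score is the deviation of maximal magnitude, signed.
`ES = +1` exactly when the members fill a prefix of the ranking, `−1` for a
suffix. If the maximal positive and negative deviations tie in magnitude,
the one attained earlier in the walk is returned; this makes the statistic
total and deterministic. One consequence of that tie rule is that the
antisymmetry `ES(reversed ranking) = −ES` holds whenever the extreme is
unique in magnitude but only `|ES|` is preserved at an exact tie — the
property tests treat the tied case accordingly.

All candidate values of the running sum are integer multiples of
`1/(s(N − s))`, so the implementation works on integer numerators and
divides once at the end. Extremes and magnitude ties are therefore resolved
in exact arithmetic, and the statistic agrees bit-for-bit with a
full-trajectory enumeration (verified exhaustively for all universes
`N ≤ 12`, set sizes `≤ 4`).

The null distribution draws uniformly random compound sets of exactly the
observed size — 10,000 of them by default — and the two-tailed empirical
p-value is `(#{|ES_null| ≥ |ES_obs|} + 1)/(n_perm + 1)`. The absolute-value
form is the standard symmetric two-tailed choice; the add-one correction
keeps p strictly positive, with floor `1/(n_perm + 1)`. Because a uniform
random set's ES does not depend on which compounds sit where, the null
depends only on `(N, s)`; `enrich_all()` therefore caches one null per
distinct set size by default. Each null's RNG substream is derived from the
master seed plus its cache key (set size, or target id when
`cache_nulls = FALSE`), so results are independent of target processing
order; the two policies are both reproducible but numerically different,
and the size-keyed cache is the reference behaviour.

FDR control is Benjamini–Hochberg in a single family across all tested
targets, pooling curated ("referenced") and predicted associations —
`family_by_source = TRUE` splits the correction when the two catalogues
should not compete. Target sets are intersected with the screened compound
universe before testing; sets left empty (or covering the entire universe,
where the statistic is undefined) are dropped with a warning, and
`set_size` is always reported post-intersection.

## What the synthetic corpus emulates

`simulate_corpus()` generates the statistical structure the screen assumes,
with known ground truth. Per gene, a baseline intensity is drawn
`Normal(8, 2)` (log2 scale); each batch adds a gene-wise offset
`Normal(0, 0.5)`; each sample adds measurement noise `Normal(0, 1)`.
Regulator compounds shift the query gene by ±2 (i.e. twice the noise SD)
and 50 further random genes by `Normal(0, 1)` amounts, so signatures have
multi-gene structure and the merge is exercised realistically. Batch
effects are deliberately *additive* offsets: within-batch vehicle-mean
subtraction then removes them exactly in expectation, which makes the
normalization stage testable rather than decorative.

The default study conditions are 1000 genes, 300 compounds with 3
replicates each across 5 batches (6 vehicles per batch), 20 up- and 20
down-regulators, one planted signal target set of 15 compounds at purity
0.8 (12 members drawn from same-direction regulators) among 20 random
noise sets of the same size. These sizes keep a full
simulate–screen–enrich run around a second while leaving the planted
signal recoverable but not trivial: the test suite requires the signal
target to reach FDR < 0.05 in at least 90% of 50 seeded runs and at least
80% of planted up-regulators to land in the top decile of the ranking.
Calibration is checked separately on a null configuration (no regulators,
uniformly random sets): the fraction of p-values below 0.05 must sit
within binomial 99% bounds of 0.05 across 2000 set draws, and small-universe
permutation p-values are compared against exhaustive enumeration.

What the generator does *not* emulate: real dose–response structure, cell
line heterogeneity, correlated gene modules, platform- or probe-level
artefacts, non-additive batch effects, and compound library redundancy.
Passing tests demonstrate that the pipeline's statistics behave as designed
under its own assumptions — not that those assumptions hold for any
particular real corpus.

## Numerical and degenerate-input choices

* Ranks are 1-based; rank 1 = strongest up-regulation, everywhere.
* The ES is computed in exact integer arithmetic (above); no floating-point
  tolerance enters any comparison or tie-break.
* Degenerate sets (empty after intersection, or equal to the whole
  universe) are errors at the statistic level and drop-with-warning at the
  pipeline level.
* `n_perm = 1` is legal and reproducible; p is then 0.5 or 1.
* All randomness flows from explicit integer seeds; per-consumer substreams
  are derived by hashing the seed with a stable string key, so no result
  depends on evaluation order, and the ambient RNG state is never consumed
  or disturbed (`withr::with_seed`).
* Replicate counts of 1 are supported: the prototype ranked list of a
  single experiment is that experiment.

## Limitations

The screen is single-gene by design; multi-gene query signatures are out of
scope. No parametric approximation to the permutation null is offered —
p-value resolution is bounded by `1/(n_perm + 1)`, so FDRs near the
significance boundary with few targets can be coarse. Compound identifiers
are matched exactly; harmonising vendor names or salts across catalogues
must happen upstream. Finally, the enrichment universe equals the ranked
library, so targets whose compounds were never screened simply cannot be
tested — their absence is reported, not imputed.
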