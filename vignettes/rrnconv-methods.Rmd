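---
title: "Methods: inferring and estimating rRNA gene conversion rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and estimating rRNA gene conversion rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the choices made
where the design was genuinely open, and what the tests do and do not show.

## The measurement problem

A multicopy gene family under concerted evolution — here modelled on the
seven *E. coli* rRNA operons — homogenizes because gene conversion copies
sequence between near-identical loci. In a mutation accumulation (MA)
design, independent lineages pass through repeated single-cell bottlenecks,
so almost all conversions that happen are retained regardless of fitness,
and the event count per lineage over `T` generations is modelled as
Poisson(μ·T) with μ the per-genome per-generation conversion rate.

The catch is that conversions are only *observable* at heterologous sites:
alignment columns where copies differ. A conversion between two copies that
are identical over its window changes nothing; a later overlapping event can
hide or revert an earlier one; and two events can merge into what parsimony
reads as one. The reconstructable ("observable") count therefore undershoots
the true count, and the rate must be estimated through a simulation that
reproduces the losing process.

## Parsimonious event inference

For each evolved copy (the *recipient*), the changed columns relative to the
ancestral family are partitioned into the minimum number of events such that
each event can be explained by copying a single ancestral *donor* over a
contiguous span. A donor is compatible with an event iff its ancestral
sequence equals the evolved recipient over **every** column of the event's
span — changed and unchanged alike — so that realizing the event produces
only the observed changes.

The partition is built greedily left to right: extend the current event's
window to the next changed column while at least one donor remains
compatible, close it when none does. Because compatibility is a conjunction
over the span, growing a window can only shrink the donor set (antitone
feasibility), so every prefix of a feasible group is feasible and the greedy
maximal-extension partition attains the true minimum. We still verify this
against an exhaustive oracle (`count_min_events_oracle()`, all partitions of
the changed columns into contiguous donor-consistent groups) on hundreds of
randomized small instances in the test suite.

Extents follow the field's convention: the *minimum extent* runs from the
first to the last changed column; the *maximum extent* is computed per donor
by growing the window outward column by column while that donor matches the
evolved sequence, stopping at the first mismatch or the region boundary, and
reporting the widest single-donor interval. We deliberately report a
single-donor interval (rather than the envelope of per-side reaches over
different donors) because the maximum size is meant to be realizable by one
physical event from one donor.

Gaps are treated as a fifth character state everywhere, so the small indels
that segregate between copies are indexed, inferred and simulated by the
same machinery as substitutions. Coordinates are 1-based inclusive alignment
columns. Regions are analyzed independently; events never span a region
boundary. The 23S–5S spacer is special-cased: its two divergent length
alleles (186 bp and 92 bp in the packaged defaults) share too little
homology for partial exchanges, so spacer conversions are whole-unit allele
swaps with a single possible extent covering the entire spacer.

## The conversion simulator

Simulated events are parameterized from observed events: pick a template
event uniformly with replacement from the region set in scope, draw the size
uniformly between that event's minimum and maximum inferred sizes, place it
uniformly inside the region, and draw recipient and donor uniformly. A
50-column floor is applied to sizes (the approximate minimum for efficient
RecA-mediated homologous recombination); a template whose maximum falls
below the floor yields the floor size. The template also fixes the simulated
event's region, so the observed regional weighting (e.g. 7:27 between 16S
and 23S) is preserved without inventing a placement prior. Sizes and
positions are measured in alignment columns, which for these nearly gap-free
alignments coincide with base pairs.

Events are applied sequentially and donors contribute their **current**
(possibly previously converted) sequence — this is the physical process, and
it is what makes hiding and reversion of earlier events possible. One
consequence worth stating plainly: a donor that has itself become a mosaic
of two ancestral sequences can, when copied, leave a trace that parsimony
must explain with *two* ancestral-donor events. The reconstructed count
therefore undershoots the true count on average but can exceed it in
individual lineages (one or two lineages in fifteen at study-like
parameters). The estimator is unaffected by this asymmetry because the same
counting rule is applied to the simulated and the observed data.

Since conversions only move existing states between copies, ancestrally
monomorphic columns can never change; the simulation kernel (C++) therefore
tracks state only at heterologous columns, which is what makes the
Monte-Carlo estimation below cheap.

## Rate estimation

`simulate_observable_counts()` draws, per replicate, a Poisson number of
events for each of `n_lineages` lineages (defaults: 15 lineages, 13,750
generations), applies them, and sums the minimal reconstructable counts over
lineages and regions. `estimate_rate_ml()` then:

* evaluates the Monte-Carlo probability of *exactly* the observed count on a
  candidate grid: `{0}` plus 61 log-spaced rates spanning a factor of 30 on
  either side of the naive rate `observed/(n_lineages × generations)`,
  followed by one 21-point local refinement around the argmax; grid ties
  resolve to the smallest rate;
* uses common random numbers (the same substream seed at every candidate
  rate) so the likelihood profile and the tail curves are smooth enough to
  grid-search and bisect;
* finds the 95% bounds by log-scale bisection (relative tolerance 1%) on the
  tail definitions: the lower bound is the largest rate with ≤ 2.5%
  probability of producing the observed count *or more*, the upper bound the
  smallest rate with ≤ 2.5% probability of the observed count *or fewer*.
  For an observed count of zero the lower bound is pinned at 0.

In a fully observable regime (a toy family in which every ordered pair of
copies differs at every column, short windows, low rate) this machinery must
reduce to the closed-form Poisson answer: μ̂ ≈ k/(nT) and the exact
tail-based Poisson interval. The acceptance tests check exactly that, and
end-to-end parameter recovery on the synthetic family (50 repetitions at
1,000 replicates) requires the generating rate inside the 95% CI at least
45 times — the coverage a 95% interval should deliver.

The regional likelihood ratio test compares independent per-region ML rates
against one shared rate, with likelihoods being the Monte-Carlo
probabilities of the exact observed counts maximized over a common grid
under common random numbers (so the statistic is nonnegative by
construction). The χ²(1) reference for a simulated likelihood ratio is an
approximation and is labelled as such; a Monte-Carlo likelihood of zero is
reported as a bound with a warning, never silently. Type-I error at the
nominal 5% level is checked by simulation in the test suite.

## Conditional resampling null

To ask whether particular operons or sites convert more or less often than
chance, conversions are drawn one at a time — each assigned to a uniformly
random lineage — until the total observable count equals the empirically
observed one; the observable events of the final sequences (not the raw
draws) are then tabulated by recipient operon and by changed heterologous
column. Because a draw can raise the observable count by more than one (a
new event can split an existing one), the walk can skip past the target, and
above the target its drift is upward; the implementation therefore restarts
the replicate on overshoot, which makes the procedure a rejection sampler
conditioned on exactly the target count. An iteration cap (10⁶ draws per
replicate) turns pathological configurations into an explicit error.

Per-category summaries report the null mean and the 2.5%/97.5% quantiles
(inverse-ECDF quantiles, type 1, appropriate for small integer counts).
Empirical p-values are twice the smaller tail proportion *including ties*,
capped at 1, and Bonferroni-adjusted by the number of categories of the kind
under test (the operon count for operons; the number of heterologous columns
for sites). A site is credited to an event only if the event *changed* it,
not merely covered it — the interpretation that matches counting "conversion
events changing the sequences of heterologous sites"; covering-based
attribution would need the event structure rather than the per-column diff.

## Identity evolution

Mean pairwise identity is computed on the concatenated gene-region
alignments with the full alignment length as denominator for every pair —
two aligned gaps count as a match, gap against base as a mismatch — and
reported in percent; the per-lineage delta is evolved minus ancestral, in
percentage points. The across-lineage trend test is a two-sided Wilcoxon
signed rank test against zero: zeros are dropped (their count is reported),
the exact null is used for n ≤ 25 when the remaining deltas are untied, the
normal approximation otherwise, and an all-zero input returns p = 1 with a
degenerate flag rather than an error.

## The synthetic family generator

`generate_operon_family()` emulates the architecture the analysis was built
for: 7 copies, gene regions of 1542 and 2904 columns, a biallelic spacer
with 186/92-bp variants split 4/3 among copies, and a target mean pairwise
identity of 99.6% over the concatenated gene regions. Heterologous columns
are placed uniformly at a density solved analytically from the expected
pairwise mismatch per column under the allele-partition scheme (each copy
assigned an allele uniformly, conditioned on all alleles present; 10% of
columns carry three alleles), rather than calibrated by rejection. Across
seeds the realized identity lands within ±0.1 of the target and the
calibration is unbiased to well within that.

What the generator does *not* emulate — and hence what passing tests cannot
certify about real data: heterologous sites are placed independently and
uniformly, whereas real operon families carry clustered divergence (e.g. a
run of linked differences private to one copy) and recombinogenic motifs
(Chi-like sites) that modulate local conversion rates; there is no point
mutation during the MA simulation (none was needed for the system modelled,
where no de novo rRNA point mutations were found); and gene regions evolve
without indels. Because real divergence is more clustered, real
observability per event differs from the synthetic family's, and rate
estimates on synthetic inputs are internally consistent but not a
reproduction of any published rate. The synthetic size templates
(`synthetic_size_sampler()`) mimic the observed spread — mostly single-base
minimum sizes with maximum extents of a few hundred to ~2137 columns.

## Numerical and degenerate-input choices

* Grid policy: ≥ 60 log-spaced candidates over a ×30 span plus one local
  refinement; ties toward the smaller rate. An observed count that no grid
  rate ever produces raises an estimation-failure error carrying the range
  of simulated totals as a diagnostic.
* Bisection: log-scale, relative tolerance 1%, brackets expanded by
  doublings (cap 60) before refinement; the returned bound is the bracket
  side that satisfies the tail condition.
* Reduced-replicate configurations are first class: the test suite runs the
  estimator at 300–2,000 replicates and the recovery/type-I studies at
  1,000/300 replicates with problem sizes (15 lineages, the full-length
  synthetic family or a 40-column toy) chosen so the whole suite stays at
  desk scale; `scripts/acceptance.R` uses 1,000–2,000 replicates.
* Determinism: every user-facing simulation takes a seed (or derives
  substreams from a master seed), and the pipeline embeds the seed, a config
  hash and the package version in its JSON summary; identical config + seed
  gives byte-identical outputs.
* Validation errors are typed by cause: alignment-shape, identity (operon
  labels), alphabet, novel-allele (a change matching no other copy — never
  observed in the modelled system and impossible under pure conversion, so
  it guards corrupted input), unclassified spacer, size-guard (oracle),
  non-convergence (resampling cap).

## Known limitations

* The maximum-extent rule reports the widest *single-donor* interval; when
  donors disagree about how far an event could have extended, per-side
  envelopes over different donors would be wider. This matters only for the
  size templates fed to the simulator.
* The packaged observed-events table is a synthetic stand-in constrained to
  published tallies (its filename and documentation say so); analyses that
  depend on the real per-event coordinates (e.g. real per-site hotspots)
  cannot be reproduced from it.
* Published summaries disagree internally on one tally (11 vs 10 events for
  one operon); the packaged table follows the 11-count bookkeeping and the
  discrepancy is surfaced here rather than silently resolved.
* The LRT's χ² reference on simulated likelihoods is approximate; with few
  replicates the statistic inherits Monte-Carlo noise, which the type-I
  calibration test bounds but does not remove.
* No FDR alternative to Bonferroni, no spatial clustering test for site
  hotspots, and no probabilistic assignment among donor candidates — donor
  sets are reported whole.
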