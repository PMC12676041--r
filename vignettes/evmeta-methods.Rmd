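---
title: "Methods: differential expression and exhaustive EV-proteome meta-comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and exhaustive EV-proteome meta-comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmeta)
```

evmeta analyses the protein cargo of extracellular vesicles (EVs) released
by cells under oxygen stress. It covers three statistical tasks: calling
differentially expressed proteins (DEPs) from a label-free two-condition
intensity table; quantifying how much of a detected proteome was already
reported in EV catalogs; and an exhaustive comparison of protein-identifier
sets across many published datasets, summarised by a Simpson
condition-type diversity index. This vignette explains the models, the
parameters that matter, and the choices made where the design was open.

## Identifier space

Cross-study set operations are only meaningful over a shared identifier
space. evmeta canonicalises UniProt accessions: whitespace stripped,
upper-cased, and isoform suffixes (`-1`, `-2`, ...) removed by default so
isoforms merge into one protein. Published EV proteome lists rarely agree
on isoform annotation, so merging maximises comparability; the stripping
can be disabled (`strip_isoform = FALSE`) when isoform resolution is the
point. Gene symbols are deliberately *not* used for membership — symbol
aliasing would make set intersections ambiguous — and no online mapping
service is consulted: lists must arrive as accessions.

## Differential expression

The model is the standard one for label-free MS intensities: abundances are
treated as log-normal, so tests run on log2-transformed intensities
(variance stabilisation), while fold changes are reported on the raw scale
as mean(treatment)/mean(reference), which is what bench scientists quote.
Both conventions are recorded in the result object.

Choices and their defaults:

- **Test** (`t_variant = "student"`): a pooled-variance two-sample t-test.
  With triplicates per group there is little information to estimate two
  separate variances, and the pooled test is the plain reading of a
  "two-sample t-test"; Welch is available by flag.
- **Multiplicity** (`bh_adjust()`): Benjamini–Hochberg step-up across
  exactly the *tested* proteins. Proteins failing the min-valid filter are
  excluded from the family — including them would dilute m with tests that
  were never performed.
- **Significance criterion** (`significance_on = "q_value"`,
  `alpha = 0.05`): the FDR-adjusted q is the default gate. A raw-p gate is
  selectable because both conventions circulate for this design; rather
  than silently resolving the ambiguity the choice is an explicit
  configuration.
- **Fold-change dead zone** (`fc_up = 1.20`, `fc_down = 0.83`): calls
  require both statistical significance and a ratio outside
  [0.83, 1.20]. Note 0.83 ≈ 1/1.20, so the zone is symmetric on the log
  scale.
- **Missing values** (`min_valid_per_group = 2`): no imputation. Zeros and
  non-positive entries count as missing (a label-free zero almost always
  means "not quantified", and log2 requires positivity; a
  `zeros_are_values` flag overrides at read time). A protein needs at
  least two observed intensities per group to be testable; anything else
  is reported as `not_tested` rather than guessed at. Imputation schemes
  inject distributional assumptions that a small-n t-test cannot absorb.

Degenerate inputs are resolved by the limit of the statistic: two groups
with zero variance and equal means give t = 0, p = 1; zero variance with
unequal means gives the smallest representable positive p. These cases are
unreachable with continuous data but occur with truncated or
integer-rounded inputs.

### Power of the triplicate design

With triplicates and multiplicative noise of CV 0.2 (natural scale), the
log2-scale residual sd is √log(1.04)/log 2 ≈ 0.286, so a planted |log2
effect| of 2 has noncentrality ≈ 8.6 on 4 degrees of freedom. That sounds
enormous, but a 4-df variance estimate is itself so variable that the
BH-adjusted threshold inside a several-thousand-protein family (which
demands p on the order of 10⁻³) is missed by a substantial fraction of
true effects: the self-consistent power of the q < 0.05 gate in a
5,200-protein family is ≈ 0.64 by the noncentral-t closed form. The
package's Monte-Carlo checks measure exactly this: FDR is controlled
comfortably below nominal (the fold-change dead zone removes a further
slice of borderline nulls), while sensitivity of the default gate sits
near two-thirds, not near one. This is a property of 3-vs-3 label-free
designs generally — worth keeping in mind when interpreting "only k
proteins changed" claims — and is why the raw-p gate, which corresponds to
what several published analyses actually did, recovers far more of the
planted effects at the cost of a higher false-discovery fraction.

## Catalog overlap

`compare_catalog()` partitions a query proteome against reference catalogs
(ExoCarta/Vesiclepedia-style snapshots supplied by the user as plain
lists): per-catalog overlap counts plus combined `in_any`/`in_none`, with
`in_any + in_none = |query|` by construction. The proteins in no catalog
are returned explicitly — these "novel in EVs" candidates are usually the
interesting ones.

## Exhaustive meta-comparison

Given a registry of N datasets (each a protein set with a condition type
among normoxia, hypoxia, OGD, stroke, other), every subset of two or more
datasets is one *comparison*: the tuple of dataset ids involved and the
exact intersection of their protein sets. There are 2^N − N − 1 such
subsets (all subsets minus the empty set and the N singletons); at the
reference scale N = 16 that is 65,519 comparisons. Empty intersections are
enumerated and counted — they are information too — but excluded from
downstream collapse by default.

Implementation: protein sets become boolean membership vectors over the
sorted union universe, and the subset lattice is walked depth-first so each
subset's intersection is a single vectorised AND away from its parent's —
2^N intersections total rather than the Σ C(N,k)·(k−1) of recomputing each
subset from scratch. Results are then ordered size-ascending, then
lexicographically by registry position; the order is part of the contract
so downstream output is byte-reproducible. A cap (`max_n = 24`) guards
against accidental 2^N blow-ups; 16 datasets over a few-hundred-protein
universe enumerate in about a second.

**Anchoring.** Analyses usually centre on the study's own datasets:
`filter_by_anchor()` keeps comparisons whose parts intersect the anchors
(`mode = "any"`) or contain them all (`mode = "all"`). With k anchors,
any-mode keeps (2^N − N − 1) − (2^(N−k) − (N−k) − 1) comparisons —
49,150 of the 65,519 at N = 16, k = 2 — because the removed comparisons
are exactly the enumerable subsets of the N − k non-anchors. Any-mode is
the default since it reproduces that published count exactly; all-mode is
the stricter reading.

**Redundancy collapse.** Two comparisons with identical common sets say
the same thing; the one with fewer parts adds nothing. Comparisons are
grouped by exact set-equality of their intersections and each group
becomes one record whose `parts_union` is the union of member part-tuples
(a true disjoint union is impossible when tuples share members, which they
normally do). The defining soundness property — the intersection over
`parts_union` equals the shared common set — holds automatically for
genuine intersections: every member tuple's intersection equals C, so the
union's intersection can be no larger, and it contains C because every
involved set contains C. The implementation re-verifies this at
construction and raises an internal-consistency error on violation, which
can only signal corrupted input. Collapse is idempotent. Grouping empty
intersections would produce one degenerate all-datasets record, which is
why they are excluded by default (`keep_empty = TRUE` retains them).

**Ranking.** Collapsed records are ranked descending by shared-protein
count or by the number of datasets involved, with ties broken by the other
key and then lexicographically by `parts_union` — fully deterministic, so
ranked tables are stable across runs and machines.

**Simpson type diversity.** Each comparison is scored by the probability
that two datasets drawn from it share a condition type. The default
estimator is the without-replacement form Σ n_t(n_t−1)/(n(n−1)), chosen
because it attains both advertised endpoints exactly: 0 when all types are
distinct and 1 when all agree. The classic with-replacement Σ(n_t/n)² is
available but its floor is 1/n, not 0, so "0 = fully mixed" only holds for
the default variant. A high-SI, high-overlap comparison says the shared
proteins travel with a condition type; a low-SI one says they are
condition-independent EV cargo.

## Over-representation analysis

`run_ora()` replaces web-service annotation with a local hypergeometric
upper-tail test: for a query of n proteins from a universe of M, a term
with K members in the universe and k in the query scores
P[X ≥ k], X ~ Hypergeometric(M, K, n), with fold enrichment (k/n)/(K/M).
The default universe is the set of detected proteins, not the whole
proteome — testing against the full proteome inflates every term that is
merely "detectable by MS". Terms are tested only when k ≥ 1 and the BH
family is the tested terms. No annotation database ships with the package;
term content is version-dependent and must be a user-supplied GMT file.

## Synthetic data: what it emulates and what it does not

`generate_registry()` plants the structure the meta-comparison is designed
to detect: a core shared by all datasets (ubiquitous EV machinery), a
block shared within each condition type (type-specific cargo), and
per-dataset uniform noise. Defaults (N = 16, universe 600, core 25, type
block 40, noise 80, first two datasets typed hypoxia/normoxia) give
pairwise overlaps of the same order as published EV-proteome comparisons
(tens of shared proteins between a few-hundred-protein sets).

`generate_abundance()` plants a 210-protein, 3-vs-3 design with 83 up / 61
down proteins at |log2 effect| = 2 by default: log-normal baselines
(meanlog log 10⁶, sdlog 1, spanning the usual orders of magnitude of MS
intensities), multiplicative log-normal noise with CV 0.2 on the natural
scale, and a 5% uniform missing rate (typical for a curated label-free
table; set 0 to disable). Uniform missingness is the default because it
keeps the FDR/sensitivity behaviour analysable; real label-free
missingness is abundance-dependent (left-censored), and an
intensity-biased mode (`missing_mode = "intensity"`) is provided for
stress-testing the filter.

All randomness flows from one explicit `seed` through an isolated RNG
scope; identical parameters and seed reproduce outputs bit for bit, and no
global RNG state leaks.

What the generators deliberately omit: between-run normalisation drift,
batch effects, peptide-level rollup noise, correlated proteins
(co-regulation), and shared-protein structure beyond core/type/noise.
Passing tests on synthetic data therefore demonstrate algorithmic
correctness and calibration under the stated model — not robustness to
real-data pathologies, which enter upstream of this pipeline.

## Problem sizes and limitations

The test suite exercises the enumeration exhaustively to N = 12,
brute-force checks BH on a thousand random vectors and the hypergeometric
tail to M = 12, and runs the FDR/sensitivity Monte-Carlo at 5,200 proteins
× 20 replicates; the full N = 16 run appears in the acceptance path.
These sizes were chosen so the whole suite completes in well under a
minute while still covering every combinatorial regime.

Known limitations: the enumeration is exact and exponential — it is meant
for N of a few dozen at most, and the `max_n` cap makes that explicit;
no between-sample normalisation is applied (tables are assumed
pre-normalised); the DEP stage models two groups only; and accession
normalisation does not resolve merged/demerged UniProt entries across
database releases — the registry is only as consistent as its curation.
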