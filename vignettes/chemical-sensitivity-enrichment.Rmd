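---
title: "Methods: gene and pathway sensitivity to chemical exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene and pathway sensitivity to chemical exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemsens)
```

## The statistic and its rationale

`chemsens` treats the number of distinct chemical–gene interactions a
gene accumulates across the curated literature as a measure of that
gene's sensitivity to chemical exposures. An "interaction" is one
reported significant expression change of one gene in response to one
chemical, in one study, in one biological model; the unit of counting is
therefore the unique (study PMID, taxon, chemical, gene) combination.
Duplicated rows collapse before counting, and rows whose direction
disagrees within a duplicate group collapse to direction "unspecified",
because keeping both would count the same study twice while averaging
their directions would invent evidence.

Two filters precede counting. First, only human (*Homo sapiens*), mouse
(*Mus musculus*) and rat (*Rattus norvegicus*) evidence is retained —
the three organisms that dominate quantitative toxicology. Second,
genes absent from any of the three genomes are removed, using a
gene-presence table supplied by the caller: a gene–species pair can be
missing from interaction data either because the gene is insensitive in
that species or because it does not exist there, and only the latter
genes are excluded. A record gene missing from the presence table is a
hard error rather than a silent keep-or-drop, forcing the caller to
supply a complete table.

## Equal-area centering

Interaction counts are all positive, but the enrichment walk below is
designed for a signed statistic with mass on both sides of zero. The
package subtracts one constant $c$ from every gene's count. Writing the
positive and negative areas of the centered rank curve as
$A^+(c)=\sum_i \max(x_i-c,0)$ and $A^-(c)=\sum_i \max(c-x_i,0)$, their
difference is $A^+-A^- = \sum_i (x_i - c)$, which vanishes exactly when
$c = \bar x$. The arithmetic mean is therefore the unique equal-area
shift; it is computed exactly, never searched. Centering is a location
shift, so the ranking order is untouched, and the centered scores sum
to zero up to floating-point accumulation (the tests require a relative
residual below $10^{-9}$; in practice it is $\sim 10^{-14}$). Rank ties
are broken by gene symbol ascending — the data give no reason to prefer
one order and determinism is required for reproducible enrichment.
Degenerate inputs (fewer than two genes, or all counts equal) are
errors: such a ranking carries no ordering signal.

## The enrichment walk

For a ranked universe of $N$ genes with centered scores $s_i$ and a
gene set with $N_h$ members ("hits"), the running sum starts at zero
and, moving down the list, rises by
$|s_i|^p / \sum_{\text{hits}} |s_j|^p$ at a hit and falls by
$1/(N - N_h)$ at a miss. Both step families sum to one, so the profile
returns to zero after the last gene; the enrichment score ES is the
signed extremum of largest magnitude, bounded in $[-1, 1]$. The signed
(rather than positive-max) convention is what lets depleted sets —
pathways whose genes sit at the insensitive bottom of the ranking —
receive negative scores and hence "least sensitive" calls.

The weight exponent defaults to $p = 1$, the classic weighted
statistic; $p = 0$ reduces to an unweighted Kolmogorov–Smirnov walk and
is retained because its antisymmetry (negating and reversing the list
negates ES) makes a sharp property test. A set whose every member sits
exactly at the shift constant has all hit weights zero under $p>0$ and
is rejected as degenerate.

Implementation note: the walk is a single `cumsum` over the step
vector, and the profile's terminal value is checked against zero at
$10^{-9}$. The extremum uses `which.max(abs(.))`, whose first-position
tie-break matches the scalar reference implementation used in the
tests. `fgsea::calcGseaStat` agrees with this walk to $10^{-12}$ on
random fixtures and serves as an independent oracle in the test suite,
never as the implementation.

## Null model, NES, p and q

The input is a single preranked list, so phenotype permutation is
unavailable; the null is **gene-set permutation**: `n_permutations`
(default 1000) uniform random subsets of the universe, matched to the
restricted set size. One null array is shared by all sets of equal
size, and each array's random substream is derived deterministically
from `(seed, set_size)`, so adding or removing a collection cannot
shift another collection's null.

* **NES** = ES / mean(|same-sign null ES|). Sign-stratified
  normalization was chosen over sign-pooled because positive and
  negative walks are not symmetric for skewed centered scores; the
  choice is configurable in principle but fixed here for comparability.
  If no null value shares the observed sign (pathological at sensible
  permutation counts), NES is reported missing and the set is excluded
  from FDR.
* **Nominal p** uses the add-one estimator
  $(1 + \#\{|{\rm null}| \ge |{\rm ES}|\}) / (1 + \#\{\rm same\ sign\})$,
  which cannot report an impossible 0 from finite permutations.
* **FDR q** is the sign-stratified ratio-of-tails estimator on NES: for
  a positive observation, the fraction of positive *null* NES at least
  as large divided by the fraction of positive *observed* NES at least
  as large, clipped to $[0,1]$, mirrored for negative NES. Monotonicity
  is enforced by a running minimum walking from the least extreme to
  the most extreme NES on each side — the direction matters: run the
  other way, a single extreme set with an empty null tail drags every
  q on its side to zero.

Sets are first restricted to the ranked universe; the size bounds
(defaults 15–500 genes after restriction) are the common preranked
conventions, recorded in the run manifest. A pathway is called **most
sensitive** at NES ≥ 1.9 and q ≤ 0.05, **least sensitive** at
NES ≤ −1.9 and q ≤ 0.05, both comparisons inclusive.

## The synthetic generator

The generator emulates the three inputs — interaction table,
gene-presence table, GMT collections — with a latent-rate model: gene
$g$ receives $\lambda_g$ from a log-normal with arithmetic mean
`base_rate` and log-scale standard deviation `dispersion`, and emits
$k_g \sim \mathrm{Poisson}(\lambda_g)$ interaction lines. The
log-normal–Poisson choice reproduces the qualitative feature that
matters for enrichment — a heavy right tail in per-gene counts, i.e. a
strongly concave rank curve — without claiming a mechanistic model of
curation. Each line draws a chemical uniformly, a taxon and direction
from weight vectors, and a synthetic PMID; use terms are drawn once per
chemical (1–3 legal vocabulary terms), since annotation is a property
of the chemical. Key collisions are regenerated so emitted tables are
born deduplicated, giving deduplication tests a clean zero baseline.

Defaults define the benchmark used throughout the tests: 2,000 genes,
`base_rate` 34 (the per-gene mean of the real deposited data,
591,084/17,338), `dispersion` 1, three planted-high and two planted-low
sets of 50 genes at effect factor 3 (rates multiplied or divided by 3),
40 null sets of 50 genes, uniform taxa, direction weights
0.45/0.45/0.10 for +/−/1, and a 5% presence-table holdout to exercise
the shared-genome filter (planted genes are never held out, so the
benchmark's ground truth survives filtering). Null sets are sampled
from non-planted genes only — disjoint from planted structure, though
different null sets may overlap one another, as real pathway
collections do; with 250 planted genes, 40 mutually disjoint null sets
of 50 would in any case not fit in a 2,000-gene universe.

What the generator does **not** emulate: correlated gene modules
outside the planted sets, per-chemical differences in study breadth,
dose–response structure, curation biases toward famous genes, or
directional coherence within pathways. Passing the planted-recovery
benchmark therefore demonstrates that the statistics recover rate
shifts of the stated size under heavy-tailed counts — not that real
pathway calls at these thresholds have the same operating
characteristics.

## Problem sizes and runtime choices

Unit tests run on universes of 4–2,000 genes. The exhaustive-oracle
check enumerates all subsets for $N \le 12$, set sizes $\le 3$, and
compares exact tail probabilities with 2,000-permutation estimates at a
3-standard-error band, requiring agreement on at least 95% of the 21
$(N, k)$ combinations; tail counts use a $10^{-9}$ relative epsilon
because the vectorized accumulator and the scalar oracle can disagree
by one ulp on exact ties. The recovery benchmark runs the full
pipeline over 20 generator seeds at 1,000 permutations (about two
minutes single-threaded) and requires every planted set called at
q ≤ 0.05 with the correct sign and at most 10% of all q ≤ 0.05 calls
being null sets. `scripts/acceptance.R` re-derives the same quantities
at five seeds.

## Known limitations

* Interaction counts conflate a gene's intrinsic responsiveness with
  its popularity as a study target; the package deliberately uses raw
  counts (no per-chemical or per-study normalization), matching the
  statistic it implements.
* The deduplication key uses taxon as the "biological model"; tissue or
  cell-line identity is not in the input schema, so two studies of
  different tissues in the same species and paper count once.
* FDR q-values are ratio estimators and can be noisy when few sets are
  tested; they are clipped and monotonized but not smoothed.
* Excel-workbook inputs are assumed converted to TSV upstream; the
  package's canonical interchange is UTF-8 TSV with a header row, which
  keeps artifacts diffable and byte-reproducible.
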