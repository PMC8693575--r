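---
title: "Methods: n-wise overlap enrichment and dictionary-learning itemset mining"
author: "multiOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: n-wise overlap enrichment and itemset mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiOverlap)
```

# The problem

Epigenomic features — transcription-factor binding sites, histone marks,
accessible chromatin — act in complexes of more than two components.
Given $k \ge 2$ sets of genomic regions (BED-style intervals), we ask, for
every *combination* $\gamma$ of sets (a subset of the $k$ set identities):
is $\gamma$ observed on more base pairs than expected if the sets were
positioned independently of one another?

Two measures describe a combination: $S(\gamma)$, the total number of base
pairs on which all of $\gamma$'s sets are simultaneously open, and
$N(\gamma)$, the number of contiguous windows carrying it. Enrichment is
the log2 fold change
$$m(\gamma) = \log_2 \frac{S_{obs}(\gamma)}{S_{exp}(\gamma)},$$
with $S_{exp}$ estimated by Monte Carlo shuffling under the null.

## Coordinates and merging

All user-facing coordinates are BED-standard 0-based half-open, so a region
$[500, 520)$ has length $20$ and $[500,520) \cap [520,530) = \varnothing$.
Internally a 1-based closed `GRanges` is stored. Every set is merged at
load time (overlapping or abutting regions fused) so that "set open" is a
plain boolean during the sweep; `readRegions(merge = FALSE)` exposes the
raw intervals for callers who need them, but all overlap and shuffling
operations require merged sets. Regions extending past their chromosome
end are an error, never silently clipped: clipping hides input mistakes.

# Finding the overlaps: sweep line

`sweepIntersections()` sorts the region starts and ends ("critical
points") of all sets per chromosome and accumulates a bit-coded open count
in one pass, emitting every maximal window where at least two sets are
open, with one open flag per set — the intersection matrix. Sorting makes
the cost $O(N \log N)$ in the total region count; the pass itself is
linear. At an identical coordinate, close events are processed before open
events, which is what makes abutting half-open intervals non-overlapping.
The per-base-pair brute-force scanner `bruteForceCounts()` (a completely
separate implementation over explicit position vectors and `rle`) and an
`IRanges::disjoin`-based computation serve as independent cross-checks in
the test suite; the sweep must agree with the scanner exactly on
randomized instances.

## Exact and transitive counting

Combinations are partially ordered: $\gamma_1$ is a *parent* of $\gamma_2$
when its sets are a strict subset of $\gamma_2$'s. *Exact* counting
credits a window only to the precise flag combination open on it.
*Transitive* counting (the default) also credits every window of a child
to its parents, fusing windows that become contiguous before counting
$N$ — so with $A = \{[100,200), [500,550)\}$, $B = \{[480,520)\}$ and
$C = \{[510,520)\}$, exact counting gives $S(A{+}B) = 10$ while transitive
counting gives $S(A{+}B) = 20$ with $N = 1$. Transitive labels carry a
trailing `+ ...` to signal that they stand for the combination and all its
children. The identity
$S_{trans}(\gamma) = \sum_{\gamma' \supseteq \gamma} S_{exact}(\gamma')$
is asserted on randomized instances in the tests.

# The null model

Each non-locked set is shuffled independently, per chromosome, by
permuting two series: the multiset of region lengths and the multiset of
inter-region gap lengths (including the two flanking gaps to the
chromosome ends; a chromosome with $m$ regions has $m + 1$ gaps, possibly
zero-length). The permuted series are laid out end to start. Both
multisets are exactly conserved, so regions are *not* uniformly
re-placed: the inter-region distance distribution of the input is part of
the null. The two series are permuted separately (not as one interleaved
series) — the plain reading of "permute the region lengths, but also the
inter-region lengths" — and this is a documented, deliberate choice.
Regions that abut after shuffling (a zero-length gap drawn between them)
are fused before counting, consistent with merged-set semantics.

Reproducibility: a master seed spawns one substream per (shuffle, set)
pair, so results are bit-identical for any batch size and set order.
Locking all sets degenerates the null (every shuffle reproduces the
observed data); the package warns and proceeds, because the no-op case is
a useful self-check (fold change 0, empirical p-value 1).

## Sub-genome restriction

When features can only plausibly occur in part of the genome (promoters,
enhancers, the merged candidate regions themselves), shuffling across the
whole genome overstates enrichment. `subgenomeRestrict()` concatenates the
inclusion regions into one pseudo-chromosome per source chromosome,
remaps all sets (discarding parts outside the inclusion blocks), and
returns the sub-genome `Seqinfo` so shuffling and counting happen entirely
inside it. Fragments of one region that land on adjoining blocks abut
across the seam and are fused — merged-set semantics in the concatenated
space — and the inverse mapping (`mapFromSubgenome()`) splits them back at
block boundaries, so retained base pairs are conserved in both directions.

# The statistical model

For each tracked combination the S (and N) shuffle samples are fitted with
a Negative Binomial by the *method of moments*:
$$p = \bar{x} / s^2, \qquad r = \bar{x}^2 / (s^2 - \bar{x}),$$
defined when the variance exceeds the mean (the convention matches
`stats::pnbinom`: mean $= r(1-p)/p$, variance $=$ mean$/p$). Maximum
likelihood is deliberately not used: moment fitting is more robust, and
with extreme tails a small likelihood difference would swing the p-value
by orders of magnitude. The p-value is the inclusive upper tail
$P(X \ge S_{obs})$ — enrichment only; a depletion column can be derived
from it. The default of 200 shuffles reflects that one to two hundred
samples give a stable moment fit.

Numerical edge cases never raise: an *underdispersed* sample (variance
$\le$ mean, where the NB is undefined) falls back to a Poisson tail with a
prominent flag, and an all-zero sample is *untestable* (the empirical
p-value is reported instead). The fold change uses a 1 bp pseudo-count
only when either term is zero, keeping $m(\gamma)$ finite
($\log_2\frac{S+1}{S_{exp}+1}$ in that case, the plain ratio otherwise).

## Goodness of fit

Each fit is scored with a Cramér's V statistic: samples and fitted-NB
probabilities are binned into shared quantile classes (at most 10 bins,
targeting $\ge 5$ expected counts per bin), and
$V = \sqrt{\chi^2 / (n \,(\text{bins}-1))}$. The verdict is `good` below a
threshold of 0.25. Both the binning and the threshold are package knobs —
documented settings, not claims about any external convention — and the
score is reported alongside the verdict so users can apply their own
cut. Poor fits arise mainly when a combination is too rare in the
shuffles; p-values are then conservative, while fold changes remain
accurate. Merged superbatches (`mergeRuns()`, which concatenates sample
arrays zero-padded over the union of combinations) do not re-assess fit:
their diagnostic column reads `not assessed`.

## Companion p-values

An empirical p-value $(1 + \#\{x \ge S_{obs}\})/(n+1)$ (add-one rule,
floored at $1/(n+1)$) is always reported. A Beta-distribution p-value is
also provided: samples are rescaled by the total bp of the analysed
(sub-)genome and a Beta is moment-fitted. With hundreds of shuffles the
Beta moments are imprecise, so the fit is flagged low-confidence below
1000 shuffles; it is the preferable model only with thousands of samples.
No multiple-testing correction is applied by default; an optional
Benjamini–Hochberg column is available (`bhColumn = TRUE`).

# The itemset miner

With $k$ sets up to $2^k$ combinations exist, and the most enriched are
not necessarily the most interesting (2 expected bp observed 2000 times is
very enriched and still rare). The miner selects $q$ representative
itemsets directly from the binary overlap matrix $X$ (one row per overlap
window, one 0/1 column per set) via sparse dictionary learning:
$$\min_{U,V} \tfrac{1}{2}\lVert X - UV\rVert_2^2 + \alpha \lVert U\rVert_1
\quad \text{s.t. } \lVert V_i\rVert_2 = 1,$$
where the rows of $V$ (atoms) are candidate itemsets and the usage of an
atom is the column sum of its coefficients in $U$. Matrix factorization
confers noise robustness: weak random flips do not create strong rank-one
structure, so planted complexes survive noise that breaks exhaustive
rule-based miners.

**Smothering.** The abundance of each distinct row pattern is first
reduced quadratically — a pattern with count $c$ is retained
$\lceil\sqrt{c}\rceil$ times, never dropped — so rare combinations are not
drowned out. The exact reduction rule is isolated in `smotherMatrix()` as
a documented reading of "quadratic reduction".

**Library creation.** Factorizations are repeated under the penalty
schedule $\alpha_1 = 1/k$, $\alpha_{i+1} = \alpha_i + (i+1)/k$; higher
penalties admit fewer, longer atoms. After each factorization, atoms with
positive total usage are binarized (items with weight $\ge 0.3$ of the
atom's maximum; a configurable threshold, since binary atoms are implied
rather than prescribed by the model) and added to the library,
deduplicated by membership. The schedule stops when total usage reaches
zero. Design choices made here: atoms per factorization default to
$\min(k, q+2)$ (capacity for $q$ complexes plus slack); codes and atoms
are constrained non-negative, because itemset memberships and usages have
no meaningful sign; and atoms are initialized at the most frequent
distinct row patterns of the smothered matrix, an informed and stable
starting point that makes the library far less sensitive to the
factorization's random draws than random initialization (remaining slots
and the symmetry-breaking jitter still come from the seeded RNG).

**Greedy selection.** Starting from an empty dictionary, each remaining
candidate is tentatively appended, $X$ (the raw matrix, not the smothered
one — selection should be judged on the data actually being explained) is
sparse-coded against the enlarged dictionary, and the candidate minimizing
$$d_1(X, \tilde{X}) = \lVert X - \tilde{X}\rVert_1 + \alpha \textstyle\sum U$$
is kept; the selection penalty defaults to $\alpha = 0.5/k$, decoupled
from the library schedule. Ties break toward the smaller membership, then
lexicographically — deterministic and biased toward parsimony. Because
atoms enter the coder as unit-$L_2$-norm indicator vectors, each atom's
squared weight sum is identically one, which is exactly the squared-sum
usage normalization that keeps broad atoms from dominating the ranking —
here folded into the model constraint rather than applied as a separate
correction. Redundant atoms (selecting $AB$ when $A$ and $B$ are present)
are allowed whenever they improve the rebuild, which is what lets the
miner report whole complexes. The greedy objective can only improve as
atoms are added (a new atom can always be ignored by the coder), and the
tests assert this monotonicity on every run. A custom selection-loss hook
is a natural extension point (e.g. supervised variable selection); it is
not implemented here.

# Synthetic data: what it does and does not emulate

`generateRegionSets()` places a query uniformly at random without
within-set overlap (order-statistics construction), then builds each
reference by copying a designed fraction of query regions — optionally
jittered by a uniform shift in $\pm j$ bp, a simple and analytically
tractable association model — and filling the remainder independently.
Defaults are the package's standard study conditions: a 10 Mb single
chromosome, 1000 regions of 100 bp per set, three independent references.
Under independence the expected pairwise overlap is $f_1 f_2 G$ bp (about
1000 bp at these settings), which the generator and the shuffler both
reproduce within Monte Carlo error in the tests.

`generateOverlapMatrix()` draws each row from one planted complex
(multinomial abundances) and flips every cell independently with the
noise rate. The standard fixture is three complexes — AB, ABCD, EF — over
$k = 6$ items, equal abundances, $m = 1000$ rows, chosen to exercise
overlapping complexes (AB $\subset$ ABCD) alongside a disjoint one.

What passing these tests does *not* show about real data: real peak sets
have heavy-tailed width distributions, chromosome-specific density, GC and
mappability biases, and spatially correlated noise, none of which the
generators emulate. The synthetic fixtures validate the algorithmic and
statistical machinery (counting identities, calibration under a true null,
recovery of planted structure), not biological generalization.

# Problem sizes and numerical settings

The test suite and the acceptance script run at desk scale, chosen so the
whole battery completes in minutes while still exercising every code
path: oracle equivalence on 100 randomized instances (up to 8 sets,
genomes up to 50 kb); null calibration on 4 independent sets of 1000
regions over 50 seeds at 200 shuffles each; miner recovery at $m = 1000$,
$k = 6$ with noise swept to 20%. Coordinate arithmetic is done in doubles
(exact for genomic magnitudes); set membership is bit-coded in integers,
capping $k$ at 30 — far above the ~20-set practical ceiling for this kind
of analysis. Coder and dictionary updates use coordinate descent with
tolerances of $10^{-7}$ and $10^{-5}$ respectively; a failed factorization
is retried once with a fresh substream and then skipped with a warning.

# Known limitations

* The NB null is asymptotic: with few regions per chromosome, sparse
  sub-genomes or very high-order combinations, fits degrade (the verdict
  column says so) and p-values become conservative.
* Transitive $N$ merges child windows a posteriori; $N$-based p-values
  mirror the S-based machinery and share its caveats.
* The miner is biased toward abundant combinations (smothering only
  partially compensates) and may return compromise atoms when $q$ is far
  from the true number of complexes; it is a pre-selection device, not an
  exhaustive miner — whatever it selects, the enrichment statistics of the
  selected combinations are unchanged.
* Within-set overlap structure (multiplicity above 1) is collapsed by
  merging; signal-level analysis is out of scope.

# A compact example

```{r example, eval = FALSE}
g <- genomeInfo(c(chr1 = 1e7))
sim <- generateRegionSets(genome = g, seed = 3,
    references = data.frame(name = c("B", "C"),
                            overlapFraction = c(0.5, 0), jitter = 0,
                            n = 1000L, length = 100L))
mc <- runMonteCarlo(sim$sets, g, queryIndex = 1,
                    config = shuffleConfig(nShuffles = 200, seed = 11))
res <- summarizeEnrichment(mc)
res[, c("combination", "S_obs", "S_exp_mean", "log2_fold_change", "p_nb_S")]
writeResultsTsv(res, "results.tsv")
writeDot(buildCombinationDag(res), "results.dot")
```
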