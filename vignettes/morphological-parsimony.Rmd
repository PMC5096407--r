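---
title: "Maximum parsimony on morphological matrices: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony on morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

The package analyses discrete morphological character matrices of sabellid
polychaetes (fan worms) under maximum parsimony. Its packaged data are a
26-taxon × 33-character matrix spanning *Pseudobranchiomma*, *Branchiomma*,
*Sabella*, *Sabellastarte*, *Stylomma* and *Bispira*, rooted with a
*Pseudopotamilla* terminal, and an 11-taxon reduction to the terminals with
DNA data. The headline question the analysis addresses is whether
*Pseudobranchiomma* is monophyletic: under equal-weights parsimony the genus
is not recovered as a clade, because *Branchiomma* falls inside it.

Everything the analysis scripts do — scoring, search, implied weighting,
resampling support, consensus, identification — is exposed as package
functions so each step can be tested in isolation and re-run on simulated
data.

# The optimality criteria

**Equal-weights parsimony.** For an unrooted binary tree $T$ and character
$i$, $s_i(T)$ is the minimum number of state changes needed to explain the
observed states on $T$, computed by the Fitch set-intersection pass for
unordered (non-additive) characters. Tree length is $TL = \sum_i s_i$; the
best trees minimise it. Fitch counts are root-invariant, so the package
searches unrooted and roots on the outgroup only for display.

**Implied weighting.** Each character has a minimum conceivable length
$m_i$ (its number of distinct determinately observed states minus one) and
extra steps $e_i = s_i - m_i$ on a given tree. The concave fit
$f_i = k/(k + e_i)$ rewards characters with little homoplasy; the search
maximises $F = \sum_i f_i$. Larger concavity constants $k$ weight more
gently; as $k \to \infty$ the ranking converges to equal weights (a tested
property). Internally the search minimises $\sum_i e_i/(k+e_i) = n - F$,
which orders trees identically.

**Homoplasy indices.** With $g_i$ the character's length on the worst
(star-equivalent) tree, the ensemble consistency index is
$CI = \sum m_i / \sum s_i$ and the retention index
$RI = (\sum g_i - \sum s_i)/(\sum g_i - \sum m_i)$.

# Cell semantics

Cells are `0`–`9` (determinate), `[01]` (polymorphic), `?` (missing), `-`
(inapplicable; the en dash is accepted on input) and `V` (recorded as
"variable" without an enumerated state span). For scoring, `?`, `-` and `V`
all carry the full set of states observed in their column, so they can
never add steps. No inapplicable-aware algorithm is used: the matrix
distinguishes `-` from `?` semantically, but the scoring treats both as
uncertainty, the convention of the standard software for non-additive
characters. The two documented readings of `V` (full uncertainty vs
polymorphism across the column's observed states) produce identical masks
under this engine, so the configuration switch affects only cell-kind
reporting and serialisation.

# Reporting conventions

Two conventions are needed to reproduce the published statistics of the
26-taxon matrix, and both are worth stating explicitly.

*Truncation.* On the packaged matrix an optimal tree gives
$CI = 37/69 = 0.536$ and $RI = 100/132 = 0.758$. The published values (0.53,
0.75) follow truncation, not rounding; `report_decimal()` implements both
and `diagnostics()` reports the truncated form alongside full precision.

*Informative-character accounting.* Eleven columns of the matrix are
uninformative in the strict textbook sense (at least two states each
observed in at least two taxa) — mostly autapomorphies of the outgroup.
The published analysis nevertheless counted all 33 characters as
parsimony-informative, and its CI is arithmetically the all-characters
ratio ($37/69$, not the strict-filter ratio $24/56 = 0.43$). The evident
operative notion was "variable" (at least two observed states).
`is_parsimony_informative()` therefore defaults to the strict rule but
offers `rule = "variable"`, and `diagnostics()` defaults its CI filter to
`"variable"` so that the reported values match the published accounting.
Users who want the textbook filter pass `informative = "strict"`.

# Search machinery

The default search is the classic two-phase heuristic: `replicates` random
addition sequences (greedy stepwise insertion in a seeded random taxon
order, first-best tie-break) each followed by branch swapping to a local
optimum, keeping up to `hold` equal-score trees per replicate; the pooled
optima are then swapped to closure — no neighbour improves the score or
adds a new optimal topology. TBR neighbourhoods are scored by a compiled
sweep that bisects every branch, computes directional Fitch state sets for
every attachment edge of the two components, and prices each reconnection
in one pass per character; NNI and SPR use the R neighbourhood generators
(`swap_neighbors()`), which also serve as the reference implementation the
compiled sweep is tested against. An exact branch-and-bound
(`branch_and_bound()`, up to 12 taxa) and full topology enumeration
(`enumerate_topologies()`, up to 9 taxa) provide oracles.

The default budget of 200 addition replicates is the package's desk-scale
choice: on the 26-taxon matrix every tested seed reaches the optimum well
before 200 replicates, and the published protocol's 10,000 replicates add
nothing but runtime here. The parsimony ratchet (`ratchet_search()`)
alternates swapping under perturbed character weights (a seeded fraction
upweighted) with re-optimisation under original weights, never returning a
worse score than the plain search it starts from; it is the escape hatch
for datasets with genuine composite optima. "Drift" and "tree fusing" from
the same software family are not implemented; the source reports they found
the same optima.

**Counting optimal trees.** Distinct-optimum counts depend on a collapsing
convention. The package collapses every internal branch whose minimum
possible length over all minimum-change reconstructions is zero — decided
exactly, per character, by a two-pass unit-cost Sankoff dynamic programme
(`collapse_zero_branches()`), validated in the tests against brute-force
enumeration of optimal reconstructions. Two subtleties follow. First,
during the search the pool is deduplicated by collapsed topology: the
26-taxon matrix has over a thousand distinct binary resolutions of its six
collapsed optima, and holding one representative per collapsed class keeps
the search fast without changing the count. Second, branches that can
individually be zero cannot always all be zero at once, so a collapsed
tree's hard-polytomy length may exceed the binary optimum; the binary
representatives (`binary_trees`) are the objects that rescore exactly to
`best_score`, while the collapsed trees are display/counting objects. With
`collapse = "none"` the pool is deduplicated by binary topology instead.

**Ties and determinism.** All scores are doubles compared with an absolute
tolerance of $10^{-7}$ (integer-valued under equal weights; implied-weight
fits are sums of small rationals, far coarser than the tolerance). Every
stochastic entry point takes a seed and restores the caller's RNG state;
identical inputs and seeds give identical results, a tested contract.

# Implied weighting on the packaged matrix

At $k = 7$–$8$ the fit-optimal trees are three of the six equal-weights
most-parsimonious trees, matching the published account. At $k = 3$–$6$
this implementation finds a *better-fitting* family than the equal-weights
optima: seven distinct collapsed trees of length 70 whose fit (e.g.
$F = 27.258$ at $k = 3$) strictly exceeds the best fit attainable by any
length-69 tree ($27.204$). The published count of "six" trees for
$k = 3$–$6$ matches the fit-suboptimal equal-weights optimum set, which
suggests the original runs stopped on that island. The package reports what
the criterion actually optimises; the discrepancy is flagged in the
implied-weighting run report and left visible in the acceptance suite
rather than papered over.

# Jackknife support

`jackknife()` deletes each character independently with probability
`p_del` per replicate, re-searches the reduced matrix, and lets each
replicate contribute the bipartitions common to all of its optimal trees;
support is the percentage of replicates containing a bipartition. The
deletion probability defaults to 0.36, the common independent-removal
convention near $1/e$; the source analyses do not state theirs, so the
value is explicit configuration echoed in reports. Per-replicate search
budgets are reduced (20 addition replicates, small tree pool) — a
replicate's contribution is its consensus splits, which saturate long
before the optimum plateau is fully enumerated. Supports are mapped onto
the full-data strict consensus for display, with labels shown at or above
a threshold (default 50).

# The synthetic-data generator

`simulate_matrix()` evolves each character independently down a known
binary tree under a symmetric (Mk) transition model with uniform root
state, equal exchange rates and unit branch lengths; `rate` is the expected
number of substitutions per branch. Afterwards cells are masked to `?` or
`-` at configured fractions. The generator emulates the statistical shape
of the empirical matrix — unordered characters with 2–4 states, missing and
inapplicable cells — and `random_tree()` draws topologies uniformly by
sequential random attachment (a tested distributional property).

What the generator does **not** emulate: hierarchical inapplicability
(masking is random because the engine scores `-` as uncertainty, so
controlling-character structure would be untestable), rate heterogeneity
across branches or characters, and correlated characters. Passing recovery
tests therefore show that the pipeline is a consistent estimator under its
own generative assumptions, not that real morphological data meet those
assumptions.

One operating characteristic matters when designing recovery experiments:
binary characters produce *exact ties* — parallel changes on different
branches can support conflicting resolutions with identical step counts —
so even with abundant low-rate binary data the strict consensus of the
optimum set retains occasional polytomies and strict topology recovery
plateaus below certainty. With three or four states per character
(within the empirical matrix's range) such ties are rare and recovery
approaches 100% as characters accumulate. The validation suite's recovery
experiment accordingly uses three-state characters at rate 0.05 with 200
characters on 12 taxa; the simulation-check script prints the rates it
achieves.

# Problem sizes used by the validation suite

The suite favours exhaustive small-scale oracles over large stochastic
runs: Fitch scoring is checked against brute-force ancestral-state
minimisation on all 105 six-taxon topologies for every matrix column;
search correctness against full enumeration on seven taxa (945 topologies)
and branch and bound; the collapse rule against enumeration of optimal
reconstructions on six taxa; uniformity of random topologies by a
chi-square test at $n = 4$ over 3,000 draws. The main-search budget in the
analysis scripts (200 replicates), jackknife budget (200 replicates of 5
additions) and recovery experiment (40 seeds) are the package's desk-scale
choices and are echoed in every run report.

# Known limitations

* Inapplicable states are scored as uncertainty; no coherent
  inapplicable-aware method (e.g. explicit controlling characters) is
  implemented.
* Sankoff cost matrices, ordered (additive) characters, successive
  approximations weighting, Bremer support and bootstrap resampling are out
  of scope.
* The identification key fixture repairs a structurally inconsistent
  printed numbering; the repairs are enumerated in the fixture's
  `provenance_notes` and two leads are editorial rather than transcribed.
* Collapsed-optimum counts are convention-dependent; run reports flag the
  convention whenever a count is reported.
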