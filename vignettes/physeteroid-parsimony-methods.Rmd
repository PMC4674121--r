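---
title: "Parsimony, support, and body-size methods in cachalot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony, support, and body-size methods in cachalot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cachalot` packages the analysis chain used to place a fragmentary fossil
sperm whale in the physeteroid tree and to estimate its body size from a
partial rostrum: maximum parsimony on a discrete morphological matrix,
clade support, squared-change-parsimony mapping of a continuous size proxy,
and a two-method allometric regression pipeline. This vignette describes
the models, the numerical choices, and what the shipped synthetic data do
and do not demonstrate.

## Character matrices and their ambiguities

A morphological matrix is a taxa-by-characters grid of *state sets*
(`characterMatrix()`), held as integer bitmasks. Three notations are
routine in paleontological matrices, and all collapse to set semantics:

* a single digit — a singleton set;
* `{01}`, `(01)` or `0/1` — a polymorphic/uncertain cell, read as the set
  \{0,1\};
* `?` — a missing cell, read as the full symbol set.

**Design choice: polymorphism as uncertainty.** A polymorphic tip may adopt
any listed state at zero cost inside the tree. This is the standard Fitch
treatment; the alternative ("true" polymorphism, charging for the extra
state) is a different optimality model and is out of scope. The choice is
fixed and documented rather than configurable because every downstream
statistic (length, CI, RI, support) depends on it.

Taxon labels compare with underscores and spaces interchangeable, the usual
NEXUS convention. The writer emits one canonical dialect (curly-brace
polymorphism, `?`, no interleaving) so that write–read round trips are
identity; the reader is tolerant about case, whitespace, and comments.

## Minimum-change scoring

For unordered characters the parsimony length of a tree is the minimum
number of state changes over all labelings of internal nodes. `cachalot`
scores with the max-count recursion: at each internal node, count how many
child state-sets contain each state, keep the states attaining the maximum
*c*, and add (number of children − *c*) steps. On binary trees this is
exactly the classic intersection/union rule; on multifurcations it still
returns the exact minimum, which matters because consensus trees contain
polytomies. Scoring treats the edge list as undirected and roots itself
anywhere, so the score is root-invariant by construction; the test suite
verifies both properties against an exhaustive labeling oracle.

Per-character extremes use closed forms: the best case over all trees is
(size of the smallest state set hitting every scoreable cell) − 1, found by
subset enumeration over the ≤ 10 symbols; the worst case is (number of
scoreable cells) − (largest attainable single-state frequency), with
polymorphic cells resolved in favour of the dominant state and missing
cells ignored. These feed the ensemble consistency index CI = Σmin/L and
retention index RI = (Σmax − L)/(Σmax − Σmin). **Convention:** characters
that cannot show homoplasy (constant columns, autapomorphies) are included
in the sums by default, matching the default of the standard parsimony
programs; `includeUninformative = FALSE` excludes them. A zero-length tree
has CI = RI = 1 by convention, and RI is defined as 1 when Σmax = Σmin.

## Heuristic search

Starting trees are random addition sequences: taxa are inserted in random
order at the attachment point minimizing the incremental length, ties
broken uniformly at random. Each start is refined by
tree-bisection-reconnection (TBR): cut any edge, suppress the freed
degree-two node on each fragment, and rejoin any edge (or the lone leaf) of
one fragment to any edge of the other. By default the climb accepts the
first shorter neighbor (a steepest-descent scan is available;
`steepestDescent = TRUE`); both stop at a local optimum.

**Plateau handling.** Equally short trees matter (the consensus and the
shortest-tree count depend on them), so after the replicates the tied set
is closed under TBR at constant length: every equal-length neighbor of a
retained tree is retained and swapped in turn, up to `maxTrees` (default
10,000; exceeding it flags the result truncated). On all ≤ 7-taxon random
instances tried, this closure provably recovers the complete set of
shortest trees (exhaustive enumeration in the tests).

**Branch collapse.** Shortest-tree counts depend on whether branches with
no required change are collapsed. `collapseZeroLengthBranches()` contracts
every internal branch whose contraction leaves the length unchanged, and
counts are reported under both conventions, because the convention used by
any particular published count is rarely stated.

**A note on TBR neighborhoods.** One bisection-reconnection cannot
exchange both cherries of a five-leaf tree at once: the 5-leaf
neighborhood has 12 distinct topologies, not 14, and the two unreachable
trees are exactly those sharing no bipartition with the source. Both the
compiled enumerator and an independent naive rearranger agree on this; the
hill climb is unaffected (those trees are reachable in two moves).

Seeds are mandatory for all stochastic operations and recorded in the
per-replicate log, which also tracks start length, end length and
rearrangements tried.

## Clade support

*Bootstrap.* Each replicate resamples characters with replacement, reruns
the search at reduced effort (default 10 addition replicates; the plateau
cap is lowered to 100 trees per replicate for runtime), and records the
clades of the replicate's strict consensus of shortest trees — one vote per
replicate per clade, not one per tied tree, a convention that differs
between programs and is therefore stated here. Support is the percentage
of replicates containing the clade; a majority-rule tree carries the values
as node labels.

*Bremer decay.* For k = 1..kMax the shortest-tree set is closed under TBR
within length best + k, and a clade's decay index is the smallest k at
which it drops from the strict consensus of that pool; clades surviving at
kMax report `Inf` ("> kMax"). The retention is heuristic; on ≤ 7 taxa it
matches exhaustive enumeration (tested), and beyond that it inherits the
usual caveat that suboptimal-tree sets found heuristically may be
incomplete.

## Squared-change parsimony

Condylobasal length (a standard cetacean body-size proxy) is mapped onto
the consensus by minimizing the sum of squared changes along edges, all
edges weighted 1 — the unweighted variant, appropriate because a consensus
tree carries no branch lengths. Tips are fixed at their values; the unique
minimizer satisfies the mean-of-neighbors condition at every internal node
and is obtained by a direct solve of the (symmetric positive-definite)
normal equations. Iterative local averaging and a generic quadratic
minimizer serve as oracles in the tests, which also verify
affine-equivariance and polytomy handling. The reconstruction runs on the
rooted display tree (rooted on the outgroup branch when present); the root
value is reported but is root-placement-dependent, and is flagged as such
in interpretation. Binning for display uses equal-width classes over the
range of all node values (left-closed, last bin right-closed; degenerate
range → one bin), default 6 classes.

Either condylobasal length or a derived total length can be mapped; CBL is
the default input since it is the measured quantity and total length is an
extrapolation from it.

## The two-method body-size pipeline

Both methods are bivariate OLS regressions (via `stats::lm`) on antorbital
notch width (AON), the one cranial width measurable on rostrum-only
specimens. Where only one side of the notch survives, the half-width is
doubled (`deriveAON()`), explicitly a *minimum* estimate. With the
published coefficient pairs (all cm):

* Method 1 (lower bound): CBL = 2.51·AON + 2.84; TL = 3.4·CBL + 161.
* Method 2 (upper bound, rostrum-corrected): CBL − RL = 0.634·AON + 31.2,
  so CBL = fit + rostrum length; TL − CBL = 6.33·AON + 31.2, so
  TL = fit + CBL.

Unrounded values flow through every composition; rounding to 0.1 cm
happens only at report time. This matters at the last digit: the Method-1
total length matches its published value only when the *unrounded* CBL
feeds the second equation.

**Known inconsistency.** The printed Method-2 total-length equation does
not reproduce its published worked value (it yields 488.3 cm, below the
Method-1 value, rather than the published 627.1 cm). The package
implements the equation exactly as printed, exposes all coefficients as
arguments, and treats the 627.1 figure as unverifiable rather than
adjusting any coefficient to force agreement. A related consequence: the
four relationships cannot all hold exactly on one dataset — (TL − CBL) ~ AON
is linearly determined by the other three — so the noise-free generator
reproduces three pairs exactly and the fourth as its composition
(slope 2.4 × 2.51 = 6.024, intercept 2.4 × 2.84 + 161 = 167.816).

`pipelineFromData()` refits all four regressions from a reference table
(AON, CBL, RL, TL per specimen; TL typically present only for extant taxa),
dropping incomplete rows per regression and failing loudly when fewer than
three usable rows remain.

## Synthetic data: what it emulates, what it does not

No machine-readable deposit exists for the study matrix or the reference
measurement set, so the package generates stand-ins and labels them as
such.

*Characters:* a symmetric Mk process — uniform root state, per-edge change
probability `rate`, uniform choice among alternative states — with missing
cells and polymorphic cells (true state ∪ one random other) injected at
configured rates. The shipped 21 × 43 stand-in uses rate 0.08, 25%
missing, 2% polymorphic on a plausible physeteroid topology (seed
20150923), chosen once to mirror the real matrix's coarse texture (about
2–3 steps per character, heavy fossil missingness). The Mk model makes no
claim about how real morphology evolves: no rate heterogeneity, no
correlated characters, no acquisition bias. Passing tests on such data
show the *algorithms* are correct, not that the published numbers are
reproduced — tree statistics from the stand-in (length 110, CI 0.664,
RI 0.706, ingroup bootstrap ≈ 43%) differ from the published ones
(length 100, CI 0.585, RI 0.715, bootstrap 85) precisely because the real
matrix could not be transcribed.

*Allometry:* AON uniform on 10–200 cm (pygmy sperm whale to sperm whale
scale), responses generated from the published coefficient pairs plus
Gaussian noise (default sd 15 cm, set once as a realistic cranial-regression
scatter), 36 specimens as in the reference dataset.

One calibration in the test suite deserves a note: the topology-recovery
check ("low rate → ≥ 95% of 100 seeds recover the generating tree") uses a
per-edge rate of 0.02. At higher rates the misses are, demonstrably,
datasets on which the generating tree is strictly longer than the optimum
— unrecoverable by any correct search — so "low rate" is implemented as a
rate at which the generating tree is an MPT in almost all draws; the
search itself located the optimum in every diagnostic run.

## Numerical and degenerate-input choices

* State codes are 0–9 (bitmask representation); symbols beyond a matrix's
  declared set are parse errors naming the taxon and line.
* Scoring uses an early-exit bound in search loops (a neighbor's scoring
  stops as soon as it exceeds the incumbent), which changes nothing about
  results, only runtime.
* Ties in random addition are broken by the seeded RNG; all generators are
  pure functions of (config, seed).
* Degenerate inputs: a constant matrix scores length 0 with CI = RI = 1;
  a star tree is scored correctly (one polytomy); an empty stratigraphic
  range table annotates nothing and returns the tree unchanged; a
  degenerate trait range bins every node to class 1.
* Problem sizes in the test suite (≤ 8 taxa for labeling oracles, ≤ 7 for
  exhaustive topology enumeration, 100 addition replicates on the 21-taxon
  stand-in, 100 bootstrap replicates at 10 addition replicates each) were
  chosen so the oracles are exact and the whole suite completes in minutes
  on a single core.

## Limitations

Ordered or weighted (Sankoff) characters, implied weighting, ratchet
searches, likelihood/Bayesian inference, branch-length-weighted
squared-change parsimony, ML/REML Brownian ancestral states, and
phylogenetically corrected (PGLS) allometry are all out of scope. Searches
are heuristic above 7 taxa; suboptimal-tree pools (Bremer) and bootstrap
consensus sets are capped and may be incomplete on very flat tree-length
plateaus; and every number computed from the shipped stand-in data
characterizes the stand-in, not the published specimen tables.
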