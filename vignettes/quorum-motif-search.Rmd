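---
title: "Exact quorum planted motif search: models, algorithms, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact quorum planted motif search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumotif)
```

## The problem

Transcription factors bind short, degenerate sites. The combinatorial
abstraction used throughout this package is the *quorum planted (l,d)-motif*:
given `n` sequences over a fixed alphabet, an l-mer `t` is an (l,d)-motif at
quorum `q` if at least `q` sequences contain a window within Hamming distance
`d` of `t`. With `q = n` this is the classic planted motif search (PMS)
problem; allowing `q < n` models the realistic situation where some promoters
in a co-regulated set simply lack the site. The search is exact: *every*
motif satisfying the definition is reported, which is what distinguishes this
family of algorithms from profile/EM heuristics (MEME, Gibbs samplers). The
price is worst-case exponential time — the problem is NP-hard — so all the
engineering goes into pruning.

## The search engines

All four engines provably return the same motif set; they differ only in how
much of the candidate space they touch.

**Brute force** (`algorithm = "brute"`) tests candidates directly against
the definition, either all `sigma^l` l-mers or (exactly equivalent, by the
pivot observation below) the union of d-balls around the windows of the
first `n - q + 1` sequences. It exists as the in-package oracle: every other
engine is tested against it.

**Single-pivot branch and bound** (`"qpmsprune"`). Any motif must lie in the
d-ball of one of its instances, and at least one instance must occur in the
first `n - q + 1` sequences. For each window `x` of those sequences the
d-ball `B_d(x)` is organised as a *mutation tree*: the root is `x`, and a
child mutates exactly one position to the right of its parent's last mutated
position, so each ball member appears exactly once and node depth equals
distance from `x`. During a depth-first traversal the engine maintains, for
every other sequence, the minimum window distance to the current node `t`,
updated incrementally (one character comparison per window per mutation).
A node is emitted when at least `q - 1` other sequences are within `d`.
A subtree is pruned when fewer than `q - 1` other sequences are within
`2d - depth`: any descendant `t'` satisfies
`h(t', s_j) >= h(t, s_j) - (d - depth)`, so by the triangle inequality no
descendant can reach the quorum — pruning is lossless.

**Surviving-window lists** (`"qpmspruneI"`). At a node `(t, p)` at depth
`depth`, descendants can alter only positions beyond `p`, in at most
`d - depth` places. The closest any descendant can get to a window `y` is
therefore

    a + max(0, b - (d - depth))

with `a` the prefix (positions `1..p`) and `b` the suffix mismatch count of
`t` versus `y`. When this exceeds `d`, window `y` is dead for the entire
subtree and is dropped from the sequence's *surviving list*; an empty list
marks the sequence unreachable. Lists only shrink along a root-to-leaf path
(and are restored on backtrack), so deep nodes — of which there are
exponentially many — touch very few windows. The package asserts, as a
tested invariant, that this mode never changes the output and never performs
more incremental distance updates than the plain mode.

**Two pivots** (`"qpms7"`). The same coverage argument applied twice: a
motif has instances in two distinct sequences among the first `n - q + 2`.
For every window pair `(x, y)` from two such sequences with
`h(x, y) <= 2d` (otherwise `B_d(x)` and `B_d(y)` are disjoint and the pair
is skipped), the engine traverses the mutation tree of `x` restricted to
nodes whose subtree can still reach `B_d(y)` — the same minimum-descendant-
distance bound, applied to `y`. Emission requires the node within `d` of
*both* pivots plus `q - 2` further sequences. The surviving-window rule
becomes a three-ball feasibility question on the suffix: window `w` stays
alive at node `(t, p)` exactly when some completion of the suffix lies
simultaneously within `d - depth` of `t`'s suffix, within `d - a_w` of `w`'s
suffix, and within `d - a_y` of `y`'s suffix (prefix mismatch counts `a_w`,
`a_y` already being committed). Backtracking triggers when fewer than
`q - 2` surviving lists are non-empty.

### Three-ball feasibility

Whether three Hamming balls intersect is decided exactly by a small dynamic
program over positions: the state is the pair of mismatch counts committed
against the first two centers, the value the minimum mismatches against the
third; per-column choices are the column's distinct characters plus, when
the alphabet is larger than the set of distinct column characters, an
"other" character that mismatches all three. This runs in
`O(L * d^2)` per test. A constant-time closed-form case analysis of the
per-column patterns exists, but the DP is chosen deliberately: it is exact
for every alphabet size `sigma >= 2` (including the binary edge case where
an "other" character may not exist), and it is small enough to verify
against exhaustive search over all `sigma^L` strings — which the test suite
does, for every radius triple on a thousand random center triples. Speed is
adequate: the test sits behind two O(1) screens (negative radius, two-ball
disjointness) that reject the vast majority of windows first.

### The 2d preprocessing filter

Two instances of one motif are within `2d` of each other. A window with
fewer than `q - 1` other sequences holding a window within `2d` therefore
cannot be an instance of any reportable motif, and is removed from pivot
candidacy and from initial surviving lists (`filter = TRUE`; the default
for qPMS7). Removed windows can never witness a reportable motif either —
every witness set of a reported motif spans `q` sequences whose instance
windows mutually support each other — so the filter is lossless, which the
equivalence suite checks by running every engine with the filter both off
and on.

### Determinism and tie-breaking

Children of a tree node are explored in increasing mutated position, then
alphabet order; pivot windows in increasing offset; pivot sequence pairs in
increasing index order. Results are deduplicated into a set and reported in
lexicographic order. Identical inputs yield byte-identical outputs.

## The planted-instance generator

`generate_planted_instance()` reproduces the standard benchmark
construction: `n` background strings drawn i.i.d. (uniform by default, an
arbitrary frequency vector optionally), a uniform random l-mer as the
ground-truth motif, and a mutated copy overwritten at a uniform random
offset in each of `q` distinct sequences. Defaults are the benchmark shape
`n = 20`, `m = 600`. Two mutation modes exist because "mutated in at most
`d` positions" leaves the exact count open: the default `exact-d` plants
copies at the very edge of the ball (the hardest, "challenging-instance"
placement, and the convention of the benchmark literature); `up-to-d` draws
the count uniformly from `0..d`. One plant per chosen sequence, overwriting
background, so overlap pathologies cannot arise. Instances are reproducible
from a single integer seed via R's default Mersenne-Twister generator, with
the caller's RNG state left untouched.

What the simulator deliberately does *not* emulate: positional bias of real
binding sites, compositional bias and repeats of real promoters, correlated
mutations, or sites described by weight matrices rather than a consensus
with a mismatch budget. Passing tests on simulated data therefore
demonstrate algorithmic correctness of the exact search, not biological
sensitivity on real promoter collections.

`challenging_presets()` records the standard (l, d) ladders at which
benchmark instances become challenging — DNA: (13,4)…(23,9) at `q = n` and
(13,3)…(21,7) at `q = n/2`; protein: (11,5)…(19,9) and (11,4)…(19,8).
They are provided as data, not as a runtime promise: an interpreted-glue
implementation on one desktop CPU is validated here at a scaled-down shape
((11,3) at `q = 20` and (9,2) at `q = 10`, both at `n = 20`, `m = 600`,
chosen to finish in minutes), while the upper rungs of the ladders are the
domain of long-running dedicated runs.

## Binding-site discovery (two phases)

Phase I (`phase1_select()`) scans a grid: for each motif length `l` from
`l_min` to `l_max` it raises `d` from 0 until the search returns something,
tags the motifs with the `(l, d)` they were found at, and moves to the next
`l`; a run exceeding its time budget is abandoned (budget exhaustion is a
logged, non-fatal event — the scan simply moves on). Phase II
(`phase2_sites()`) ranks candidates by *sequence specificity* and reports,
for the top `k_top` motifs, every window within `d_site` mismatches as a
binding site.

Sequence specificity ranks a motif by how often it would match by chance:
`E_i` is the expected number of windows of string `i` within `d` mismatches
under an i.i.d. background — `(m_i - l + 1) * P(X <= d)` where `X` is
Poisson-binomial with per-position match probability equal to the background
frequency of the motif character (computed by an exact `O(l*d)` tail DP, and
cross-checked against Monte-Carlo simulation in the tests). The per-sequence
expectations combine multiplicatively; the package scores
`sum_i log(E_i)` and ranks ascending, which is monotone-equivalent to the
product and numerically safe for long sequence sets. Ties are broken
lexicographically so Phase II output is reproducible.

Defaults and their reasons: `l_min = 10`, `l_max = 20` covers the length
range of well-characterised eukaryotic TFBS consensus motifs;
`d_max(l) = ceiling(l/4)` lets the mismatch budget grow with length the way
the challenging-instance ladders do; `k_top = 5` keeps the report focused on
the specificity winners; `d_site` defaults to the `d` the motif was found at
(a site is an instance under the motif's own model); the scoring background
defaults to frequencies estimated from the input (real promoter sets are
GC-biased; a uniform background is one switch away). All are user-visible
parameters, and all are choices of this package rather than community
constants.

## Numerical and engineering choices

* **Coordinates** are 0-based half-open everywhere in machine-readable
  output; file headers say so.
* **Encoding**: sequences are mapped to integer codes once at the border;
  mismatch tests are code comparisons, independent of alphabet size.
  Characters outside the alphabet (e.g. `N`) get a sentinel code; every
  window covering one is ineligible as a pivot, a candidate instance or a
  match witness, and `strict = TRUE` refuses such sequences outright.
* **Counters**: each engine reports nodes visited, subtrees pruned and
  incremental distance updates. The update counter is the denominator of
  the surviving-list work-dominance invariant; the counters are also how
  the tests pin traversal behaviour without timing anything.
* **Time budgets** are wall-clock checks every 4096 nodes inside the
  compiled core; a run that exceeds its budget returns what it has, flagged
  `timed_out`, and Phase I treats that as "move on to the next length".
* **Guards**: brute force refuses full enumeration beyond a candidate cap
  (default `4^10`) unless asked to use the union-of-balls generator, which
  handles protein-sized alphabets; degenerate inputs (`q > n`, `d >= l`,
  `l` longer than the shortest sequence) fail fast with classed errors the
  command-line wrapper maps to distinct exit codes.

## Problem sizes used in the shipped checks

The test suite validates oracle equivalence on 200 randomized instances
(DNA: `l` 5–9, `d` 1–2, `n` 4–8, `m` 20–60, quorum `n`, `n-1` or `n-2`;
protein: `l` 4–6, `d` 1), neighborhood enumeration exhaustively for every
DNA center up to `l = 6`, three-ball feasibility against exhaustive search
on 1000 random center triples for all radius triples, and planted recovery
at the benchmark shape (`n = 20`, `m = 600`) at (11,3, q=20) and
(9,2, q=10). These sizes are chosen so the whole suite runs in minutes on
one CPU while still exercising every code path at full combinatorial
density.

## Known limitations

* Single-strand search only: no reverse-complement awareness and no
  IUPAC-degenerate or gapped motifs.
* The two-pivot idea generalises to more pivots; this implementation stops
  at two.
* Runtime grows steeply along the challenging ladders; the upper rungs
  ((17,6)+ DNA at `q = n`) are not realistic for this build on one desktop
  core.
* The specificity score models chance occurrence under an i.i.d.
  background; it does not provide a significance test for site counts, and
  repeats or compositional structure in real promoters will inflate
  apparent matches.

## A worked call

```{r example}
inst <- generate_planted_instance(n = 8, m = 120, l = 9, d = 2, q = 6,
                                  seed = 7)
inst$motif
fit <- pms_search(inst$seqs, l = 9, d = 2, q = 6, algorithm = "qpms7")
tidy(fit)
glance(fit)
```

The planted motif is recovered together with any other l-mer that happens to
satisfy the quorum, each with its support recomputed over all `n`
sequences.
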