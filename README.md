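# quorumotif

Exact search for **quorum planted (l,d)-motifs** in DNA and protein
sequences, with a planted-instance benchmark simulator and a two-phase
transcription-factor-binding-site discovery workflow.

## The problem

Given `n` sequences over one alphabet, an l-mer `t` is an *(l,d)-motif at
quorum q* if at least `q` of the sequences contain a window `w` with
Hamming distance `H(t, w) <= d`. With `q = n` this is the classic Planted
Motif Search (PMS); `q < n` (qPMS) models co-regulated promoter sets in
which some sequences lack the binding site. The search here is **exact**:
every l-mer satisfying the definition is reported, unlike profile/EM
heuristics that may miss weak motifs. The package is aimed at people who
study regulatory sequence — or who study the algorithms themselves — and
want a tested, scriptable implementation with a defensible answer set.

Four interchangeable engines produce identical motif sets:

| engine | idea |
|---|---|
| `brute` | test candidates against the definition (oracle) |
| `qpmsprune` | single-pivot DFS over the mutation tree of each window, triangle-inequality pruning (`< q-1` sequences within `2d - depth`) |
| `qpmspruneI` | same, plus per-sequence *surviving-window lists*: a window is dropped once `a + max(0, b - (d - depth)) > d` (prefix/suffix mismatches vs. the node) |
| `qpms7` | two pivot windows `x, y` with `H(x,y) <= 2d`; traversal restricted to nodes that can still reach `B_d(y)`; windows survive under an exact three-Hamming-ball intersection test |

A lossless preprocessing filter removes windows with fewer than `q - 1`
other sequences holding a window within `2d`. The compute cores are C++
(Rcpp); the user surface is tibble-first R with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Plant a motif and find it again:

```r
library(quorumotif)

inst <- generate_planted_instance(n = 8, m = 120, l = 9, d = 2, q = 6,
                                  seed = 7)
inst$motif
#> [1] "GTATACTGG"

fit <- pms_search(inst$seqs, l = 9, d = 2, q = 6, algorithm = "qpms7")
tidy(fit)
#> # A tibble: 48 × 5
#>    motif         l     d     q support
#>    <chr>     <int> <int> <int>   <int>
#>  1 AAACCGACA     9     2     6       6
#>  2 AACCGTCAG     9     2     6       6
#>  3 ACAAACTGA     9     2     6       6
#> # … 45 more rows (including GTATACTGG)

glance(fit)
#>   algorithm l d q n filter n_motifs timed_out nodes_visited nodes_pruned
#> 1     qpms7 9 2 6 8   TRUE       48     FALSE         16202        13504
#>   distance_updates pivot_pairs
#> 1           103717        3596
```

The planted 9-mer is recovered along with 47 spurious l-mers that genuinely
satisfy the (9,2) quorum-6 definition on this instance — at these parameters
random 120-mers already harbour chance motifs, which is exactly why the
benchmark literature grades parameter pairs as "challenging". `support` is
the number of sequences with a window within `d`, recomputed over all `n`.
Per-sequence evidence for one motif:

```r
assemble_report(inst$seqs, inst$motif, d = 2, q = 6)
#> # A tibble: 8 × 4
#>   motif     id    distance offsets
#>   <chr>     <chr>    <int> <list>
#> 1 GTATACTGG seq1         2 <int [2]>
#> 2 GTATACTGG seq2         2 <int [1]>
#> ...
```

(`seq6` sits at distance 3: only 6 of the 8 sequences received a plant.)

Binding-site discovery on a FASTA file, from the shell:

```sh
Rscript inst/cli/qpms.R simulate -l 11 -d 2 -n 20 -m 600 --seed 5 -o demo.fa
Rscript inst/cli/qpms.R search -i demo.fa -l 11 -d 2 -o motifs.tsv -v
Rscript inst/cli/qpms.R tfbs -i demo.fa --l-min 10 --l-max 12 -o sites.tsv
```

All machine output is TSV with a self-describing `#` header; coordinates
are 0-based half-open.

## Layout

* `R/`, `src/` — tibble-first surface over the C++ search cores
* `vignettes/quorum-motif-search.Rmd` — the models, the pruning math, and
  every tunable default with its rationale
* `inst/cli/qpms.R` — `search` / `simulate` / `tfbs` subcommands
* `tests/testthat/` — oracle-based unit tests and the acceptance suite
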