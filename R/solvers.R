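#' Exact quorum planted (l,d)-motif search
#'
#' Finds every l-mer `t` such that at least `q` of the `n` input sequences
#' contain a window within Hamming distance `d` of `t`. Four exact engines
#' are available:
#'
#' * `"brute"` — enumeration oracle: tests every candidate l-mer, either the
#'   whole `sigma^l` space or the union of d-balls around the windows of the
#'   first `n - q + 1` sequences (both exact; see `brute_mode`).
#' * `"qpmsprune"` — single-pivot branch and bound: for each window `x` of
#'   each of the first `n - q + 1` sequences, a depth-first traversal of the
#'   mutation tree of `x`, with incremental window distances, emission when
#'   `q - 1` other sequences are within `d`, and triangle-inequality pruning
#'   when fewer than `q - 1` are within `2d - depth`.
#' * `"qpmspruneI"` — the same search with per-sequence surviving-window
#'   lists: a window is dropped as soon as no descendant of the current node
#'   can be within `d` of it, so deeper nodes touch ever fewer windows. The
#'   output is identical; only the work differs.
#' * `"qpms7"` — two-pivot search: for every pair of windows `x`, `y` from
#'   two of the first `n - q + 2` sequences with `hamming(x, y) <= 2d`, a
#'   traversal of the mutation tree of `x` restricted to nodes that can still
#'   reach the d-ball of `y`; windows survive under an exact three-ball
#'   intersection test and emission requires both pivots within `d` plus
#'   `q - 2` further sequences.
#'
#' A preprocessing filter (on by default for `"qpms7"`) discards windows that
#' cannot be instances of any motif: a window is kept only if at least
#' `q - 1` other sequences have a window within `2d` of it. The filter never
#' changes the result.
#'
#' @param seqs A [seq_set()] (or data frame with `id`, `seq` columns).
#' @param l Motif length.
#' @param d Maximum mismatches per instance, `0 <= d < l`.
#' @param q Quorum: minimum number of sequences with an instance. Defaults to
#'   `n` (the classic planted motif search).
#' @param algorithm One of `"qpms7"`, `"qpmsprune"`, `"qpmspruneI"`,
#'   `"brute"`.
#' @param filter Apply the 2d preprocessing filter? `NULL` means the
#'   algorithm default (`TRUE` for qPMS7, `FALSE` otherwise).
#' @param evidence Attach per-motif, per-sequence best distances and offsets?
#'   `TRUE` (full evidence), `NA` (support column only), or `FALSE` (skip the
#'   support recomputation too — fastest for very large answer sets; the
#'   `support` column is then `NA`).
#' @param brute_cap Refuse full enumeration beyond this many candidates
#'   (guards accidental exponential runs).
#' @param brute_mode `"auto"`, `"full"` or `"union"` candidate generation for
#'   the brute-force engine.
#' @param time_budget Wall-clock seconds after which the engine stops early
#'   (result flagged `timed_out`, motif set possibly incomplete). `Inf`
#'   disables the check.
#' @return A `pms_result`: list with `motifs` (tibble: `motif`, `support`),
#'   `evidence` (tibble: `motif`, `id`, `distance`, `offsets` list-column; or
#'   `NULL`), `params`, `stats` (node/update counters), and `timed_out`.
#'   Motifs are lexicographically sorted; `support` is recomputed over all
#'   `n` sequences.
#' @examples
#' toy <- seq_set(c("ACGTA", "TACGT", "CCGTT"))
#' fit <- pms_search(toy, l = 3, d = 1, q = 3, algorithm = "brute")
#' tidy(fit)
#' @export
pms_search <- function(seqs, l, d, q = NULL,
                       algorithm = c("qpms7", "qpmsprune", "qpmspruneI", "brute"),
                       filter = NULL, evidence = TRUE,
                       brute_cap = 4^10, brute_mode = c("auto", "full", "union"),
                       time_budget = Inf) {
  seqs <- as_seq_set(seqs)
  algorithm <- match.arg(algorithm)
  brute_mode <- match.arg(brute_mode)
  n <- nrow(seqs)
  q <- q %||% n
  pars <- check_params(seqs, l, d, q)
  l <- pars$l; d <- pars$d; q <- pars$q
  if (algorithm == "qpms7" && q < 2L) {
    abort("qpms7 needs q >= 2 (two pivot sequences)", class = "qpms_param_error")
  }
  alphabet <- seq_alphabet(seqs)
  codes <- seqset_codes(seqs)
  if (is.null(filter)) filter <- algorithm == "qpms7"
  keep <- if (isTRUE(filter)) cpp_preprocess_filter(codes, l, d, q) else NULL
  budget <- if (is.finite(time_budget)) as.double(time_budget) else 0
  res <- switch(algorithm,
    brute = {
      r <- cpp_brute_force(codes, l, d, q,
                           as.double(brute_cap), brute_mode, alphabet$size, keep)
      list(motifs = r$motifs,
           stats = list(nodes_visited = r$candidates, nodes_pruned = 0,
                        distance_updates = 0),
           timed_out = FALSE)
    },
    qpmsprune = run_prune(codes, l, d, q, FALSE, keep, budget, alphabet$size),
    qpmspruneI = run_prune(codes, l, d, q, TRUE, keep, budget, alphabet$size),
    qpms7 = {
      r <- cpp_qpms7(codes, l, d, q, keep, budget, alphabet$size)
      list(motifs = r$motifs,
           stats = list(nodes_visited = r$nodes_visited,
                        nodes_pruned = r$nodes_pruned,
                        distance_updates = r$distance_updates,
                        pivot_pairs = r$pivot_pairs),
           timed_out = r$timed_out)
    }
  )
  motifs_chr <- decode_matrix(res$motifs, alphabet)
  evidence_tbl <- NULL
  if (isFALSE(evidence)) {
    support <- rep(NA_integer_, length(motifs_chr))
  } else {
    ev <- cpp_evidence(codes, res$motifs)
    support <- if (length(motifs_chr)) {
      as.integer(rowSums(ev$dist <= d, na.rm = TRUE))
    } else {
      integer()
    }
    if (isTRUE(evidence) && length(motifs_chr)) {
      evidence_tbl <- tibble(
        motif = rep(motifs_chr, each = n),
        id = rep(seqs$id, times = length(motifs_chr)),
        distance = as.integer(t(ev$dist)),
        offsets = unlist(ev$offsets, recursive = FALSE)
      )
    }
  }
  motif_tbl <- tibble(motif = motifs_chr, l = l, d = d, q = q,
                      support = support)
  out <- list(
    motifs = motif_tbl,
    evidence = evidence_tbl,
    params = list(l = l, d = d, q = q, n = n, algorithm = algorithm,
                  filter = isTRUE(filter), alphabet = alphabet$name),
    stats = as_tibble(res$stats),
    timed_out = isTRUE(res$timed_out)
  )
  class(out) <- "pms_result"
  out
}

run_prune <- function(codes, l, d, q, use_lists, keep, budget, sigma) {
  r <- cpp_qpmsprune(codes, l, d, q, use_lists, keep, budget, sigma)
  list(motifs = r$motifs,
       stats = list(nodes_visited = r$nodes_visited,
                    nodes_pruned = r$nodes_pruned,
                    distance_updates = r$distance_updates),
       timed_out = r$timed_out)
}

#' 2d preprocessing window filter
#'
#' A window `u` of sequence `i` can be an instance of some (l,d,q)-motif only
#' if at least `q - 1` of the other sequences contain a window `v` with
#' `hamming(u, v) <= 2d` (two instances of one motif are within `2d` of each
#' other by the triangle inequality). Windows failing the test are removed
#' from pivot candidacy and from initial surviving lists; the search result
#' is unchanged.
#'
#' @inheritParams pms_search
#' @return Named list (one element per sequence) of kept window offsets,
#'   0-based.
#' @export
preprocess_filter <- function(seqs, l, d, q = NULL) {
  seqs <- as_seq_set(seqs)
  q <- q %||% nrow(seqs)
  pars <- check_params(seqs, l, d, q)
  keep <- cpp_preprocess_filter(seqset_codes(seqs), pars$l, pars$d, pars$q)
  setNames(lapply(keep, as.integer), seqs$id)
}

#' Per-sequence evidence for one motif
#'
#' Fills in, for every sequence, the best window distance to the motif and
#' all offsets attaining it, and checks the quorum contract (`support >= q`).
#'
#' @inheritParams pms_search
#' @param motif The motif l-mer (must satisfy the quorum at `(d, q)`).
#' @return Tibble with columns `motif`, `id`, `distance`, `offsets`
#'   (list-column of 0-based starts), plus attributes `support`.
#' @export
assemble_report <- function(seqs, motif, d, q = NULL) {
  seqs <- as_seq_set(seqs)
  q <- q %||% nrow(seqs)
  alphabet <- seq_alphabet(seqs)
  tc <- encode_lmer(motif, alphabet)
  ev <- cpp_evidence(seqset_codes(seqs), matrix(tc, nrow = 1))
  dist <- as.integer(ev$dist[1, ])
  support <- sum(dist <= d, na.rm = TRUE)
  if (support < q) {
    abort(sprintf("motif %s has support %d < q = %d", motif, support, q),
          class = "qpms_param_error")
  }
  out <- tibble(motif = motif, id = seqs$id, distance = dist,
                offsets = lapply(ev$offsets[[1]], as.integer))
  attr(out, "support") <- support
  out
}
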