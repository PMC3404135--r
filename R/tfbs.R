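#' Expected number of motif matches in a random string
#'
#' Under an i.i.d. background, the expected number of windows of a random
#' string of length `seq_length` within `d` mismatches of `motif` is
#' `(seq_length - l + 1) * P(X <= d)`, where `X` is the number of
#' mismatching positions — a Poisson-binomial variable with per-position
#' match probability equal to the background frequency of the motif
#' character at that position. The tail is computed by an exact dynamic
#' program over positions.
#'
#' @param motif The motif l-mer.
#' @param seq_length String length (`>= l`).
#' @param d Maximum mismatches.
#' @param background Per-character background frequencies (named by symbol or
#'   in alphabet order; default uniform).
#' @param alphabet Alphabet of the motif.
#' @return Expected match count (double).
#' @examples
#' expected_match_count("AC", 2, 1) # 7/16
#' @export
expected_match_count <- function(motif, seq_length, d, background = NULL,
                                 alphabet = "dna") {
  alphabet <- motif_alphabet(alphabet)
  codes <- encode_lmer(motif, alphabet)
  l <- length(codes)
  if (seq_length < l) {
    abort("seq_length must be >= motif length", class = "qpms_param_error")
  }
  if (d < 0) abort("d must be >= 0", class = "qpms_param_error")
  prob <- check_background(background, alphabet)
  p_match <- prob[codes + 1L]
  (seq_length - l + 1) * pbinom_tail_le(1 - p_match, d)
}

# P(sum of independent Bernoulli(p_i) <= d), exact DP
pbinom_tail_le <- function(p_mismatch, d) {
  d <- min(d, length(p_mismatch))
  dp <- c(1, rep(0, d))  # dp[k+1] = P(k mismatches so far)
  for (p in p_mismatch) {
    shifted <- c(0, dp[-length(dp)] * p)
    dp <- dp * (1 - p) + shifted
  }
  sum(dp)
}

#' Sequence specificity of a motif
#'
#' The scoring function used to rank candidate motifs: the log of the
#' product over input strings of the expected number of matches within `d`
#' mismatches under the i.i.d. background, `sum_i log E_i`. Rarer-by-chance
#' motifs score lower and rank better.
#'
#' @param seqs A [seq_set()].
#' @param motif Motif l-mer.
#' @param d Mismatch radius the motif was found at.
#' @param background Per-character background frequencies; `NULL` estimates
#'   them from `seqs` (real promoter sets are compositionally biased).
#' @return The score (double; smaller = more specific).
#' @export
sequence_specificity <- function(seqs, motif, d, background = NULL) {
  seqs <- as_seq_set(seqs)
  alphabet <- seq_alphabet(seqs)
  if (is.null(background)) background <- estimate_background(seqs)
  sum(vapply(nchar(seqs$seq), function(m) {
    log(expected_match_count(motif, m, d, background, alphabet))
  }, numeric(1)))
}

#' Empirical per-character background frequencies of a sequence set
#'
#' @param seqs A [seq_set()].
#' @return Named numeric vector over the alphabet (pseudocount 1 per symbol,
#'   so every frequency is positive).
#' @export
estimate_background <- function(seqs) {
  seqs <- as_seq_set(seqs)
  alphabet <- seq_alphabet(seqs)
  chars <- unlist(strsplit(seqs$seq, "", fixed = TRUE), use.names = FALSE)
  counts <- as.numeric(table(factor(chars, levels = alphabet$symbols)))
  freq <- (counts + 1) / (sum(counts) + alphabet$size)
  setNames(freq, alphabet$symbols)
}

#' Phase I: select candidate motifs over an (l, d) grid
#'
#' For each motif length `l` from `l_min` to `l_max`, runs the search engine
#' at `d = 0, 1, ...` up to `d_max(l)`; the first `d` that yields any motif
#' contributes its motifs (tagged with the `(l, d)` they were found at,
#' scored by [sequence_specificity()]) and the scan moves to the next `l`.
#' A run exceeding `time_budget` seconds is terminated and the scan moves to
#' the next `l` as well.
#'
#' @param seqs A [seq_set()].
#' @param q Quorum passed to the engine (default `n`).
#' @param l_min,l_max Motif length range.
#' @param d_max Function of `l` giving the largest `d` to try (default
#'   `ceiling(l / 4)`).
#' @param algorithm Search engine (see [pms_search()]).
#' @param time_budget Seconds allowed per `(l, d)` run; `0` returns an empty
#'   candidate set immediately.
#' @param background Background frequencies for scoring; `NULL` estimates
#'   from `seqs`.
#' @return Tibble of candidates: `motif`, `l`, `d`, `score`, ordered by
#'   score then motif.
#' @export
phase1_select <- function(seqs, q = NULL, l_min = 10, l_max = 20,
                          d_max = function(l) ceiling(l / 4),
                          algorithm = "qpms7", time_budget = 600,
                          background = NULL) {
  seqs <- as_seq_set(seqs)
  q <- q %||% nrow(seqs)
  empty <- tibble(motif = character(), l = integer(), d = integer(),
                  score = numeric())
  if (time_budget <= 0) return(empty)
  if (l_min > l_max) abort("l_min must be <= l_max", class = "qpms_param_error")
  if (l_max > min(nchar(seqs$seq))) {
    abort("l_max exceeds the shortest sequence length", class = "qpms_param_error")
  }
  if (is.null(background)) background <- estimate_background(seqs)
  out <- list()
  for (l in seq(l_min, l_max)) {
    for (d in seq(0, d_max(l))) {
      if (d >= l) break
      fit <- pms_search(seqs, l = l, d = d, q = q, algorithm = algorithm,
                        evidence = FALSE, time_budget = time_budget)
      if (fit$timed_out) {
        message(sprintf("phase I: (l=%d, d=%d) exceeded the %gs budget; moving to next l",
                        l, d, time_budget))
        break
      }
      if (nrow(fit$motifs) > 0) {
        scores <- vapply(fit$motifs$motif, function(mm) {
          sequence_specificity(seqs, mm, d, background)
        }, numeric(1), USE.NAMES = FALSE)
        out[[length(out) + 1L]] <- tibble(motif = fit$motifs$motif,
                                          l = l, d = d, score = scores)
        break
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$score, .data$motif)
}

#' Phase II: extract binding sites from top-scoring motifs
#'
#' Sorts candidates ascending by score (ties broken lexicographically by
#' motif), keeps the best `k_top`, and reports every window of every
#' sequence within `d_site` mismatches of a kept motif as a binding site.
#'
#' @param seqs A [seq_set()].
#' @param candidates Tibble from [phase1_select()] (columns `motif`, `l`,
#'   `d`, `score`).
#' @param k_top Number of top motifs to keep.
#' @param d_site Site distance threshold; `NULL` uses each motif's own `d`.
#' @return Tibble of sites: `id`, `start`, `end` (0-based half-open),
#'   `site`, `distance`, `motif`, `score`.
#' @export
phase2_sites <- function(seqs, candidates, k_top = 5, d_site = NULL) {
  seqs <- as_seq_set(seqs)
  if (k_top < 1) abort("k_top must be >= 1", class = "qpms_param_error")
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(tibble(id = character(), start = integer(), end = integer(),
                  site = character(), distance = integer(),
                  motif = character(), score = numeric()))
  }
  cand <- dplyr::arrange(candidates, .data$score, .data$motif)
  cand <- head(cand, k_top)
  alphabet <- seq_alphabet(seqs)
  codes <- seqset_codes(seqs)
  rows <- purrr::pmap(cand, function(motif, l, d, score, ...) {
    tc <- encode_lmer(motif, alphabet)
    dmax <- d_site %||% d
    per_seq <- purrr::pmap(list(seqs$id, seqs$seq, codes), function(sid, sstr, sc) {
      n_off <- length(sc) - l + 1L
      if (n_off < 1L) return(NULL)
      hits <- integer()
      dists <- integer()
      for (o in 0:(n_off - 1L)) {
        w <- sc[(o + 1L):(o + l)]
        if (any(w < 0L)) next
        h <- sum(w != tc)
        if (h <= dmax) {
          hits <- c(hits, o)
          dists <- c(dists, h)
        }
      }
      if (length(hits) == 0L) return(NULL)
      tibble(id = sid, start = hits, end = hits + l,
             site = substring(sstr, hits + 1L, hits + l),
             distance = dists, motif = motif, score = score)
    })
    dplyr::bind_rows(per_seq)
  })
  dplyr::bind_rows(rows)
}
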