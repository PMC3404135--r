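#' Hamming distance between equal-length strings
#'
#' Counts mismatching positions. Vectorized over pairs (the shorter argument
#' is recycled).
#'
#' @param u,v Character vectors of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_dist("ACGT", "ACGA")
#' @export
hamming_dist <- function(u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(as.character(u), n)
  v <- rep_len(as.character(v), n)
  if (any(nchar(u) != nchar(v))) {
    abort("strings must have equal length", class = "qpms_param_error")
  }
  mapply(
    function(a, b) sum(strsplit(a, "", fixed = TRUE)[[1]] !=
                       strsplit(b, "", fixed = TRUE)[[1]]),
    u, v,
    USE.NAMES = FALSE
  )
}

#' Minimum Hamming distance of an l-mer to a longer sequence
#'
#' The distance of an l-mer to a sequence is the minimum over all its
#' contiguous length-l windows; all offsets attaining the minimum are
#' returned (0-based, ascending). Windows covering out-of-alphabet characters
#' are ineligible.
#'
#' @param u An l-mer (single string).
#' @param s A sequence at least as long as `u`.
#' @param alphabet Alphabet of both strings.
#' @return List with `dist` (integer) and `offsets` (integer vector,
#'   0-based window starts attaining `dist`).
#' @examples
#' min_hamming("ACG", "TTACGTT")
#' @export
min_hamming <- function(u, s, alphabet = "dna") {
  alphabet <- motif_alphabet(alphabet)
  if (nchar(s) < nchar(u)) {
    abort("sequence shorter than the l-mer", class = "qpms_param_error")
  }
  t <- encode_lmer(u, alphabet)
  sc <- encode_seqs(toupper(s), alphabet)[[1]]
  res <- cpp_min_hamming(sc, t)
  list(dist = res$dist, offsets = as.integer(res$offsets))
}

#' Number of sequences containing a match within d
#'
#' Counts the non-excluded sequences whose minimum window distance to the
#' l-mer `t` is at most `d` — the quantity the quorum test `>= q` is applied
#' to.
#'
#' @param seqs A [seq_set()] (or data frame with `id`, `seq`).
#' @param t Candidate l-mer.
#' @param d Maximum mismatches.
#' @param exclude Integer indices (1-based) of sequences to leave out.
#' @return Integer count.
#' @examples
#' quorum_count(seq_set(c("ACGTA", "TACGT", "CCGTT")), "ACG", d = 1)
#' @export
quorum_count <- function(seqs, t, d, exclude = integer()) {
  seqs <- as_seq_set(seqs)
  alphabet <- seq_alphabet(seqs)
  tc <- encode_lmer(t, alphabet)
  if (d < 0) abort("d must be >= 0", class = "qpms_param_error")
  cpp_quorum_count(seqset_codes(seqs), tc, as.integer(d),
                   as.integer(exclude) - 1L)
}

as_seq_set <- function(seqs, alphabet = "dna") {
  if (inherits(seqs, "seq_set")) return(seqs)
  seq_set(seqs, alphabet = alphabet)
}

# shared validation of (l, d, q) against a sequence set
check_params <- function(seqs, l, d, q) {
  n <- nrow(seqs)
  if (length(l) != 1L || is.na(l) || l < 1L) {
    abort("l must be a positive integer", class = "qpms_param_error")
  }
  if (length(d) != 1L || is.na(d) || d < 0L || d >= l) {
    abort("d must satisfy 0 <= d < l", class = "qpms_param_error")
  }
  if (length(q) != 1L || is.na(q) || q < 1L || q > n) {
    abort("q must satisfy 1 <= q <= n", class = "qpms_param_error")
  }
  if (l > min(nchar(seqs$seq))) {
    abort("l exceeds the shortest sequence length", class = "qpms_param_error")
  }
  invisible(list(l = as.integer(l), d = as.integer(d), q = as.integer(q)))
}
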