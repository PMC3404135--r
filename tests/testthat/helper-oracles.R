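# Independent, brute-force R oracles used to validate the compiled search
# machinery. Everything here is deliberately naive: enumeration and direct
# definitions only, no sharing of code paths with the package internals.

DNA <- c("A", "C", "G", "T")

r_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all l-mers over `symbols`, lexicographically sorted
r_all_lmers <- function(l, symbols = DNA) {
  if (l == 0) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(symbols), l), stringsAsFactors = FALSE))
  sort(apply(grid, 1, paste, collapse = ""))
}

# Hamming ball by filtering the whole space
r_ball <- function(x, d, symbols = DNA) {
  all <- r_all_lmers(nchar(x), symbols)
  all[vapply(all, function(z) r_hamming(z, x) <= d, logical(1))]
}

r_windows <- function(s, l) {
  m <- nchar(s)
  vapply(seq_len(m - l + 1), function(o) substr(s, o, o + l - 1), character(1))
}

r_min_hamming <- function(u, s) {
  ws <- r_windows(s, nchar(u))
  dists <- vapply(ws, r_hamming, numeric(1), a = u)
  list(dist = min(dists), offsets = which(dists == min(dists)) - 1L)
}

r_quorum_count <- function(t, strings, d, exclude = integer()) {
  idx <- setdiff(seq_along(strings), exclude)
  sum(vapply(strings[idx],
             function(s) r_min_hamming(t, s)$dist <= d, logical(1)))
}

# definition-direct motif search over the full candidate space
r_motif_search <- function(strings, l, d, q, symbols = DNA) {
  cands <- r_all_lmers(l, symbols)
  cands[vapply(cands, function(t) r_quorum_count(t, strings, d) >= q,
               logical(1))]
}

# feasibility of the three-ball intersection for EVERY radius triple at once:
# ok[r1+1, r2+1, r3+1] == some z has h(z,ci) <= ri for all i.
# Exhaustive over sigma^L strings, vectorized; the full-space character
# matrices are cached per (L, alphabet).
.lmer_cache <- new.env(parent = emptyenv())

r_lmer_matrix <- function(L, symbols) {
  key <- paste0(L, ":", paste(symbols, collapse = ""))
  if (is.null(.lmer_cache[[key]])) {
    grid <- do.call(expand.grid,
                    c(rep(list(symbols), L), stringsAsFactors = FALSE))
    .lmer_cache[[key]] <- as.matrix(grid)
  }
  .lmer_cache[[key]]
}

r_three_ball_cube <- function(c1, c2, c3, symbols = DNA) {
  L <- nchar(c1)
  M <- r_lmer_matrix(L, symbols)
  nstr <- nrow(M)
  dvec <- function(center) {
    ch <- strsplit(center, "")[[1]]
    rowSums(M != matrix(ch, nrow = nstr, ncol = L, byrow = TRUE))
  }
  d1 <- dvec(c1); d2 <- dvec(c2); d3 <- dvec(c3)
  A <- array(FALSE, dim = c(L + 1, L + 1, L + 1))
  A[unique(cbind(d1, d2, d3)) + 1L] <- TRUE
  for (i in 2:(L + 1)) A[i, , ] <- A[i, , ] | A[i - 1, , ]
  for (i in 2:(L + 1)) A[, i, ] <- A[, i, ] | A[, i - 1, ]
  for (i in 2:(L + 1)) A[, , i] <- A[, , i] | A[, , i - 1]
  A
}

random_string <- function(m, symbols = DNA) {
  paste(sample(symbols, m, replace = TRUE), collapse = "")
}

random_seq_set <- function(n, m, symbols = DNA,
                           alphabet = if (length(symbols) == 4) "dna" else "protein") {
  seq_set(vapply(seq_len(n), function(i) random_string(m, symbols),
                 character(1)), alphabet = alphabet)
}

# small protein alphabet helper
PROTEIN <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# motif sets from all four engines on one instance, as sorted character vectors
all_engine_motifs <- function(seqs, l, d, q, filter = FALSE) {
  lapply(
    c(brute = "brute", prune = "qpmsprune", pruneI = "qpmspruneI",
      seven = "qpms7"),
    function(a) tidy(pms_search(seqs, l, d, q, algorithm = a,
                                filter = filter, evidence = FALSE))$motif
  )
}
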