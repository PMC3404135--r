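#' Generate a planted (l,d,q) benchmark instance
#'
#' Builds the standard planted-motif benchmark: `n` i.i.d. random background
#' strings of length `m`, one uniform random l-mer chosen as the motif, and a
#' mutated copy of it overwritten at a uniform random offset in each of `q`
#' distinct sequences. In mode `"exact-d"` (the default) every planted copy
#' differs from the motif in exactly `d` positions — the hardest placement,
#' at the edge of the ball; `"up-to-d"` draws the mutation count uniformly
#' from `0..d`. Instances are fully reproducible from `seed` (R's default
#' Mersenne-Twister RNG; the global RNG state is left untouched).
#'
#' @param n Number of sequences (default 20, the benchmark shape).
#' @param m Sequence length (default 600).
#' @param l Motif length.
#' @param d Maximum mutations per planted copy.
#' @param q Number of sequences that receive a plant. Defaults to `n`.
#' @param alphabet `"dna"`, `"protein"` or a [motif_alphabet()].
#' @param seed Required integer seed.
#' @param mode `"exact-d"` or `"up-to-d"`.
#' @param base_freq Optional per-character background frequencies (named or
#'   in alphabet order); default uniform.
#' @return A `planted_instance`: list with `seqs` ([seq_set()]), `motif`
#'   (character), `plants` (tibble: `seq_index`, `id`, `offset` 0-based,
#'   `site`, `n_mut`), `seed` and `params`.
#' @examples
#' inst <- generate_planted_instance(n = 5, m = 40, l = 6, d = 1, seed = 1)
#' inst$motif
#' inst$plants
#' @export
generate_planted_instance <- function(n = 20, m = 600, l, d, q = NULL,
                                      alphabet = "dna", seed,
                                      mode = c("exact-d", "up-to-d"),
                                      base_freq = NULL) {
  mode <- match.arg(mode)
  alphabet <- motif_alphabet(alphabet)
  q <- q %||% n
  if (missing(seed)) abort("a seed is required", class = "qpms_param_error")
  if (n < 1 || q < 1 || q > n) {
    abort("need n >= q >= 1", class = "qpms_param_error")
  }
  if (m < l) abort("need m >= l", class = "qpms_param_error")
  if (d < 0 || d >= l) abort("need 0 <= d < l", class = "qpms_param_error")
  sigma <- alphabet$size
  prob <- check_background(base_freq, alphabet)
  withr::with_seed(as.integer(seed), {
    strings <- vapply(seq_len(n), function(i) {
      paste(sample(alphabet$symbols, m, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    motif_chars <- sample(alphabet$symbols, l, replace = TRUE)
    motif <- paste(motif_chars, collapse = "")
    planted_in <- sort(sample.int(n, q))
    plants <- lapply(planted_in, function(i) {
      k <- if (mode == "exact-d") as.integer(d) else sample.int(d + 1L, 1L) - 1L
      site_chars <- motif_chars
      if (k > 0) {
        pos <- sample.int(l, k)
        for (p in pos) {
          others <- alphabet$symbols[alphabet$symbols != site_chars[p]]
          site_chars[p] <- others[sample.int(sigma - 1L, 1L)]
        }
      }
      offset <- sample.int(m - l + 1L, 1L) - 1L
      list(seq_index = as.integer(i), offset = as.integer(offset),
           site = paste(site_chars, collapse = ""), n_mut = as.integer(k))
    })
    for (pl in plants) {
      s <- strings[pl$seq_index]
      substr(s, pl$offset + 1L, pl$offset + l) <- pl$site
      strings[pl$seq_index] <- s
    }
    seqs <- seq_set(strings, alphabet = alphabet)
    plants_tbl <- tibble(
      seq_index = vapply(plants, `[[`, integer(1), "seq_index"),
      id = seqs$id[vapply(plants, `[[`, integer(1), "seq_index")],
      offset = vapply(plants, `[[`, integer(1), "offset"),
      site = vapply(plants, `[[`, character(1), "site"),
      n_mut = vapply(plants, `[[`, integer(1), "n_mut")
    )
    out <- list(
      seqs = seqs, motif = motif, plants = plants_tbl,
      seed = as.integer(seed),
      params = list(n = n, m = m, l = l, d = d, q = q,
                    alphabet = alphabet$name, mode = mode,
                    base_freq = prob)
    )
    class(out) <- "planted_instance"
    out
  })
}

check_background <- function(base_freq, alphabet) {
  if (is.null(base_freq)) {
    return(rep(1 / alphabet$size, alphabet$size))
  }
  if (!is.null(names(base_freq))) {
    base_freq <- base_freq[alphabet$symbols]
  }
  if (length(base_freq) != alphabet$size || anyNA(base_freq) ||
      any(base_freq <= 0)) {
    abort("background must give a positive frequency for every symbol",
          class = "qpms_param_error")
  }
  as.numeric(base_freq / sum(base_freq))
}

#' @export
print.planted_instance <- function(x, ...) {
  p <- x$params
  cat("<planted_instance> n=", p$n, " m=", p$m, " (l,d,q)=(", p$l, ",", p$d,
      ",", p$q, ") alphabet=", p$alphabet, " mode=", p$mode,
      " seed=", x$seed, "\n", sep = "")
  cat("motif: ", x$motif, "\n", sep = "")
  cat("plants in ", nrow(x$plants), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Challenging (l,d) ladders for the planted-motif benchmark
#'
#' The standard "challenging instance" parameter ladders at the benchmark
#' shape (n = 20, m = 600): DNA with quorum n (classic planted motif search)
#' or quorum n/2, and the protein analogues.
#'
#' @param kind One of `"dna-pms"`, `"dna-qpms"`, `"protein-pms"`,
#'   `"protein-qpms"`.
#' @return Tibble with columns `l`, `d`.
#' @examples
#' challenging_presets("dna-pms")
#' @export
challenging_presets <- function(kind = c("dna-pms", "dna-qpms",
                                         "protein-pms", "protein-qpms")) {
  kind <- match.arg(kind)
  switch(kind,
    "dna-pms" = tibble(l = c(13L, 15L, 17L, 19L, 21L, 23L),
                       d = c(4L, 5L, 6L, 7L, 8L, 9L)),
    "dna-qpms" = tibble(l = c(13L, 15L, 17L, 19L, 21L),
                        d = c(3L, 4L, 5L, 6L, 7L)),
    "protein-pms" = tibble(l = c(11L, 13L, 15L, 17L, 19L),
                           d = c(5L, 6L, 7L, 8L, 9L)),
    "protein-qpms" = tibble(l = c(11L, 13L, 15L, 17L, 19L),
                            d = c(4L, 5L, 6L, 7L, 8L))
  )
}

#' Write a planted instance to FASTA plus a truth sidecar
#'
#' The sidecar is a machine-readable TSV with header comments recording the
#' generator parameters and seed, and one row per plant with 0-based
#' half-open coordinates.
#'
#' @param inst A `planted_instance`.
#' @param fasta_path FASTA output path.
#' @param truth_path Sidecar output path (defaults to `<fasta>.truth.tsv`).
#' @return Invisibly, a list of the two paths.
#' @export
write_instance <- function(inst, fasta_path,
                           truth_path = paste0(fasta_path, ".truth.tsv")) {
  stopifnot(inherits(inst, "planted_instance"))
  write_sequences(inst$seqs, fasta_path)
  p <- inst$params
  header <- c(
    paste0("# quorumotif planted instance truth file"),
    paste0("# version=", as.character(utils::packageVersion("quorumotif"))),
    paste0("# motif=", inst$motif),
    paste0("# seed=", inst$seed),
    paste0("# n=", p$n, " m=", p$m, " l=", p$l, " d=", p$d, " q=", p$q,
           " alphabet=", p$alphabet, " mode=", p$mode),
    paste0("# coordinates: 0-based half-open [start, end)")
  )
  body <- inst$plants
  body$end <- body$offset + p$l
  body <- body[, c("seq_index", "id", "offset", "end", "site", "n_mut")]
  con <- file(truth_path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(colnames(body), collapse = "\t"), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, truth = truth_path))
}

#' Read back a truth sidecar
#'
#' @param path Truth file written by [write_instance()].
#' @return Tibble of plants with attributes `motif` and `seed`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("truth file not found: ", path), class = "qpms_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  motif <- sub("^# motif=", "", grep("^# motif=", comments, value = TRUE))
  seed <- sub("^# seed=", "", grep("^# seed=", comments, value = TRUE))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  out <- as_tibble(tab)
  attr(out, "motif") <- motif
  attr(out, "seed") <- as.integer(seed)
  out
}
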