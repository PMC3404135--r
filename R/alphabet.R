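#' Sequence alphabets
#'
#' A motif alphabet is an ordered set of distinct single characters over which
#' sequences, l-mers and Hamming balls are defined. Two presets cover the
#' usual cases: `"dna"` (A, C, G, T) and `"protein"` (the 20 standard amino
#' acids). Characters outside the alphabet (e.g. `N` in DNA) are tolerated on
#' input but every window covering one is ineligible both as an l-mer and as a
#' match witness.
#'
#' @param x A preset name (`"dna"` or `"protein"`), a character vector of
#'   single characters, or an existing `motif_alphabet`.
#' @return A `motif_alphabet` object: list with elements `symbols` (ordered
#'   character vector) and `size`.
#' @examples
#' motif_alphabet("dna")
#' motif_alphabet(c("0", "1"))
#' @export
motif_alphabet <- function(x = "dna") {
  if (inherits(x, "motif_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L && x %in% c("dna", "protein")) {
    symbols <- switch(x,
      dna = c("A", "C", "G", "T"),
      protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    )
    name <- x
  } else {
    symbols <- as.character(x)
    name <- "custom"
  }
  if (any(nchar(symbols) != 1L)) {
    abort("alphabet symbols must be single characters", class = "qpms_param_error")
  }
  if (anyDuplicated(symbols)) {
    abort("alphabet symbols must be distinct", class = "qpms_param_error")
  }
  if (length(symbols) < 2L) {
    abort("an alphabet needs at least 2 symbols", class = "qpms_param_error")
  }
  structure(list(symbols = symbols, size = length(symbols), name = name),
            class = "motif_alphabet")
}

#' @export
print.motif_alphabet <- function(x, ...) {
  cat("<motif_alphabet> ", x$name, " (size ", x$size, "): ",
      paste(x$symbols, collapse = ""), "\n", sep = "")
  invisible(x)
}

# encode a character vector of strings to a list of 0-based integer code
# vectors; characters outside the alphabet become -1
encode_seqs <- function(strings, alphabet) {
  symbols <- alphabet$symbols
  lapply(strsplit(strings, "", fixed = TRUE), function(ch) {
    i <- match(ch, symbols)
    i[is.na(i)] <- 0L
    i - 1L
  })
}

encode_lmer <- function(s, alphabet) {
  stopifnot(length(s) == 1L)
  codes <- encode_seqs(toupper(s), alphabet)[[1]]
  if (any(codes < 0L)) {
    abort(paste0("'", s, "' contains characters outside the alphabet"),
          class = "qpms_param_error")
  }
  codes
}

decode_lmer <- function(codes, alphabet) {
  paste(alphabet$symbols[codes + 1L], collapse = "")
}

# decode an integer matrix (rows = l-mers) to a character vector
decode_matrix <- function(m, alphabet) {
  if (nrow(m) == 0L) return(character())
  apply(m, 1L, decode_lmer, alphabet = alphabet)
}
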