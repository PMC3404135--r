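#' Build a sequence set
#'
#' A `seq_set` is the input container for all searches: a tibble with columns
#' `id` and `seq`, carrying its alphabet as an attribute. Sequences are
#' uppercased on construction. By default characters outside the alphabet are
#' tolerated (windows covering them are simply ineligible); `strict = TRUE`
#' rejects such sequences outright.
#'
#' @param x A character vector of sequences, or a data frame with columns
#'   `id` and `seq`.
#' @param alphabet Alphabet preset name or [motif_alphabet()] object.
#' @param ids Optional identifiers (defaults to `seq1`, `seq2`, ...).
#' @param strict Reject sequences containing out-of-alphabet characters?
#' @return A `seq_set` tibble with columns `id`, `seq`.
#' @examples
#' seq_set(c("ACGTACGT", "TTACGTTT"))
#' @export
seq_set <- function(x, alphabet = "dna", ids = NULL, strict = FALSE) {
  alphabet <- motif_alphabet(alphabet)
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      abort("data frame input needs columns 'id' and 'seq'", class = "qpms_input_error")
    }
    ids <- as.character(x$id)
    x <- as.character(x$seq)
  } else {
    x <- as.character(x)
    if (is.null(ids)) {
      ids <- names(x) %||% paste0("seq", seq_along(x))
      if (is.null(names(x)) && length(x) > 0L) ids <- paste0("seq", seq_along(x))
    }
  }
  if (length(x) == 0L) abort("no sequences given", class = "qpms_input_error")
  x <- toupper(x)
  bad <- vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) any(!ch %in% alphabet$symbols), logical(1)
  )
  if (strict && any(bad)) {
    abort(paste0("sequence(s) ", paste(ids[bad], collapse = ", "),
                 " contain characters outside the alphabet"),
          class = "qpms_input_error")
  }
  out <- tibble(id = as.character(ids), seq = x)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", class(out))
  out
}

#' @export
print.seq_set <- function(x, ...) {
  a <- attr(x, "alphabet")
  cat("<seq_set> ", nrow(x), " sequence(s), alphabet ", a$name,
      " (size ", a$size, ")\n", sep = "")
  NextMethod()
}

seq_alphabet <- function(seqs) {
  a <- attr(seqs, "alphabet")
  if (is.null(a)) motif_alphabet("dna") else a
}

# encoded (0-based, -1 = out of alphabet) integer code list for a seq_set
seqset_codes <- function(seqs) {
  encode_seqs(seqs$seq, seq_alphabet(seqs))
}

#' Read sequences from FASTA or plain text
#'
#' FASTA is parsed with `Biostrings`; the description line after `>` is used
#' as the id up to the first whitespace. Plain text means one sequence per
#' line. `format = "auto"` sniffs the first non-empty character (`>` means
#' FASTA).
#'
#' @param path Input file.
#' @param format `"auto"`, `"fasta"` or `"plain"`.
#' @inheritParams seq_set
#' @return A [seq_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "plain"),
                           alphabet = "dna", strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "qpms_input_error")
  }
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(trimws(first[1]), ">")) "fasta" else "plain"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    strings <- as.character(ss)
  } else {
    strings <- readLines(path, warn = FALSE)
    strings <- trimws(strings)
    strings <- strings[nzchar(strings)]
    ids <- paste0("seq", seq_along(strings))
  }
  if (length(strings) == 0L) {
    abort(paste0("no sequences in ", path), class = "qpms_input_error")
  }
  seq_set(strings, alphabet = alphabet, ids = ids, strict = strict)
}

#' Write a sequence set as FASTA
#'
#' @param seqs A [seq_set()].
#' @param path Output file.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
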