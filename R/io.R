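# TSV writers. Every machine output opens with a '#' header block recording
# the package version and the full run configuration, so files are
# self-describing; coordinates are 0-based half-open throughout.

tsv_header <- function(kind, config) {
  cfg <- paste(names(config), unlist(lapply(config, as.character)),
               sep = "=", collapse = " ")
  c(paste0("# quorumotif ", kind),
    paste0("# version=", as.character(utils::packageVersion("quorumotif"))),
    paste0("# config: ", cfg),
    "# coordinates: 0-based half-open")
}

write_tsv_block <- function(tbl, path, header) {
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  writeLines(header, con)
  writeLines(paste(colnames(tbl), collapse = "\t"), con)
  if (nrow(tbl)) {
    utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write motif search results as TSV
#'
#' One row per motif: `motif`, `l`, `d`, `q`, `support`, then per-sequence
#' best distance (`dist.<id>`) and comma-joined best offsets
#' (`offsets.<id>`), when the result carries evidence.
#'
#' @param result A `pms_result` from [pms_search()].
#' @param path Output file.
#' @param config Optional extra name=value pairs recorded in the header.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(result, path, config = list()) {
  stopifnot(inherits(result, "pms_result"))
  tbl <- result$motifs
  if (!is.null(result$evidence) && nrow(tbl)) {
    ev <- result$evidence
    ids <- unique(ev$id)
    for (sid in ids) {
      sub <- ev[ev$id == sid, ]
      tbl[[paste0("dist.", sid)]] <- sub$distance[match(tbl$motif, sub$motif)]
      tbl[[paste0("offsets.", sid)]] <-
        vapply(sub$offsets[match(tbl$motif, sub$motif)],
               paste, character(1), collapse = ",")
    }
  }
  header <- tsv_header("motifs", c(result$params[c("l", "d", "q", "n",
                                                   "algorithm", "filter")],
                                   config))
  write_tsv_block(tbl, path, header)
}

#' Write binding sites as BED-like TSV
#'
#' Columns: `id`, `start`, `end` (0-based half-open), `site`, `distance`,
#' `motif`, `score`.
#'
#' @param sites Tibble from [phase2_sites()].
#' @param path Output file.
#' @param config Optional extra name=value pairs for the header.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path, config = list()) {
  write_tsv_block(sites, path, tsv_header("binding sites", config))
}

#' Write Phase I candidates as TSV
#'
#' @param candidates Tibble from [phase1_select()].
#' @param path Output file.
#' @param config Optional extra name=value pairs for the header.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path, config = list()) {
  write_tsv_block(candidates, path, tsv_header("candidate motifs", config))
}
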