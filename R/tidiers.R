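#' @export
print.pms_result <- function(x, ...) {
  p <- x$params
  cat("<pms_result> ", p$algorithm, " (l,d,q)=(", p$l, ",", p$d, ",", p$q,
      ") on ", p$n, " sequence(s)",
      if (p$filter) ", 2d-filter on" else "",
      if (x$timed_out) " [TIMED OUT: possibly incomplete]" else "",
      "\n", sep = "")
  cat(nrow(x$motifs), " motif(s) found\n", sep = "")
  if (nrow(x$motifs)) print(x$motifs, n = 10)
  invisible(x)
}

#' Tidy a motif search result
#'
#' @param x A `pms_result` from [pms_search()].
#' @param ... Unused.
#' @return The motif tibble (`motif`, `l`, `d`, `q`, `support`), one row per
#'   reported motif.
#' @export
tidy.pms_result <- function(x, ...) {
  x$motifs
}

#' One-row summary of a motif search run
#'
#' @param x A `pms_result`.
#' @param ... Unused.
#' @return A one-row tibble: parameters, motif count, search counters and
#'   the time-out flag.
#' @export
glance.pms_result <- function(x, ...) {
  p <- x$params
  dplyr::bind_cols(
    tibble(algorithm = p$algorithm, l = p$l, d = p$d, q = p$q, n = p$n,
           filter = p$filter, n_motifs = nrow(x$motifs),
           timed_out = x$timed_out),
    x$stats
  )
}

#' Plot per-sequence match distances of found motifs
#'
#' Tile map of the best window distance of each sequence to each reported
#' motif; cells at or under the search radius `d` are the supporting
#' matches.
#'
#' @param object A `pms_result` built with `evidence = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pms_result <- function(object, ...) {
  if (is.null(object$evidence)) {
    abort("run pms_search() with evidence = TRUE to plot", class = "qpms_param_error")
  }
  ev <- object$evidence
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$id, y = .data$motif,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$distance), size = 3) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "sequence", y = "motif",
                  fill = "best\ndistance",
                  title = sprintf("(l,d,q) = (%d,%d,%d): motif support",
                                  object$params$l, object$params$d,
                                  object$params$q)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tidy a planted instance
#'
#' @param x A `planted_instance`.
#' @param ... Unused.
#' @return The plants tibble (ground truth: one row per planted site).
#' @export
tidy.planted_instance <- function(x, ...) {
  x$plants
}

#' One-row summary of a planted instance
#'
#' @param x A `planted_instance`.
#' @param ... Unused.
#' @return One-row tibble of generator parameters plus the motif and seed.
#' @export
glance.planted_instance <- function(x, ...) {
  p <- x$params
  tibble(n = p$n, m = p$m, l = p$l, d = p$d, q = p$q,
         alphabet = p$alphabet, mode = p$mode, motif = x$motif,
         seed = x$seed)
}

#' Plot a planted instance
#'
#' Shows each sequence as a horizontal track with the planted site marked;
#' a quick visual check that plants are where the truth table says.
#'
#' @param object A `planted_instance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.planted_instance <- function(object, ...) {
  p <- object$params
  tracks <- tibble(id = object$seqs$id, len = nchar(object$seqs$seq))
  ggplot2::ggplot(tracks) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$len, y = .data$id,
                                       yend = .data$id), color = "grey70") +
    ggplot2::geom_segment(
      data = object$plants,
      ggplot2::aes(x = .data$offset, xend = .data$offset + p$l, y = .data$id,
                   yend = .data$id),
      linewidth = 3, color = "firebrick"
    ) +
    ggplot2::labs(x = "position (0-based)", y = NULL,
                  title = sprintf("planted %s at (l,d,q) = (%d,%d,%d)",
                                  object$motif, p$l, p$d, p$q)) +
    ggplot2::theme_minimal()
}
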