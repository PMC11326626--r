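#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a CoNLL-style BIOE token file
#'
#' One token per line, token and tag separated by a tab, sentences
#' separated by blank lines — the layout sequence-labelling trainers
#' consume.
#'
#' @param labelled_tokens Token tibble with a `label` column from
#'   [encode_bioe()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_conll <- function(labelled_tokens, path) {
  x <- dplyr::arrange(tibble::as_tibble(labelled_tokens), .data$doc_id,
                      .data$sentence, .data$token_idx)
  lines <- character()
  groups <- split(seq_len(nrow(x)), paste(x$doc_id, x$sentence, sep = "\r"))
  groups <- groups[order(vapply(groups, min, integer(1)))]
  for (idx in groups) {
    lines <- c(lines, paste0(x$token[idx], "\t", x$label[idx]), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CoNLL-style BIOE token file
#'
#' @param path File written by [write_conll()].
#' @return Token tibble with columns `doc_id` (constant `"conll"`),
#'   `sentence`, `token_idx`, `token`, `label`. Character offsets are
#'   reconstructed assuming single spaces between tokens, which is enough
#'   to score decoded spans consistently.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sent <- 0L
  rows <- list()
  idx <- 0L
  cursor <- 0L
  new_sentence <- TRUE
  for (line in lines) {
    if (!nzchar(line)) {
      new_sentence <- TRUE
      next
    }
    if (new_sentence) {
      sent <- sent + 1L
      idx <- 0L
      new_sentence <- FALSE
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    idx <- idx + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = "conll", sentence = sent, token_idx = idx,
      token = parts[[1]],
      start = cursor, end = cursor + nchar(parts[[1]]),
      label = if (length(parts) > 1L) parts[[2]] else "O"
    )
    cursor <- cursor + nchar(parts[[1]]) + 1L
  }
  dplyr::bind_rows(rows)
}

#' Write enumerated span candidates as TSV
#'
#' @param spans Tibble from [enumerate_spans()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_span_candidates <- function(spans, path) {
  utils::write.table(
    spans[, c("doc_id", "sentence", "start_tok", "end_tok", "label")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
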