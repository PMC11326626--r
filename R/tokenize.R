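token_pattern <- "[[:alnum:]]+(?:[-./'][[:alnum:]]+)*|[^[:alnum:][:space:]]"

# Sentence end: run of terminal punctuation followed by whitespace or the
# section end. Internal periods in tokens like "PM1.0" are not followed by
# whitespace and therefore never split.
sentence_end_pattern <- "[.!?]+(?=\\s|$)"

tokenize_span <- function(text, offset0) {
  m <- gregexpr(token_pattern, text, perl = TRUE)[[1]]
  if (m[[1]] == -1L) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, m, m + len - 1L),
    start = as.integer(offset0 + m - 1L),
    end = as.integer(offset0 + m - 1L + len)
  )
}

#' Segment documents into sentences and offset-preserving tokens
#'
#' Splits each document into sentences within its section boundaries
#' (segmentation never crosses a section edge) and tokenizes each sentence
#' with a rule-based, offset-preserving tokenizer: tokens are maximal
#' alphanumeric runs that may keep internal hyphens, periods and
#' apostrophes (so "10-mm" and "PM1.0" stay single tokens, as device and
#' substance mentions require), plus single punctuation characters. Every
#' token records its exact character offsets into the document text.
#'
#' @param documents Tibble with `doc_id` and `text`.
#' @param sections Optional tibble with `doc_id`, `label`, `start`, `end`;
#'   absent sections default to one section spanning the whole text.
#'
#' @return A token tibble: `doc_id`, `section`, `sentence` (1-based index
#'   within document), `token_idx` (1-based within sentence), `token`,
#'   `start`, `end` (0-based, half-open character offsets).
#' @export
segment_and_tokenize <- function(documents, sections = NULL) {
  purrr::map(seq_len(nrow(documents)), function(i) {
    doc_id <- documents$doc_id[[i]]
    text <- documents$text[[i]]
    secs <- if (is.null(sections)) {
      tibble::tibble(label = "Text", start = 0L, end = nchar(text))
    } else {
      s <- dplyr::filter(sections, .data$doc_id == !!doc_id)
      if (nrow(s) == 0L) {
        tibble::tibble(label = "Text", start = 0L, end = nchar(text))
      } else {
        dplyr::arrange(s, .data$start)[, c("label", "start", "end")]
      }
    }
    sent_counter <- 0L
    out <- purrr::map(seq_len(nrow(secs)), function(si) {
      sec_text <- substr(text, secs$start[[si]] + 1L, secs$end[[si]])
      ends <- gregexpr(sentence_end_pattern, sec_text, perl = TRUE)[[1]]
      bounds <- if (ends[[1]] == -1L) {
        nchar(sec_text)
      } else {
        e <- ends + attr(ends, "match.length") - 1L
        if (max(e) < nchar(sec_text)) c(e, nchar(sec_text)) else e
      }
      sent_start <- 1L
      purrr::map(bounds, function(b) {
        chunk <- substr(sec_text, sent_start, b)
        toks <- tokenize_span(chunk, secs$start[[si]] + sent_start - 1L)
        sent_start <<- b + 1L
        if (nrow(toks) == 0L) return(NULL)
        sent_counter <<- sent_counter + 1L
        toks$doc_id <- doc_id
        toks$section <- secs$label[[si]]
        toks$sentence <- sent_counter
        toks$token_idx <- seq_len(nrow(toks))
        toks
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
    out
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::select("doc_id", "section", "sentence", "token_idx",
                  "token", "start", "end")
}
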