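#' Train a dictionary (gazetteer) baseline tagger
#'
#' Collects every training annotation's normalised surface string
#' (lowercased, whitespace collapsed) per category together with its
#' observed training frequency. The resulting gazetteer is the classic
#' dictionary-lookup baseline: it can only ever predict spans it has seen,
#' so its exact-match recall is bounded by the seen-span fraction of the
#' test data — a useful reference point for learning-based models.
#'
#' @param train Annotation tibble.
#' @return Gazetteer tibble: `category`, `surface` (normalised), `freq`.
#' @export
train_dictionary_tagger <- function(train) {
  train <- as_annotations(train)
  if (nrow(train) == 0L) {
    return(tibble::tibble(category = character(), surface = character(),
                          freq = integer()))
  }
  train %>%
    dplyr::mutate(surface = normalize_surface(.data$surface)) %>%
    dplyr::count(.data$category, .data$surface, name = "freq") %>%
    dplyr::arrange(.data$category, dplyr::desc(.data$freq))
}

#' Apply a dictionary tagger to documents
#'
#' Case-insensitive longest-match-first scanning of each sentence: token
#' windows are tried from the widest down, left to right, and a window
#' whose normalised surface occurs in the gazetteer becomes a predicted
#' annotation; overlapping narrower or later matches are suppressed. A
#' surface listed under several categories resolves to the one with the
#' highest training frequency, ties broken by scheme order.
#'
#' @param gazetteer Tibble from [train_dictionary_tagger()].
#' @param documents Document tibble (`doc_id`, `text`).
#' @param sections Optional section tibble.
#' @param scheme Scheme tibble (tie-break order).
#' @param max_width Widest token window tried.
#' @return Annotation tibble with `annotator_id = "dictionary"`.
#' @export
apply_dictionary_tagger <- function(gazetteer, documents, sections = NULL,
                                    scheme = default_scheme(),
                                    max_width = 12L) {
  if (nrow(gazetteer) == 0L) return(empty_annotations())
  cats <- scheme_categories(scheme)
  lookup <- gazetteer %>%
    dplyr::mutate(cat_rank = match(.data$category, cats)) %>%
    dplyr::arrange(.data$surface, dplyr::desc(.data$freq), .data$cat_rank) %>%
    dplyr::distinct(.data$surface, .keep_all = TRUE)
  dict <- stats::setNames(lookup$category, lookup$surface)

  tokens <- segment_and_tokenize(documents, sections)
  preds <- tokens %>%
    dplyr::group_by(.data$doc_id, .data$sentence) %>%
    dplyr::group_map(function(g, key) {
      text <- documents$text[documents$doc_id == key$doc_id][[1]]
      n <- nrow(g)
      used <- logical(n)
      rows <- list()
      for (width in seq(from = min(max_width, n), to = 1L)) {
        for (i in seq_len(n - width + 1L)) {
          j <- i + width - 1L
          if (any(used[i:j])) next
          cand <- normalize_surface(substr(text, g$start[[i]] + 1L, g$end[[j]]))
          hit <- dict[cand]
          if (!is.na(hit)) {
            used[i:j] <- TRUE
            rows[[length(rows) + 1L]] <- tibble::tibble(
              doc_id = key$doc_id, category = unname(hit),
              start = g$start[[i]], end = g$end[[j]],
              surface = substr(text, g$start[[i]] + 1L, g$end[[j]])
            )
          }
        }
      }
      dplyr::bind_rows(rows)
    }) %>% dplyr::bind_rows()

  if (nrow(preds) == 0L) return(empty_annotations())
  preds <- dplyr::arrange(preds, .data$doc_id, .data$start, .data$end)
  preds$annotator_id <- "dictionary"
  preds$id <- paste0("T", seq_len(nrow(preds)))
  as_annotations(preds)
}
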