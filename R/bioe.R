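bioe_tag <- function(category) gsub(" ", "", category, fixed = TRUE)

bioe_category_map <- function(scheme) {
  cats <- scheme_categories(scheme)
  stats::setNames(cats, bioe_tag(cats))
}

#' Encode annotations as token-level BIOE labels
#'
#' Assigns each token one label from the alphabet `{B-c, I-c, E-c, O}`: a
#' single-token entity is `B-c` on its token; a multi-token entity is
#' `B-c`, zero or more `I-c`, then `E-c`; everything else is `O`. Category
#' tags drop internal spaces (`"Job Task/Activity"` -> `JobTask/Activity`).
#'
#' Annotation boundaries that split a token are snapped outward to whole
#' tokens with a warning. Overlapping same-category annotations keep the
#' longer span, logging the discard. Annotations crossing a sentence
#' boundary are clipped to the sentence containing their start.
#'
#' @param tokens Token tibble from [segment_and_tokenize()].
#' @param annotations Annotation tibble for the same document(s).
#' @param scheme Scheme tibble.
#' @return The token tibble with an added `label` column.
#' @export
encode_bioe <- function(tokens, annotations, scheme = default_scheme()) {
  annotations <- as_annotations(annotations)
  tokens <- dplyr::arrange(tibble::as_tibble(tokens), .data$doc_id,
                           .data$sentence, .data$token_idx)
  tokens$label <- "O"
  if (nrow(annotations) == 0L) return(tokens)
  assert_category(unique(annotations$category), scheme)

  # longer spans win overlap conflicts within a category
  annotations <- dplyr::arrange(annotations,
                                dplyr::desc(.data$end - .data$start))
  claimed <- rep(NA_integer_, nrow(tokens))  # which annotation owns the token

  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    hit <- which(tokens$doc_id == ann$doc_id &
                   tokens$end > ann$start & tokens$start < ann$end)
    if (length(hit) == 0L) next
    hit <- hit[tokens$sentence[hit] == tokens$sentence[[hit[[1]]]]]
    if (tokens$start[[hit[[1]]]] != ann$start ||
        tokens$end[[hit[[length(hit)]]]] != ann$end) {
      rlang::warn(
        paste0("Annotation [", ann$start, ",", ann$end, ") '", ann$surface,
               "' snapped outward to token boundaries.")
      )
    }
    clash <- which(!is.na(claimed[hit]))
    if (length(clash) > 0L) {
      owners <- unique(claimed[hit][clash])
      same_cat <- annotations$category[owners] == ann$category
      if (any(same_cat)) {
        rlang::inform(
          paste0("Overlapping same-category annotation '", ann$surface,
                 "' discarded (longer span kept).")
        )
        next
      }
      # cross-category overlap: first (longer) claimant keeps the tokens
      hit <- hit[is.na(claimed[hit])]
      if (length(hit) == 0L) next
    }
    claimed[hit] <- i
    tag <- bioe_tag(ann$category)
    if (length(hit) == 1L) {
      tokens$label[[hit]] <- paste0("B-", tag)
    } else {
      tokens$label[[hit[[1]]]] <- paste0("B-", tag)
      tokens$label[[hit[[length(hit)]]]] <- paste0("E-", tag)
      if (length(hit) > 2L) {
        tokens$label[hit[c(-1L, -length(hit))]] <- paste0("I-", tag)
      }
    }
  }
  tokens
}

#' Decode token-level BIOE labels back into annotations
#'
#' Maximal well-formed `B (I*) E` runs and lone `B` labels become
#' annotations spanning from the first to the last token. Malformed
#' sequences (as produced by imperfect taggers) are repaired: a leading
#' `I`/`E` without a `B` starts an entity, a category switch mid-run closes
#' the previous entity, `E` always closes, and a dangling run closes at the
#' sentence end.
#'
#' @param tokens Labelled token tibble (column `label`).
#' @param documents Optional document tibble; when given, surfaces are
#'   sliced from the text, otherwise tokens are joined with single spaces.
#' @param scheme Scheme tibble used to map label tags back to category
#'   names.
#' @return An annotation tibble.
#' @export
decode_bioe <- function(tokens, documents = NULL, scheme = default_scheme()) {
  cat_map <- bioe_category_map(scheme)
  tokens <- dplyr::arrange(tibble::as_tibble(tokens), .data$doc_id,
                           .data$sentence, .data$token_idx)
  spans <- list()
  open <- NULL  # list(tag, first, last)

  close_open <- function(doc_id) {
    if (!is.null(open)) {
      spans[[length(spans) + 1L]] <<- tibble::tibble(
        doc_id = doc_id, tag = open$tag,
        first = open$first, last = open$last
      )
      open <<- NULL
    }
  }

  groups <- split(seq_len(nrow(tokens)),
                  paste(tokens$doc_id, tokens$sentence, sep = "\r"))
  # keep document order
  groups <- groups[order(vapply(groups, min, integer(1)))]
  for (idx in groups) {
    doc_id <- tokens$doc_id[[idx[[1]]]]
    for (i in idx) {
      lab <- tokens$label[[i]]
      if (is.na(lab) || lab == "O") {
        close_open(doc_id)
        next
      }
      prefix <- substr(lab, 1L, 1L)
      tag <- substr(lab, 3L, nchar(lab))
      if (prefix == "B") {
        close_open(doc_id)
        open <- list(tag = tag, first = i, last = i)
      } else { # I or E, possibly without an opener: repair by starting one
        if (is.null(open) || open$tag != tag) {
          close_open(doc_id)
          open <- list(tag = tag, first = i, last = i)
        } else {
          open$last <- i
        }
        if (prefix == "E") close_open(doc_id)
      }
    }
    close_open(doc_id)
  }
  if (length(spans) == 0L) return(empty_annotations())
  spans <- dplyr::bind_rows(spans)
  out <- tibble::tibble(
    doc_id = spans$doc_id,
    annotator_id = "decoded",
    id = paste0("T", seq_len(nrow(spans))),
    category = unname(cat_map[spans$tag]),
    start = tokens$start[spans$first],
    end = tokens$end[spans$last]
  )
  if (anyNA(out$category)) {
    rlang::abort("Label tag not in scheme.", class = "expocorpus_parse_error")
  }
  out$surface <- purrr::map_chr(seq_len(nrow(out)), function(i) {
    if (!is.null(documents)) {
      text <- documents$text[documents$doc_id == out$doc_id[[i]]][[1]]
      substr(text, out$start[[i]] + 1L, out$end[[i]])
    } else {
      paste(tokens$token[spans$first[[i]]:spans$last[[i]]], collapse = " ")
    }
  })
  out
}

#' Enumerate candidate token spans for span-based NER
#'
#' Lists every contiguous token window of width 1 to `max_width` in each
#' sentence, labelled with the gold category when the window exactly
#' matches a gold annotation's token boundaries and `"NONE"` otherwise.
#' Gold entities longer than `max_width` get no positive candidate; they
#' are counted in the `truncated` attribute.
#'
#' @param tokens Token tibble.
#' @param annotations Gold annotation tibble.
#' @param max_width Maximum window width in tokens (default 12, wide
#'   enough for the long device and task mentions typical of this domain).
#' @return Tibble `doc_id`, `sentence`, `start_tok`, `end_tok`
#'   (inclusive), `start`, `end` (character offsets), `label`.
#' @export
enumerate_spans <- function(tokens, annotations = NULL, max_width = 12L) {
  stopifnot(max_width >= 1L)
  annotations <- as_annotations(annotations)
  tokens <- dplyr::arrange(tibble::as_tibble(tokens), .data$doc_id,
                           .data$sentence, .data$token_idx)
  out <- tokens %>%
    dplyr::group_by(.data$doc_id, .data$sentence) %>%
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      w <- pmin(max_width, n)
      grid <- purrr::map(seq_len(w), function(width) {
        i <- seq_len(n - width + 1L)
        tibble::tibble(start_tok = i, end_tok = i + width - 1L)
      }) %>% dplyr::bind_rows()
      grid$start <- g$start[grid$start_tok]
      grid$end <- g$end[grid$end_tok]
      grid
    }) %>%
    dplyr::ungroup()
  out$label <- "NONE"
  truncated <- 0L
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    hit <- which(out$doc_id == ann$doc_id & out$start == ann$start &
                   out$end == ann$end)
    if (length(hit) > 0L) {
      out$label[hit] <- ann$category
    } else {
      truncated <- truncated + 1L
    }
  }
  if (truncated > 0L) {
    rlang::inform(paste0(truncated,
      " gold annotation(s) have no candidate (wider than max_width or not token-aligned)."))
  }
  attr(out, "truncated") <- truncated
  dplyr::arrange(out, .data$doc_id, .data$sentence, .data$start_tok,
                 .data$end_tok)
}
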