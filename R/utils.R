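#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Canonical surface-string normalisation used for uniqueness, unseen-ness and
# gazetteer lookup: lower-case and collapse internal whitespace runs to one
# space (extracted article text often wraps spans across lines).
normalize_surface <- function(x) {
  stringr::str_squish(tolower(x))
}

# Empty annotation table with the canonical column set.
empty_annotations <- function() {
  tibble::tibble(
    doc_id = character(),
    annotator_id = character(),
    id = character(),
    category = character(),
    start = integer(),
    end = integer(),
    surface = character()
  )
}

# Coerce/check a data frame of annotations; fills annotator/doc columns when
# a single value is implied, re-derives nothing.
as_annotations <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(empty_annotations())
  }
  stopifnot(is.data.frame(x))
  needed <- c("doc_id", "category", "start", "end", "surface")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    rlang::abort(
      paste0("Annotation table missing column(s): ", paste(missing, collapse = ", ")),
      class = "expocorpus_usage_error"
    )
  }
  out <- tibble::as_tibble(x)
  if (!"annotator_id" %in% names(out)) out$annotator_id <- NA_character_
  if (!"id" %in% names(out)) out$id <- paste0("T", seq_len(nrow(out)))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

# Stable seed derived from a base seed and a string tag, kept within the
# 32-bit integer range so the same stream replays per annotator regardless
# of corpus iteration order.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Shared single-document guard for pairwise operations.
assert_same_document <- function(set_a, set_b) {
  docs_a <- unique(set_a$doc_id)
  docs_b <- unique(set_b$doc_id)
  if (length(docs_a) > 1L || length(docs_b) > 1L) {
    rlang::abort("Each annotation set must cover exactly one document.",
                 class = "expocorpus_usage_error")
  }
  if (length(docs_a) == 1L && length(docs_b) == 1L && docs_a != docs_b) {
    rlang::abort(
      paste0("Annotation sets belong to different documents: ",
             docs_a, " vs ", docs_b),
      class = "expocorpus_usage_error"
    )
  }
  invisible(TRUE)
}
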