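#' Configuration for the synthetic corpus generator
#'
#' Describes the shape of a synthetic annotation project: how many
#' documents, which sections they contain, sentence counts, and per
#' category the expected number of annotations per document, the span
#' length distribution (tokens) and the vocabulary size controlling how
#' often unique spans repeat. The defaults emulate the structure of a
#' consolidated occupational-exposure corpus: substance mentions dominate
#' and repeat heavily, job-task mentions are sparse and mostly unique,
#' personal-sampling evidence is rare but drawn from a tiny phrase
#' inventory.
#'
#' @param n_docs Number of documents.
#' @param sections Section labels per document.
#' @param sentences_per_section Sentences in each section.
#' @param rate Named numeric: expected annotations per document per
#'   category.
#' @param span_mean Named numeric: mean span length in tokens.
#' @param span_max Named integer: maximum span length in tokens.
#' @param vocab_size Named integer: number of distinct entity phrases per
#'   category.
#' @param seed Integer seed; recorded in the output manifest.
#' @param scheme Scheme tibble.
#' @return A validated list of class `expo_genconfig`.
#' @export
generator_config <- function(n_docs = 20L,
                             sections = c("Abstract", "Methods", "Results"),
                             sentences_per_section = 5L,
                             rate = NULL, span_mean = NULL, span_max = NULL,
                             vocab_size = NULL, seed = 1L,
                             scheme = default_scheme()) {
  cats <- scheme_categories(scheme)
  named_default <- function(x, default) {
    if (is.null(x)) {
      return(stats::setNames(default, cats))
    }
    stopifnot(all(names(x) %in% cats))
    out <- stats::setNames(default, cats)
    out[names(x)] <- x
    out
  }
  # scheme order: Substance, Occupation, Industry, JobTask, Device, Personal
  config <- list(
    n_docs = as.integer(n_docs),
    sections = sections,
    sentences_per_section = as.integer(sentences_per_section),
    rate = named_default(rate, c(12, 4, 5, 3, 1.5, 1)),
    span_mean = named_default(span_mean, c(1.8, 1.5, 1.8, 2.5, 2.5, 2.0)),
    span_max = named_default(span_max, rep(6L, length(cats))),
    vocab_size = named_default(vocab_size, c(30L, 25L, 35L, 40L, 16L, 5L)),
    seed = as.integer(seed),
    scheme = scheme
  )
  if (any(config$rate < 0) || any(config$span_mean < 1) ||
      any(config$vocab_size < 1L) || config$n_docs < 1L ||
      config$sentences_per_section < 1L) {
    rlang::abort("Generator rates and sizes must be non-negative and feasible.",
                 class = "expocorpus_config_error")
  }
  if (any(config$span_max > 15L)) {
    rlang::abort("Entity spans longer than a sentence are infeasible.",
                 class = "expocorpus_config_error")
  }
  structure(config, class = "expo_genconfig")
}

filler_lexicon <- c(
  "the", "of", "in", "for", "during", "across", "levels", "samples",
  "were", "collected", "measured", "observed", "study", "results",
  "showed", "exposure", "assessment", "mean", "values", "reported",
  "analysis", "conducted", "at", "each", "site", "over", "period",
  "with", "and", "total", "average", "between", "within", "among",
  "higher", "lower", "concentrations", "data", "from", "all"
)

synthetic_word <- function(n, prefix) {
  syll <- c("ra", "ne", "ko", "li", "mo", "ta", "ve", "su", "pi", "dor",
            "gan", "bel", "tur", "mi", "zol", "fex", "qua", "rin")
  vapply(seq_len(n), function(i) {
    paste0(prefix, paste(sample(syll, sample(2:3, 1), replace = TRUE),
                         collapse = ""))
  }, character(1))
}

build_vocabulary <- function(config) {
  cats <- scheme_categories(config$scheme)
  prefixes <- c("sub", "occ", "ind", "task", "dev", "pers")[seq_along(cats)]
  purrr::map2(cats, prefixes, function(cat, pre) {
    pool <- unique(synthetic_word(4L * config$vocab_size[[cat]], pre))
    purrr::map_chr(seq_len(config$vocab_size[[cat]]), function(i) {
      len <- min(
        1L + stats::rpois(1L, config$span_mean[[cat]] - 1),
        config$span_max[[cat]]
      )
      paste(sample(pool, len, replace = FALSE), collapse = " ")
    }) %>% unique()
  }) %>% stats::setNames(cats)
}

#' Generate a synthetic annotated corpus
#'
#' Builds template-generated English-like documents with section structure
#' and a gold annotation set (`annotator_id = "gold"`). Entity phrases are
#' drawn from per-category vocabularies and embedded between filler words,
#' so every annotation is token-aligned and same-category annotations never
#' overlap. The generator is fully determined by the config seed.
#'
#' Synthetic text carries no real-world meaning; all downstream
#' computations depend only on character offsets and surface strings,
#' which the templates provide.
#'
#' @param config An `expo_genconfig` from [generator_config()].
#' @return A list with `documents`, `sections`, `annotations` (gold) and
#'   `manifest` (the config, seed included).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "expo_genconfig"))
  withr::with_seed(config$seed, {
    cats <- scheme_categories(config$scheme)
    vocab <- build_vocabulary(config)
    n_sent <- length(config$sections) * config$sentences_per_section
    p_sent <- config$rate / n_sent

    docs <- list(); secs <- list(); anns <- list()
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("doc%03d", d)
      text <- ""
      for (sec in config$sections) {
        sec_start <- nchar(text)
        for (s in seq_len(config$sentences_per_section)) {
          cursor <- nchar(text)
          sentence_parts <- character()
          add <- function(word) {
            gap <- if (nchar(text) > cursor || nchar(text) > 0L) " " else ""
            text <<- paste0(text, gap, word)
          }
          # leading filler
          for (w in sample(filler_lexicon, sample(2:4, 1))) add(w)
          for (ci in seq_along(cats)) {
            k <- stats::rpois(1L, p_sent[[ci]])
            for (e in seq_len(k)) {
              phrase <- sample(vocab[[cats[[ci]]]], 1L)
              start <- nchar(text) + 1L  # +1 for the joining space
              add(phrase)
              anns[[length(anns) + 1L]] <- tibble::tibble(
                doc_id = doc_id, annotator_id = "gold",
                category = cats[[ci]],
                start = start, end = start + nchar(phrase),
                surface = phrase
              )
              for (w in sample(filler_lexicon, sample(1:3, 1))) add(w)
            }
          }
          text <- paste0(text, " .")
        }
        secs[[length(secs) + 1L]] <- tibble::tibble(
          doc_id = doc_id, label = sec,
          start = if (sec_start == 0L) 0L else sec_start + 1L,
          end = nchar(text)
        )
      }
      docs[[length(docs) + 1L]] <- tibble::tibble(doc_id = doc_id, text = text)
    }
    annotations <- dplyr::bind_rows(c(list(empty_annotations()), anns))
    if (nrow(annotations) > 0L) {
      annotations <- dplyr::arrange(annotations, .data$doc_id, .data$start)
      annotations$id <- paste0("T", seq_len(nrow(annotations)))
      # same-category duplicates at one position cannot arise by construction,
      # but enforce the set invariant anyway
      annotations <- dplyr::distinct(annotations, .data$doc_id,
                                     .data$category, .data$start, .data$end,
                                     .keep_all = TRUE)
    }
    list(
      documents = dplyr::bind_rows(docs),
      sections = dplyr::bind_rows(secs),
      annotations = annotations,
      manifest = config
    )
  })
}

#' Configuration for the annotator noise model
#'
#' Models the disagreement phenomena seen between human annotators: missed
#' entities, spurious extra spans, boundary jitter, and category
#' confusion.
#'
#' @param p_miss Probability that a gold annotation is dropped.
#' @param lambda_spur Expected spurious annotations per sentence.
#' @param p_jit Probability that a surviving annotation's boundaries
#'   jitter.
#' @param max_shift Maximum boundary shift in tokens.
#' @param confusion Row-stochastic category confusion matrix (rows/cols in
#'   scheme order); `NULL` for the identity (no confusion).
#' @param scheme Scheme tibble.
#' @return A validated list of class `expo_noiseconfig`.
#' @export
noise_config <- function(p_miss = 0.10, lambda_spur = 0.05, p_jit = 0.15,
                         max_shift = 1L, confusion = NULL,
                         scheme = default_scheme()) {
  cats <- scheme_categories(scheme)
  if (is.null(confusion)) {
    confusion <- diag(length(cats))
    dimnames(confusion) <- list(cats, cats)
  }
  if (p_miss < 0 || p_miss > 1 || p_jit < 0 || p_jit > 1 || lambda_spur < 0) {
    rlang::abort("Noise rates out of range.", class = "expocorpus_config_error")
  }
  if (!all(abs(rowSums(confusion) - 1) < 1e-9)) {
    rlang::abort("Confusion matrix rows must sum to 1.",
                 class = "expocorpus_config_error")
  }
  structure(
    list(p_miss = p_miss, lambda_spur = lambda_spur, p_jit = p_jit,
         max_shift = as.integer(max_shift), confusion = confusion,
         scheme = scheme),
    class = "expo_noiseconfig"
  )
}

#' Simulate a noisy annotator over a gold corpus
#'
#' Applies the noise model to the gold annotation set of a (typically
#' synthetic) corpus: each gold annotation is independently dropped with
#' probability `p_miss`; survivors have their category resampled from the
#' confusion row; with probability `p_jit` each boundary shifts by up to
#' `max_shift` tokens (spans stay non-empty, within their sentence, and
#' overlapping the original mention);
#' and spurious annotations over unannotated token windows are added per
#' sentence at rate `lambda_spur`. The random stream is derived from
#' `(seed, annotator_id)`, so one annotator's replay is independent of how
#' many others are simulated.
#'
#' @param corpus A corpus list (`documents`, `sections`, `annotations`
#'   with a gold set).
#' @param noise An `expo_noiseconfig`.
#' @param annotator_id Identifier stamped on the output rows.
#' @param seed Base integer seed.
#' @return An annotation tibble for the simulated annotator.
#' @export
simulate_annotator <- function(corpus, noise = noise_config(),
                               annotator_id = "ann1", seed = 1L) {
  stopifnot(inherits(noise, "expo_noiseconfig"))
  gold <- dplyr::filter(as_annotations(corpus$annotations),
                        .data$annotator_id == "gold")
  gold <- dplyr::arrange(gold, .data$doc_id, .data$start, .data$end,
                         .data$category)
  tokens <- segment_and_tokenize(corpus$documents, corpus$sections)
  cats <- scheme_categories(noise$scheme)

  withr::with_seed(derive_seed(seed, annotator_id), {
    out <- list()
    # token-index view of each gold annotation
    for (i in seq_len(nrow(gold))) {
      ann <- gold[i, ]
      if (stats::runif(1) < noise$p_miss) next
      category <- sample(cats, 1L, prob = noise$confusion[ann$category, ])
      doc_tok <- tokens[tokens$doc_id == ann$doc_id, ]
      first <- which(doc_tok$start == ann$start)[1]
      last <- which(doc_tok$end == ann$end)[1]
      if (is.na(first) || is.na(last)) next
      sent <- doc_tok$sentence[[first]]
      sent_rows <- which(doc_tok$sentence == sent)
      lo <- min(sent_rows); hi <- max(sent_rows)
      if (stats::runif(1) < noise$p_jit && noise$max_shift > 0L) {
        shift <- function(x) {
          max(lo, min(hi, x + sample(seq(-noise$max_shift, noise$max_shift), 1L)))
        }
        first2 <- shift(first)
        last2 <- shift(last)
        # a jittered span stays non-empty and keeps overlapping the original
        # (shifts stay below the span length), mirroring human boundary
        # disagreements which still cover the same mention
        if (first2 <= last2 && first2 <= last && last2 >= first) {
          first <- first2
          last <- last2
        }
      }
      text <- corpus$documents$text[corpus$documents$doc_id == ann$doc_id][[1]]
      out[[length(out) + 1L]] <- tibble::tibble(
        doc_id = ann$doc_id, annotator_id = annotator_id,
        category = category,
        start = doc_tok$start[[first]], end = doc_tok$end[[last]],
        surface = substr(text, doc_tok$start[[first]] + 1L,
                         doc_tok$end[[last]])
      )
    }
    result <- dplyr::bind_rows(c(list(empty_annotations()), out))

    # spurious spans over unannotated windows
    if (noise$lambda_spur > 0) {
      sent_tbl <- dplyr::distinct(tokens, .data$doc_id, .data$sentence)
      for (i in seq_len(nrow(sent_tbl))) {
        k <- stats::rpois(1L, noise$lambda_spur)
        if (k == 0L) next
        g <- tokens[tokens$doc_id == sent_tbl$doc_id[[i]] &
                      tokens$sentence == sent_tbl$sentence[[i]], ]
        text <- corpus$documents$text[
          corpus$documents$doc_id == sent_tbl$doc_id[[i]]][[1]]
        for (e in seq_len(k)) {
          width <- sample(1:3, 1L)
          if (nrow(g) < width) next
          a <- sample(seq_len(nrow(g) - width + 1L), 1L)
          b <- a + width - 1L
          start <- g$start[[a]]; end <- g$end[[b]]
          existing <- result[result$doc_id == sent_tbl$doc_id[[i]], ]
          if (any(pmin(end, existing$end) - pmax(start, existing$start) > 0L)) next
          result <- dplyr::bind_rows(result, tibble::tibble(
            doc_id = sent_tbl$doc_id[[i]], annotator_id = annotator_id,
            category = sample(cats, 1L),
            start = start, end = end,
            surface = substr(text, start + 1L, end)
          ))
        }
      }
    }
    if (nrow(result) > 0L) {
      result <- dplyr::arrange(result, .data$doc_id, .data$start, .data$end)
      result <- dplyr::distinct(result, .data$doc_id, .data$category,
                                .data$start, .data$end, .keep_all = TRUE)
      result$id <- paste0("T", seq_len(nrow(result)))
    }
    as_annotations(result)
  })
}
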