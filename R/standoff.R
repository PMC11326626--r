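#' Parse brat standoff annotation lines
#'
#' Parses the text-bound ("T") lines of a brat `.ann` file against the
#' document text. Each line has the form
#' `T<id>\t<Category> <start> <end>\t<surface>` with 0-based, half-open
#' character offsets. The surface string is re-derived from the offsets and
#' cross-checked against the recorded surface, so that a desynchronised
#' `.txt`/`.ann` pair fails loudly rather than silently shifting spans.
#'
#' Non-text-bound lines (relations `R`, events `E`, attributes `A`/`M`,
#' notes `#`) are ignored. Discontinuous (fragmented) spans are rejected.
#' Duplicate `(category, start, end)` lines are dropped with a warning so
#' that agreement counts never double-count.
#'
#' @param lines Character vector of standoff lines (one element per line).
#' @param text The full document text the offsets refer to.
#' @param scheme A scheme tibble from [load_scheme()].
#' @param doc_id,annotator_id Identifiers recorded on every row.
#'
#' @return A tibble of annotations with columns `doc_id`, `annotator_id`,
#'   `id`, `category`, `start`, `end`, `surface`.
#' @export
parse_standoff <- function(lines, text, scheme = default_scheme(),
                           doc_id = "doc", annotator_id = "annotator") {
  lines <- lines[nzchar(trimws(lines))]
  tb <- lines[startsWith(lines, "T")]
  if (length(tb) == 0L) {
    return(empty_annotations())
  }
  cats <- scheme_categories(scheme)
  n <- nchar(text)

  rows <- purrr::map(tb, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      rlang::abort(paste0("Malformed standoff line: ", line),
                   class = "expocorpus_parse_error")
    }
    ann_id <- fields[[1]]
    mid <- fields[[2]]
    recorded_surface <- if (length(fields) >= 3L) fields[[3]] else ""
    if (grepl(";", mid, fixed = TRUE)) {
      rlang::abort(
        paste0("Discontinuous span not supported: ", line),
        class = "expocorpus_parse_error"
      )
    }
    parts <- strsplit(mid, " ", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      rlang::abort(paste0("Malformed type/offset field: ", line),
                   class = "expocorpus_parse_error")
    }
    k <- length(parts)
    start <- suppressWarnings(as.integer(parts[[k - 1L]]))
    end <- suppressWarnings(as.integer(parts[[k]]))
    category <- paste(parts[seq_len(k - 2L)], collapse = " ")
    if (is.na(start) || is.na(end)) {
      rlang::abort(paste0("Non-numeric offsets: ", line),
                   class = "expocorpus_parse_error")
    }
    if (!category %in% cats) {
      rlang::abort(
        paste0("Category '", category, "' not in scheme (line: ", line, ")"),
        class = "expocorpus_parse_error"
      )
    }
    if (start < 0L || end > n || start >= end) {
      rlang::abort(
        paste0("Offsets [", start, ",", end, ") invalid for text of length ",
               n, " (line: ", line, ")"),
        class = "expocorpus_parse_error"
      )
    }
    sliced <- substr(text, start + 1L, end)
    if (nzchar(recorded_surface) && sliced != recorded_surface) {
      rlang::abort(
        paste0("Surface mismatch for ", ann_id, ": recorded '",
               recorded_surface, "' vs sliced '", sliced,
               "' - .txt and .ann are likely desynchronised"),
        class = "expocorpus_parse_error"
      )
    }
    tibble::tibble(
      doc_id = doc_id, annotator_id = annotator_id, id = ann_id,
      category = category, start = start, end = end, surface = sliced
    )
  })
  out <- dplyr::bind_rows(rows)

  dup <- duplicated(out[, c("category", "start", "end")])
  if (any(dup)) {
    rlang::warn(
      paste0(sum(dup), " duplicate (category, start, end) line(s) dropped in ",
             doc_id, "/", annotator_id)
    )
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Serialise one annotator's set to brat standoff lines
#'
#' Inverse of [parse_standoff()]: annotations are sorted by start offset
#' (then end, then category), renumbered `T1..Tn`, and written one
#' text-bound line each, so parse -> write -> parse is the identity on
#' `(category, start, end, surface)`.
#'
#' @param annotations Annotation tibble for a single document.
#' @param annotator_id Which annotator's set to serialise; required when the
#'   table holds several.
#'
#' @return Character vector of standoff lines (possibly empty).
#' @export
write_standoff <- function(annotations, annotator_id = NULL) {
  annotations <- as_annotations(annotations)
  if (!is.null(annotator_id)) {
    if (!annotator_id %in% annotations$annotator_id && nrow(annotations) > 0L) {
      rlang::abort(paste0("Unknown annotator_id: ", annotator_id),
                   class = "expocorpus_usage_error")
    }
    annotations <- dplyr::filter(annotations, .data$annotator_id == !!annotator_id)
  }
  if (nrow(annotations) == 0L) {
    return(character())
  }
  annotations <- dplyr::arrange(annotations, .data$start, .data$end, .data$category)
  sprintf(
    "T%d\t%s %d %d\t%s",
    seq_len(nrow(annotations)),
    annotations$category, annotations$start, annotations$end,
    annotations$surface
  )
}

#' Read a brat annotation project directory
#'
#' Expects the layout `<project>/<doc_id>/` containing the shared document
#' text `<doc_id>.txt`, one `<annotator_id>.ann` per annotator, and an
#' optional `sections.json` sidecar (`[{"label","start","end"}, ...]`)
#' recording section boundaries (plain `.txt` carries no section markup).
#' Documents without a sidecar get one section spanning the whole text.
#'
#' @param path Project directory.
#' @param scheme Scheme tibble; annotations are validated against it.
#'
#' @return A list with tibbles `documents` (`doc_id`, `text`), `sections`
#'   (`doc_id`, `label`, `start`, `end`) and `annotations`.
#' @export
read_brat_project <- function(path, scheme = default_scheme()) {
  doc_dirs <- list.dirs(path, recursive = FALSE)
  if (length(doc_dirs) == 0L) {
    rlang::abort(paste0("No document directories under ", path),
                 class = "expocorpus_usage_error")
  }
  per_doc <- purrr::map(doc_dirs, function(d) {
    doc_id <- basename(d)
    txt_path <- file.path(d, paste0(doc_id, ".txt"))
    if (!file.exists(txt_path)) {
      rlang::abort(paste0("Missing document text: ", txt_path),
                   class = "expocorpus_parse_error")
    }
    text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
    sec_path <- file.path(d, "sections.json")
    sections <- if (file.exists(sec_path)) {
      s <- jsonlite::read_json(sec_path, simplifyVector = TRUE)
      tibble::tibble(doc_id = doc_id, label = s$label,
                     start = as.integer(s$start), end = as.integer(s$end))
    } else {
      tibble::tibble(doc_id = doc_id, label = "Text",
                     start = 0L, end = nchar(text))
    }
    validate_sections(sections, nchar(text))
    ann_paths <- list.files(d, pattern = "\\.ann$", full.names = TRUE)
    anns <- purrr::map(ann_paths, function(p) {
      parse_standoff(readLines(p, warn = FALSE, encoding = "UTF-8"),
                     text = text, scheme = scheme, doc_id = doc_id,
                     annotator_id = sub("\\.ann$", "", basename(p)))
    })
    list(
      documents = tibble::tibble(doc_id = doc_id, text = text),
      sections = sections,
      annotations = dplyr::bind_rows(anns)
    )
  })
  list(
    documents = dplyr::bind_rows(purrr::map(per_doc, "documents")),
    sections = dplyr::bind_rows(purrr::map(per_doc, "sections")),
    annotations = dplyr::bind_rows(c(list(empty_annotations()),
                                     purrr::map(per_doc, "annotations")))
  )
}

#' Write a brat annotation project directory
#'
#' @param corpus A list with `documents`, `annotations` and optionally
#'   `sections`, as returned by [read_brat_project()] or
#'   [generate_corpus()].
#' @param path Output directory (created if needed).
#'
#' @return `path`, invisibly.
#' @export
write_brat_project <- function(corpus, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  anns <- as_annotations(corpus$annotations)
  for (i in seq_len(nrow(corpus$documents))) {
    doc_id <- corpus$documents$doc_id[[i]]
    d <- file.path(path, doc_id)
    dir.create(d, showWarnings = FALSE)
    writeLines(corpus$documents$text[[i]], file.path(d, paste0(doc_id, ".txt")),
               useBytes = TRUE)
    if (!is.null(corpus$sections)) {
      secs <- dplyr::filter(corpus$sections, .data$doc_id == !!doc_id)
      if (nrow(secs) > 0L) {
        jsonlite::write_json(
          secs[, c("label", "start", "end")],
          file.path(d, "sections.json")
        )
      }
    }
    doc_anns <- dplyr::filter(anns, .data$doc_id == !!doc_id)
    for (ann_id in unique(doc_anns$annotator_id)) {
      writeLines(write_standoff(doc_anns, ann_id),
                 file.path(d, paste0(ann_id, ".ann")), useBytes = TRUE)
    }
  }
  invisible(path)
}

validate_sections <- function(sections, text_length) {
  if (nrow(sections) == 0L) return(invisible(TRUE))
  s <- dplyr::arrange(sections, .data$start)
  if (any(s$start < 0L) || any(s$end > text_length) || any(s$start >= s$end)) {
    rlang::abort("Section boundaries outside [0, text length) or empty.",
                 class = "expocorpus_parse_error")
  }
  if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
    rlang::abort("Sections overlap.", class = "expocorpus_parse_error")
  }
  invisible(TRUE)
}

#' Validate a brat project against a scheme
#'
#' Reads every document and `.ann` file, collecting (rather than raising)
#' parse problems, so a whole project can be audited in one pass.
#'
#' @inheritParams read_brat_project
#' @return A tibble with columns `doc_id`, `annotator_id`, `ok`, `message`.
#' @export
validate_brat_project <- function(path, scheme = default_scheme()) {
  doc_dirs <- list.dirs(path, recursive = FALSE)
  rows <- purrr::map(doc_dirs, function(d) {
    doc_id <- basename(d)
    txt_path <- file.path(d, paste0(doc_id, ".txt"))
    if (!file.exists(txt_path)) {
      return(tibble::tibble(doc_id = doc_id, annotator_id = NA_character_,
                            ok = FALSE, message = "missing .txt"))
    }
    text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
    ann_paths <- list.files(d, pattern = "\\.ann$", full.names = TRUE)
    purrr::map(ann_paths, function(p) {
      aid <- sub("\\.ann$", "", basename(p))
      res <- tryCatch(
        {
          parse_standoff(readLines(p, warn = FALSE, encoding = "UTF-8"),
                         text = text, scheme = scheme,
                         doc_id = doc_id, annotator_id = aid)
          "ok"
        },
        error = function(e) conditionMessage(e)
      )
      tibble::tibble(doc_id = doc_id, annotator_id = aid,
                     ok = identical(res, "ok"),
                     message = if (identical(res, "ok")) NA_character_ else res)
    }) %>% dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
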