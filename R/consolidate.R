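#' Build a consolidation policy
#'
#' A policy assigns each scheme category an action deciding how a secondary
#' annotator's spans are merged into the primary annotator's set:
#' `primary_only` (ignore the secondary), `union` (keep everything,
#' collapsing overlapping same-category spans), `augment_novel` (add only
#' secondary spans overlapping no same-category primary span), or
#' `secondary_only`. Overlapping same-category spans under `union` are
#' collapsed according to `overlap_resolution`.
#'
#' @param scheme Scheme tibble.
#' @param action Default action applied to every category.
#' @param overlap_resolution `"prefer_primary"`, `"prefer_longer"` or
#'   `"prefer_shorter"`.
#' @return A tibble with columns `category`, `action`,
#'   `overlap_resolution`.
#' @export
default_policy <- function(scheme = default_scheme(),
                           action = c("augment_novel", "primary_only",
                                      "union", "secondary_only"),
                           overlap_resolution = c("prefer_primary",
                                                  "prefer_longer",
                                                  "prefer_shorter")) {
  action <- match.arg(action)
  overlap_resolution <- match.arg(overlap_resolution)
  tibble::tibble(
    category = scheme_categories(scheme),
    action = action,
    overlap_resolution = overlap_resolution
  )
}

validate_policy <- function(policy, scheme) {
  cats <- scheme_categories(scheme)
  bad <- setdiff(policy$category, cats)
  if (length(bad) > 0L) {
    rlang::abort(
      paste0("Policy references unknown category: ", paste(bad, collapse = ", ")),
      class = "expocorpus_config_error"
    )
  }
  actions <- c("primary_only", "union", "augment_novel", "secondary_only")
  if (!all(policy$action %in% actions)) {
    rlang::abort("Unknown policy action.", class = "expocorpus_config_error")
  }
  # every scheme category resolves to exactly one action; default fills gaps
  missing <- setdiff(cats, policy$category)
  if (length(missing) > 0L) {
    policy <- dplyr::bind_rows(
      policy,
      tibble::tibble(category = missing, action = "augment_novel",
                     overlap_resolution = "prefer_primary")
    )
  }
  if (anyDuplicated(policy$category)) {
    rlang::abort("Policy lists a category twice.",
                 class = "expocorpus_config_error")
  }
  policy
}

overlaps_any <- function(start, end, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(pmin(end[[i]], ends) - pmax(start[[i]], starts) > 0L)
  }, logical(1))
}

#' Consolidate two annotators' sets into one final set
#'
#' Merges the secondary annotator's set into the primary annotator's set
#' for one document, category by category, according to the policy. Every
#' output annotation carries a `provenance` column (`"primary"` /
#' `"secondary"`), and the merge report reconciles counts exactly:
#' `kept + added` equals the merged-set size per category.
#'
#' @param primary_set,secondary_set Annotation tibbles on the same
#'   document.
#' @param policy Policy tibble from [default_policy()] or
#'   [derive_policy()]; per-pair policies are filtered to this pair
#'   automatically.
#' @param scheme Scheme tibble used to validate the policy.
#'
#' @return A list with `annotations` (the merged set, with `provenance`)
#'   and `report` (per-category `kept`, `added`, `dropped_overlapping`).
#' @export
consolidate <- function(primary_set, secondary_set,
                        policy = default_policy(scheme),
                        scheme = default_scheme()) {
  primary_set <- as_annotations(primary_set)
  secondary_set <- as_annotations(secondary_set)
  if (all(c("annotator_a", "annotator_b") %in% names(policy))) {
    pa <- unique(primary_set$annotator_id)
    pb <- unique(secondary_set$annotator_id)
    sel <- dplyr::filter(policy,
                         .data$annotator_a %in% c(pa, pb),
                         .data$annotator_b %in% c(pa, pb))
    policy <- if (nrow(sel) > 0L) {
      sel[, c("category", "action", "overlap_resolution")]
    } else {
      rlang::warn("Annotator pair absent from policy; using default actions.")
      default_policy(scheme)
    }
  }

  docs <- union(unique(primary_set$doc_id), unique(secondary_set$doc_id))
  if (length(docs) > 1L) {
    # document-wise merge over a whole project
    parts <- purrr::map(docs, function(d) {
      consolidate(dplyr::filter(primary_set, .data$doc_id == d),
                  dplyr::filter(secondary_set, .data$doc_id == d),
                  policy, scheme)
    })
    annotations <- dplyr::bind_rows(purrr::map(parts, "annotations"))
    report <- dplyr::bind_rows(purrr::map(parts, "report")) %>%
      dplyr::group_by(.data$category) %>%
      dplyr::summarise(kept = sum(.data$kept), added = sum(.data$added),
                       dropped_overlapping = sum(.data$dropped_overlapping),
                       .groups = "drop")
    return(list(annotations = annotations, report = report))
  }
  assert_same_document(primary_set, secondary_set)
  policy <- validate_policy(policy, scheme)

  merged <- purrr::map(seq_len(nrow(policy)), function(i) {
    cat <- policy$category[[i]]
    action <- policy$action[[i]]
    res <- policy$overlap_resolution[[i]]
    p <- dplyr::filter(primary_set, .data$category == cat)
    s <- dplyr::filter(secondary_set, .data$category == cat)
    p$provenance <- rep("primary", nrow(p))
    s$provenance <- rep("secondary", nrow(s))
    if (action == "primary_only") {
      keep <- p
      dropped <- nrow(s)
    } else if (action == "secondary_only") {
      keep <- s
      keep$provenance <- rep("primary", nrow(keep))  # acts as the base set
      dropped <- nrow(p)
    } else if (action == "augment_novel") {
      novel <- !overlaps_any(s$start, s$end, p$start, p$end)
      keep <- dplyr::bind_rows(p, s[novel, , drop = FALSE])
      dropped <- sum(!novel)
    } else { # union
      novel <- !overlaps_any(s$start, s$end, p$start, p$end)
      clash <- s[!novel, , drop = FALSE]
      chosen <- p
      dropped <- 0L
      for (j in seq_len(nrow(clash))) {
        hit <- which(overlaps_any(chosen$start, chosen$end,
                                  clash$start[[j]], clash$end[[j]]))
        len_s <- clash$end[[j]] - clash$start[[j]]
        len_p <- max(chosen$end[hit] - chosen$start[hit])
        replace <- switch(res,
          prefer_primary = FALSE,
          prefer_longer = len_s > len_p,
          prefer_shorter = len_s < len_p
        )
        if (replace) {
          chosen <- chosen[-hit, , drop = FALSE]
          chosen <- dplyr::bind_rows(chosen, clash[j, , drop = FALSE])
        } else {
          dropped <- dropped + 1L
        }
      }
      keep <- dplyr::bind_rows(chosen, s[novel, , drop = FALSE])
    }
    keep <- dplyr::distinct(keep, .data$category, .data$start, .data$end,
                            .keep_all = TRUE)
    list(
      annotations = keep,
      report = tibble::tibble(
        category = cat,
        kept = sum(keep$provenance == "primary"),
        added = sum(keep$provenance == "secondary"),
        dropped_overlapping = dropped
      )
    )
  })

  annotations <- dplyr::bind_rows(purrr::map(merged, "annotations"))
  if (nrow(annotations) > 0L) {
    annotations <- dplyr::arrange(annotations, .data$start, .data$end)
    annotations$annotator_id <- "consolidated"
    annotations$id <- paste0("T", seq_len(nrow(annotations)))
  }
  list(
    annotations = annotations,
    report = dplyr::bind_rows(purrr::map(merged, "report"))
  )
}

#' Derive a per-pair consolidation policy from agreement scores
#'
#' Reconstructs a category- and pair-sensitive augmentation policy from an
#' agreement matrix: for each annotator pair and category, the secondary
#' annotator's spans are allowed to augment the primary set
#' (`augment_novel`) when the pair's F1 on that category reaches the
#' threshold, and ignored (`primary_only`) otherwise. The default threshold
#' of 0.70 corresponds to the agreement level conventionally read as strong
#' for span annotation tasks.
#'
#' @param iaa An `expo_iaa` tibble from [iaa_matrix()].
#' @param threshold F1 cutoff in `[0, 1]`.
#' @param scheme Scheme tibble.
#' @return A policy tibble with per-pair rows (`annotator_a`,
#'   `annotator_b`, `category`, `action`, `overlap_resolution`).
#' @export
derive_policy <- function(iaa, threshold = 0.70, scheme = default_scheme()) {
  x <- tibble::as_tibble(iaa)
  assert_category(unique(x$category), scheme)
  x %>%
    dplyr::transmute(
      .data$annotator_a, .data$annotator_b, .data$category,
      action = ifelse(.data$f1 >= threshold, "augment_novel", "primary_only"),
      overlap_resolution = "prefer_primary"
    )
}

#' Read/write a consolidation policy as JSON
#'
#' @param policy Policy tibble.
#' @param path File path.
#' @return `read_policy()` returns the policy tibble; `write_policy()`
#'   returns `path` invisibly.
#' @export
write_policy <- function(policy, path) {
  jsonlite::write_json(policy, path, dataframe = "rows")
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
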