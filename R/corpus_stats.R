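#' Per-category corpus statistics
#'
#' For each scheme category: the total number of annotated spans, the
#' number of distinct surface strings after lower-casing (with internal
#' whitespace runs collapsed), and the unique-span frequency — the average
#' number of times each distinct span was annotated, `total / unique`
#' rounded to 2 decimals. Categories with no annotations report zero
#' frequency and are flagged `empty`.
#'
#' @param annotations Annotation tibble (typically the consolidated gold
#'   corpus).
#' @param scheme Scheme tibble; rows come out in scheme order.
#' @return Tibble with columns `category`, `total`, `unique`, `frequency`,
#'   `empty`.
#' @export
category_statistics <- function(annotations, scheme = default_scheme()) {
  annotations <- as_annotations(annotations)
  cats <- scheme_categories(scheme)
  counts <- annotations %>%
    dplyr::mutate(norm = normalize_surface(.data$surface)) %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(total = dplyr::n(),
                     unique = dplyr::n_distinct(.data$norm),
                     .groups = "drop")
  tibble::tibble(category = cats) %>%
    dplyr::left_join(counts, by = "category") %>%
    dplyr::mutate(
      total = dplyr::coalesce(.data$total, 0L),
      unique = dplyr::coalesce(.data$unique, 0L),
      empty = .data$total == 0L,
      frequency = ifelse(.data$empty, 0, round(.data$total / .data$unique, 2))
    ) %>%
    dplyr::select("category", "total", "unique", "frequency", "empty")
}

#' Count and share of selected surface forms within a category
#'
#' How many annotations in a category carry one of the given (lowercased)
#' surface forms, and what share of the category total they account for,
#' reported as a whole percent.
#'
#' @param annotations Annotation tibble.
#' @param category A scheme category.
#' @param surface_forms Character vector of lowercased surface strings.
#' @param scheme Scheme tibble.
#' @return A one-row tibble: `category`, `count`, `total`, `share_pct`.
#' @export
span_frequency <- function(annotations, category, surface_forms,
                           scheme = default_scheme()) {
  assert_category(category, scheme)
  annotations <- as_annotations(annotations)
  in_cat <- dplyr::filter(annotations, .data$category == !!category)
  total <- nrow(in_cat)
  count <- sum(normalize_surface(in_cat$surface) %in%
                 normalize_surface(surface_forms))
  tibble::tibble(
    category = category,
    count = count,
    total = total,
    share_pct = if (total > 0L) round(100 * count / total) else 0
  )
}

#' Fraction of test annotations with spans unseen in training
#'
#' For each category, the fraction of test annotations whose lowercased
#' surface string occurs in no training annotation of the same category —
#' a direct measure of how much a memorising model could possibly recall.
#' Unseen-ness is scoped within category: a surface seen in training under
#' a different category still counts as unseen. `global = TRUE` switches to
#' corpus-global surface matching.
#'
#' @param train,test Annotation tibbles over disjoint document sets.
#' @param scheme Scheme tibble.
#' @param global If `TRUE`, a test surface is "seen" if any training
#'   category contains it.
#' @return Tibble with `category`, `n_test`, `n_unseen`,
#'   `unseen_fraction` (in `[0, 1]`, `NA` and flagged `undefined` for empty
#'   test categories).
#' @export
unseen_fraction <- function(train, test, scheme = default_scheme(),
                            global = FALSE) {
  train <- as_annotations(train)
  test <- as_annotations(test)
  shared_docs <- intersect(unique(train$doc_id), unique(test$doc_id))
  if (length(shared_docs) > 0L) {
    rlang::abort("Train and test sets share document(s); splits must be disjoint.",
                 class = "expocorpus_usage_error")
  }
  cats <- scheme_categories(scheme)
  purrr::map(cats, function(cat) {
    te <- dplyr::filter(test, .data$category == cat)
    tr <- if (global) train else dplyr::filter(train, .data$category == cat)
    seen <- unique(normalize_surface(tr$surface))
    n_test <- nrow(te)
    n_unseen <- sum(!normalize_surface(te$surface) %in% seen)
    tibble::tibble(
      category = cat, n_test = n_test, n_unseen = n_unseen,
      unseen_fraction = if (n_test > 0L) n_unseen / n_test else NA_real_,
      undefined = n_test == 0L
    )
  }) %>% dplyr::bind_rows()
}

#' Aggregate unseen-span reports over cross-validation folds
#'
#' @param reports List of tibbles from [unseen_fraction()], one per fold.
#' @return Tibble with per-category mean and standard deviation of the
#'   unseen fraction (population SD over folds), plus fold count.
#' @export
aggregate_unseen <- function(reports) {
  dplyr::bind_rows(reports, .id = "fold") %>%
    dplyr::filter(!.data$undefined) %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(
      n_folds = dplyr::n(),
      mean_unseen = mean(.data$unseen_fraction),
      sd_unseen = if (dplyr::n() > 1L) {
        stats::sd(.data$unseen_fraction) * sqrt((dplyr::n() - 1) / dplyr::n())
      } else {
        0
      },
      .groups = "drop"
    )
}
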