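#' Score predicted annotations against gold
#'
#' Uses the same exact/relaxed span-matching machinery as inter-annotator
#' agreement, but asymmetrically: precision is measured over the
#' predictions, recall over the gold annotations. Counts are pooled over
#' all documents present in the gold set, per category, and the `Overall`
#' row is the micro average (pooled tp/fp/fn across categories);
#' `overall = "macro"` instead averages the per-category metrics.
#'
#' An empty prediction set against non-empty gold yields recall 0 and
#' precision reported as 0 with the `undefined_precision` flag set.
#'
#' @param gold,predicted Annotation tibbles (one or more documents).
#' @param mode `"exact"` or `"relaxed"`.
#' @param scheme Scheme tibble.
#' @param overall `"micro"` (default) or `"macro"`.
#' @return A tibble of class `expo_eval` with one row per category plus an
#'   `"Overall"` row: `category`, `mode`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `undefined_precision`.
#' @export
score_predictions <- function(gold, predicted, mode = c("exact", "relaxed"),
                              scheme = default_scheme(),
                              overall = c("micro", "macro")) {
  mode <- match.arg(mode)
  overall <- match.arg(overall)
  gold <- as_annotations(gold)
  predicted <- as_annotations(predicted)
  docs <- union(unique(gold$doc_id), unique(predicted$doc_id))
  cats <- scheme_categories(scheme)

  per_cat <- purrr::map(cats, function(cat) {
    counts <- purrr::map(docs, function(d) {
      g <- dplyr::filter(gold, .data$doc_id == d)
      p <- dplyr::filter(predicted, .data$doc_id == d)
      g$doc_id <- d
      p$doc_id <- d
      m <- match_spans(g, p, cat, mode)
      c(tp = m$tp, fp = m$fp, fn = m$fn)
    })
    tp <- sum(purrr::map_dbl(counts, "tp"))
    fp <- sum(purrr::map_dbl(counts, "fp"))
    fn <- sum(purrr::map_dbl(counts, "fn"))
    s <- prf_from_counts(tp, fp, fn)
    tibble::tibble(
      category = cat, mode = mode,
      tp = tp, fp = fp, fn = fn,
      precision = s[["precision"]], recall = s[["recall"]], f1 = s[["f1"]],
      undefined_precision = tp + fp == 0L & tp + fn > 0L
    )
  }) %>% dplyr::bind_rows()

  if (overall == "micro") {
    tp <- sum(per_cat$tp)
    fp <- sum(per_cat$fp)
    fn <- sum(per_cat$fn)
    s <- prf_from_counts(tp, fp, fn)
    ov <- tibble::tibble(
      category = "Overall", mode = mode, tp = tp, fp = fp, fn = fn,
      precision = s[["precision"]], recall = s[["recall"]], f1 = s[["f1"]],
      undefined_precision = tp + fp == 0L & tp + fn > 0L
    )
  } else {
    active <- per_cat[per_cat$tp + per_cat$fp + per_cat$fn > 0L, ]
    ov <- tibble::tibble(
      category = "Overall", mode = mode,
      tp = sum(per_cat$tp), fp = sum(per_cat$fp), fn = sum(per_cat$fn),
      precision = mean(active$precision), recall = mean(active$recall),
      f1 = mean(active$f1), undefined_precision = FALSE
    )
  }
  out <- dplyr::bind_rows(per_cat, ov)
  structure(out, class = c("expo_eval", class(out)))
}

#' Aggregate evaluation reports over cross-validation folds
#'
#' @param reports List of `expo_eval` tibbles with a common mode, one per
#'   fold.
#' @param sd `"population"` (default) or `"sample"` standard deviation.
#' @return Tibble with, per category and metric, the mean and standard
#'   deviation over folds and the fold count. Values keep full precision;
#'   round for presentation.
#' @export
aggregate_folds <- function(reports, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  if (length(reports) < 2L) {
    rlang::abort("aggregate_folds() needs >= 2 fold reports.",
                 class = "expocorpus_usage_error")
  }
  modes <- unique(purrr::map_chr(reports, ~ unique(.x$mode)))
  if (length(modes) != 1L) {
    rlang::abort("All fold reports must share one matching mode.",
                 class = "expocorpus_usage_error")
  }
  sd_fun <- function(x) {
    s <- stats::sd(x)
    if (sd == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  dplyr::bind_rows(reports, .id = "fold_id") %>%
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") %>%
    dplyr::group_by(.data$category, .data$mode, .data$metric) %>%
    dplyr::summarise(
      n_folds = dplyr::n(),
      mean = mean(.data$value),
      sd = sd_fun(.data$value),
      .groups = "drop"
    )
}

#' @exportS3Method generics::tidy
tidy.expo_eval <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.expo_eval <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::filter(.data$category == "Overall") %>%
    dplyr::select("mode", "precision", "recall", "f1", "tp", "fp", "fn")
}

#' Bar chart of per-category evaluation metrics
#'
#' @param object An `expo_eval` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.expo_eval <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = paste0("Score (", unique(df$mode), " matching)"),
      title = "NER evaluation by category"
    ) +
    ggplot2::theme_minimal()
}
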