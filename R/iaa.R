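#' Pairwise inter-annotator agreement matrix
#'
#' For every unordered annotator pair sharing at least one document,
#' computes per-category precision/recall/F1 under the requested matching
#' mode. By default true/false positive/negative counts are pooled over all
#' shared documents before one score is computed per pair and category
#' (micro pooling); `pooling = "average"` instead averages per-document F1,
#' for sensitivity analyses.
#'
#' @param annotations Annotation tibble covering 2+ annotators (column
#'   `annotator_id`) over 1+ documents (column `doc_id`).
#' @param mode `"exact"` or `"relaxed"` span matching.
#' @param scheme Scheme tibble; one score row is produced per category.
#' @param pooling `"micro"` (pool counts, default) or `"average"`.
#'
#' @return A tibble of class `expo_iaa` with one row per (pair, category):
#'   `annotator_a`, `annotator_b` (sorted so `a < b`), `category`, `mode`,
#'   `n_docs`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, `vacuous`.
#'   Returns an empty tibble with a warning if no pair shares a document.
#' @export
iaa_matrix <- function(annotations, mode = c("exact", "relaxed"),
                       scheme = default_scheme(),
                       pooling = c("micro", "average")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  annotations <- as_annotations(annotations)
  cats <- scheme_categories(scheme)

  coverage <- dplyr::distinct(annotations, .data$doc_id, .data$annotator_id)
  pairs <- coverage %>%
    dplyr::inner_join(coverage, by = "doc_id", relationship = "many-to-many",
                      suffix = c("_a", "_b")) %>%
    dplyr::filter(.data$annotator_id_a < .data$annotator_id_b)
  if (nrow(pairs) == 0L) {
    rlang::warn("No annotator pair shares a document; empty agreement matrix.")
    out <- tibble::tibble(
      annotator_a = character(), annotator_b = character(),
      category = character(), mode = character(), n_docs = integer(),
      tp = integer(), fp = integer(), fn = integer(),
      precision = double(), recall = double(), f1 = double(),
      vacuous = logical()
    )
    return(structure(out, class = c("expo_iaa", class(out))))
  }

  per_pair <- pairs %>%
    dplyr::group_by(.data$annotator_id_a, .data$annotator_id_b) %>%
    dplyr::group_modify(function(g, key) {
      scores <- purrr::map(cats, function(cat) {
        per_doc <- purrr::map(g$doc_id, function(d) {
          set_a <- dplyr::filter(annotations, .data$doc_id == d,
                                 .data$annotator_id == key$annotator_id_a)
          set_b <- dplyr::filter(annotations, .data$doc_id == d,
                                 .data$annotator_id == key$annotator_id_b)
          set_a$doc_id <- d
          set_b$doc_id <- d
          pairwise_f1(set_a, set_b, cat, mode)
        }) %>% dplyr::bind_rows()
        tp <- sum(per_doc$tp)
        fp <- sum(per_doc$fp)
        fn <- sum(per_doc$fn)
        vac <- tp + fp + fn == 0L
        if (pooling == "micro") {
          s <- if (vac) c(precision = 1, recall = 1, f1 = 1) else prf_from_counts(tp, fp, fn)
        } else {
          s <- c(precision = mean(per_doc$precision),
                 recall = mean(per_doc$recall),
                 f1 = mean(per_doc$f1))
        }
        tibble::tibble(
          category = cat, mode = mode, n_docs = nrow(g),
          tp = tp, fp = fp, fn = fn,
          precision = s[["precision"]], recall = s[["recall"]],
          f1 = s[["f1"]], vacuous = vac
        )
      })
      dplyr::bind_rows(scores)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::rename(annotator_a = "annotator_id_a", annotator_b = "annotator_id_b")

  structure(per_pair, class = c("expo_iaa", class(per_pair)))
}

#' Per-pair mean agreement over categories
#'
#' Collapses an agreement matrix to one unweighted mean-F1 row per
#' annotator pair — the quantity annotator ranking is based on.
#'
#' @param iaa An `expo_iaa` tibble from [iaa_matrix()].
#' @param vacuous `"include"` (vacuously perfect categories count as F1 = 1,
#'   default) or `"exclude"` (dropped from the mean).
#'
#' @return Tibble with `annotator_a`, `annotator_b`, `mode`, `mean_f1`,
#'   `n_categories`.
#' @export
pair_mean_f1 <- function(iaa, vacuous = c("include", "exclude")) {
  vacuous <- match.arg(vacuous)
  x <- tibble::as_tibble(iaa)
  if (vacuous == "exclude") {
    x <- dplyr::filter(x, !.data$vacuous)
  }
  x %>%
    dplyr::group_by(.data$annotator_a, .data$annotator_b, .data$mode) %>%
    dplyr::summarise(mean_f1 = mean(.data$f1),
                     n_categories = dplyr::n(), .groups = "drop")
}

#' Box-and-whisker summary of a score distribution
#'
#' Summarises a set of pairwise agreement scores (or any numeric values)
#' with the usual box-plot statistics: quartiles by linear interpolation
#' between order statistics (quantile type 7), whiskers at the most extreme
#' data points within 1.5 interquartile ranges of the box, and everything
#' beyond the whiskers listed as outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @param labels Optional labels (e.g. annotator pairs) carried into the
#'   outlier listing.
#'
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, and a list-column `outliers` holding a
#'   tibble (`label`, `value`).
#' @export
distribution_summary <- function(values, labels = NULL) {
  if (length(values) < 1L || all(is.na(values))) {
    rlang::abort("distribution_summary() needs at least one value.",
                 class = "expocorpus_usage_error")
  }
  if (is.null(labels)) labels <- as.character(seq_along(values))
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q1 <- q[[1]]
  med <- q[[2]]
  q3 <- q[[3]]
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  whisker_low <- min(values[inside])
  whisker_high <- max(values[inside])
  out_idx <- which(!inside)
  tibble::tibble(
    n = length(values), median = med, q1 = q1, q3 = q3, iqr = iqr,
    whisker_low = whisker_low, whisker_high = whisker_high,
    outliers = list(tibble::tibble(label = labels[out_idx],
                                   value = values[out_idx]))
  )
}

#' Rank annotators and split them into primary/secondary groups
#'
#' Each annotator's score is the mean of its per-pair mean-over-categories
#' F1 with every partner it shares documents with. Annotators are sorted by
#' descending score (ties broken lexicographically by annotator id, with a
#' notice) and the top half forms the primary group. With an odd annotator
#' count the primary group takes the extra member, with a warning.
#'
#' @inheritParams pair_mean_f1
#' @return A tibble of class `expo_grouping`: `annotator`, `mean_f1`,
#'   `rank`, `group` (`"primary"`/`"secondary"`).
#' @export
rank_and_group <- function(iaa, vacuous = c("include", "exclude")) {
  means <- pair_mean_f1(iaa, vacuous = vacuous)
  long <- dplyr::bind_rows(
    dplyr::transmute(means, annotator = .data$annotator_a, f1 = .data$mean_f1),
    dplyr::transmute(means, annotator = .data$annotator_b, f1 = .data$mean_f1)
  )
  if (nrow(long) == 0L || dplyr::n_distinct(long$annotator) < 2L) {
    rlang::abort("Ranking needs an agreement matrix covering >= 2 annotators.",
                 class = "expocorpus_usage_error")
  }
  scores <- long %>%
    dplyr::group_by(.data$annotator) %>%
    dplyr::summarise(mean_f1 = mean(.data$f1), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$mean_f1), .data$annotator)
  if (anyDuplicated(scores$mean_f1)) {
    rlang::inform("Tied mean IAA scores broken lexicographically by annotator id.")
  }
  n <- nrow(scores)
  if (n %% 2L == 1L) {
    rlang::warn("Odd annotator count: primary group takes the extra member.")
  }
  n_primary <- ceiling(n / 2)
  out <- scores %>%
    dplyr::mutate(
      rank = dplyr::row_number(),
      group = ifelse(.data$rank <= n_primary, "primary", "secondary")
    )
  structure(out, class = c("expo_grouping", class(out)))
}

#' @exportS3Method generics::tidy
tidy.expo_iaa <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.expo_iaa <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::summarise(
      n_pairs = dplyr::n_distinct(paste(.data$annotator_a, .data$annotator_b)),
      n_categories = dplyr::n_distinct(.data$category),
      mean_f1 = mean(.data$f1),
      min_f1 = min(.data$f1),
      max_f1 = max(.data$f1)
    )
}

#' Box-plot of pairwise agreement by category
#'
#' Draws the distribution of per-pair F1 scores for each category, whiskers
#' at the most extreme points within 1.5 IQR of the box — the standard view
#' for judging how evenly an annotator team applies the guidelines.
#'
#' @param object An `expo_iaa` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.expo_iaa <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$f1)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1) +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = paste0("Pairwise IAA (F1, ", unique(df$mode), " matching)"),
      title = "Distribution of pairwise inter-annotator agreement"
    ) +
    ggplot2::theme_minimal()
}
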