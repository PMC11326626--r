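#' Seeded sentence-level cross-validation and held-out splits
#'
#' Draws a held-out set (10% of sentences by default), partitions the
#' remaining sentences into `k` folds of near-equal size (differing by at
#' most one), and additionally records a train/dev/test assignment for the
#' held-out protocol: the held-out sentences are the test set, a further
#' `dev_frac` of the corpus is the development set, and the rest trains.
#' The same seed always reproduces the same split.
#'
#' @param sentences Tibble with one row per sentence (`doc_id`,
#'   `sentence`); a token tibble is collapsed automatically.
#' @param k Number of folds.
#' @param holdout_frac,dev_frac Fractions of all sentences for the
#'   held-out test set and the development set.
#' @param seed Integer seed recorded on the result.
#' @return Tibble `doc_id`, `sentence`, `fold` (1..k, `NA` for held-out),
#'   `split` (`"train"`/`"dev"`/`"test"`); seed stored as attribute
#'   `"seed"`.
#' @export
make_folds <- function(sentences, k = 10L, holdout_frac = 0.10,
                       dev_frac = 0.10, seed = 1L) {
  sentences <- dplyr::distinct(tibble::as_tibble(sentences),
                               .data$doc_id, .data$sentence)
  sentences <- dplyr::arrange(sentences, .data$doc_id, .data$sentence)
  n <- nrow(sentences)
  n_hold <- round(n * holdout_frac)
  if (n - n_hold < k) {
    rlang::abort(
      paste0("Need at least ", k, " non-holdout sentences, have ", n - n_hold),
      class = "expocorpus_usage_error"
    )
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  hold_idx <- perm[seq_len(n_hold)]
  rest <- perm[-seq_len(n_hold)]
  n_dev <- round(n * dev_frac)

  fold <- rep(NA_integer_, n)
  fold[rest] <- rep(seq_len(k), length.out = length(rest))
  split <- rep("train", n)
  split[hold_idx] <- "test"
  split[rest[seq_len(min(n_dev, length(rest)))]] <- "dev"

  out <- sentences
  out$fold <- fold
  out$split <- split
  attr(out, "seed") <- as.integer(seed)
  out
}
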