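#' Match annotation spans between two annotators
#'
#' One-to-one matching of same-category annotations between two sets on the
#' same document. Under `"exact"` matching two annotations pair only when
#' their `(category, start, end)` are identical; under `"relaxed"` matching
#' it is enough for two same-category spans to overlap by at least one
#' character. Multiple overlaps are resolved greedily by descending overlap
#' length, ties broken by the earlier start in set A, then in set B, and
#' the greedy seed is then extended along alternating paths so the matching
#' always has maximum cardinality. The result is deterministic.
#'
#' @param set_a,set_b Annotation tibbles on the same document. By
#'   convention A is the reference: unmatched A annotations count as false
#'   negatives and unmatched B annotations as false positives.
#' @param category Single category to match within.
#' @param mode `"exact"` or `"relaxed"`.
#'
#' @return A list with `matched` (tibble of paired rows `idx_a`, `idx_b`,
#'   `overlap`), `unmatched_a`, `unmatched_b` (row indices), and counts
#'   `tp`, `fp`, `fn`.
#' @export
match_spans <- function(set_a, set_b, category,
                        mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  set_a <- as_annotations(set_a)
  set_b <- as_annotations(set_b)
  assert_same_document(set_a, set_b)

  ia <- which(set_a$category == category)
  ib <- which(set_b$category == category)
  a <- set_a[ia, , drop = FALSE]
  b <- set_b[ib, , drop = FALSE]

  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(
      matched = tibble::tibble(idx_a = integer(), idx_b = integer(),
                               overlap = integer()),
      unmatched_a = ia, unmatched_b = ib,
      tp = 0L, fp = length(ib), fn = length(ia)
    ))
  }

  # candidate pairs with their overlap lengths
  grid <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  ov <- pmin(a$end[grid$i], b$end[grid$j]) - pmax(a$start[grid$i], b$start[grid$j])
  keep <- if (mode == "exact") {
    a$start[grid$i] == b$start[grid$j] & a$end[grid$i] == b$end[grid$j]
  } else {
    ov > 0L
  }
  grid <- grid[keep, , drop = FALSE]
  ov <- ov[keep]

  # greedy seed matching by descending overlap, deterministic tie-breaks
  ord <- order(-ov, a$start[grid$i], b$start[grid$j])
  match_of_a <- rep(NA_integer_, nrow(a))  # a index -> b index
  match_of_b <- rep(NA_integer_, nrow(b))
  for (k in ord) {
    i <- grid$i[[k]]
    j <- grid$j[[k]]
    if (is.na(match_of_a[[i]]) && is.na(match_of_b[[j]])) {
      match_of_a[[i]] <- j
      match_of_b[[j]] <- i
    }
  }

  # augment to a maximum-cardinality matching (authoritative when greedy
  # selection leaves an augmenting path); neighbour order keeps the result
  # deterministic
  adj <- lapply(seq_len(nrow(a)), function(i) {
    js <- grid$j[grid$i == i]
    js[order(-ov[grid$i == i], js)]
  })
  try_augment <- function(i, visited) {
    for (j in adj[[i]]) {
      if (!visited[[j]]) {
        visited[[j]] <- TRUE
        owner <- match_of_b[[j]]
        if (is.na(owner)) {
          match_of_a[[i]] <<- j
          match_of_b[[j]] <<- i
          return(list(ok = TRUE, visited = visited))
        }
        res <- try_augment(owner, visited)
        visited <- res$visited
        if (res$ok) {
          match_of_a[[i]] <<- j
          match_of_b[[j]] <<- i
          return(list(ok = TRUE, visited = visited))
        }
      }
    }
    list(ok = FALSE, visited = visited)
  }
  for (i in order(a$start, a$end)) {
    if (is.na(match_of_a[[i]])) {
      try_augment(i, rep(FALSE, nrow(b)))
    }
  }

  mi <- which(!is.na(match_of_a))
  mj <- match_of_a[mi]
  matched <- tibble::tibble(
    idx_a = ia[mi],
    idx_b = ib[mj],
    overlap = as.integer(pmin(a$end[mi], b$end[mj]) -
                           pmax(a$start[mi], b$start[mj]))
  )
  list(
    matched = matched,
    unmatched_a = ia[is.na(match_of_a)],
    unmatched_b = ib[is.na(match_of_b)],
    tp = nrow(matched),
    fp = sum(is.na(match_of_b)),
    fn = sum(is.na(match_of_a))
  )
}

prf_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Pairwise agreement F1 for one category
#'
#' Precision is computed over set B (treating A as reference), recall over
#' set A; F1 is their harmonic mean and is symmetric in the two annotators.
#' When both annotators marked nothing in the category, agreement is
#' vacuously perfect: the score is 1 and the row is flagged `vacuous` so
#' that downstream averaging can exclude it if desired.
#'
#' @inheritParams match_spans
#' @return A one-row tibble: `category`, `mode`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `support_a`, `support_b`, `vacuous`.
#' @export
pairwise_f1 <- function(set_a, set_b, category,
                        mode = c("exact", "relaxed")) {
  mode <- match.arg(mode)
  m <- match_spans(set_a, set_b, category, mode)
  support_a <- m$tp + m$fn
  support_b <- m$tp + m$fp
  vacuous <- support_a == 0L && support_b == 0L
  s <- if (vacuous) {
    c(precision = 1, recall = 1, f1 = 1)
  } else {
    prf_from_counts(m$tp, m$fp, m$fn)
  }
  tibble::tibble(
    category = category, mode = mode,
    tp = m$tp, fp = m$fp, fn = m$fn,
    precision = s[["precision"]], recall = s[["recall"]], f1 = s[["f1"]],
    support_a = support_a, support_b = support_b, vacuous = vacuous
  )
}
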