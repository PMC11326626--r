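# Shorthand builder for annotation tables in tests.
ann <- function(category, start, end, doc_id = "d1", annotator_id = "a",
                surface = NULL, text = NULL) {
  n <- length(start)
  if (is.null(surface)) {
    surface <- if (!is.null(text)) {
      substr(rep(text, n), start + 1L, end)
    } else {
      sprintf("s%d_%d", start, end)
    }
  }
  tibble::tibble(
    doc_id = doc_id, annotator_id = annotator_id,
    id = paste0("T", seq_len(n)),
    category = category, start = as.integer(start), end = as.integer(end),
    surface = surface
  )
}

# Independent oracle: maximum-cardinality one-to-one matching by exhaustive
# recursion over all assignments of A-annotations to compatible, unused
# B-annotations. Only used on tiny sets.
max_matching_oracle <- function(set_a, set_b, category, mode) {
  a <- set_a[set_a$category == category, , drop = FALSE]
  b <- set_b[set_b$category == category, , drop = FALSE]
  na <- nrow(a)
  nb <- nrow(b)
  compatible <- function(i, j) {
    if (mode == "exact") {
      a$start[i] == b$start[j] && a$end[i] == b$end[j]
    } else {
      min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) > 0
    }
  }
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (i > na) {
      best <<- max(best, count)
      return(invisible(NULL))
    }
    if (count + (na - i + 1L) <= best) return(invisible(NULL))
    recurse(i + 1L, used_b, count)  # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && compatible(i, j)) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nb), 0L)
  best
}

# Independent oracle for box statistics: explicit type-7 interpolation and
# 1.5 IQR fences, written without quantile().
boxstats_oracle <- function(values) {
  x <- sort(values)
  n <- length(x)
  q_at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- q_at(0.25)
  q3 <- q_at(0.75)
  iqr <- q3 - q1
  inside <- x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr
  list(
    median = q_at(0.5), q1 = q1, q3 = q3, iqr = iqr,
    whisker_low = min(x[inside]), whisker_high = max(x[inside]),
    outliers = sort(x[!inside])
  )
}

# Random annotation set generator for property tests: spans over a short
# integer line, a couple of categories, possible overlaps/duplicates.
random_annset <- function(n, categories = c("X", "Y"), doc_id = "d1",
                          annotator_id = "a", line = 40L) {
  if (n == 0L) {
    return(ann(character(), integer(), integer(), doc_id, annotator_id))
  }
  start <- sample.int(line - 2L, n, replace = TRUE) - 1L
  len <- sample.int(6L, n, replace = TRUE)
  end <- pmin(start + len, line)
  out <- ann(sample(categories, n, replace = TRUE), start, end,
             doc_id, annotator_id)
  dplyr::distinct(out, .data$category, .data$start, .data$end, .keep_all = TRUE)
}

# Tiny deterministic two-annotator corpus used across module tests.
tiny_corpus <- function(seed = 11L) {
  corp <- generate_corpus(generator_config(n_docs = 3, seed = seed))
  a1 <- simulate_annotator(corp, noise_config(), "ann1", seed = seed)
  a2 <- simulate_annotator(corp, noise_config(), "ann2", seed = seed)
  list(corpus = corp, a1 = a1, a2 = a2)
}
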