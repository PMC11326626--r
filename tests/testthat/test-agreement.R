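test_that("span matching follows the exact and relaxed definitions", {
  a <- ann("X", 0, 5)
  b <- ann("X", 0, 5, annotator_id = "b")
  for (mode in c("exact", "relaxed")) {
    m <- match_spans(a, b, "X", mode)
    expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  }

  a <- ann("X", 0, 10)
  b <- ann("X", 5, 15, annotator_id = "b")
  m_ex <- match_spans(a, b, "X", "exact")
  expect_equal(c(m_ex$tp, m_ex$fp, m_ex$fn), c(0L, 1L, 1L))
  m_rx <- match_spans(a, b, "X", "relaxed")
  expect_equal(c(m_rx$tp, m_rx$fp, m_rx$fn), c(1L, 0L, 0L))

  # one-to-one: a single reference span cannot absorb two overlapping spans
  a <- ann("X", 0, 10)
  b <- ann(c("X", "X"), c(0, 2), c(10, 8), annotator_id = "b")
  m <- match_spans(a, b, "X", "relaxed")
  expect_equal(c(m$tp, m$fp), c(1L, 1L))
  expect_equal(m$tp, max_matching_oracle(a, b, "X", "relaxed"))

  expect_error(
    match_spans(ann("X", 0, 5, doc_id = "d1"),
                ann("X", 0, 5, doc_id = "d2"), "X"),
    class = "expocorpus_usage_error"
  )
})

test_that("greedy one-to-one matching attains the maximum-cardinality oracle", {
  withr::with_seed(2024, {
    for (rep in 1:300) {
      a <- random_annset(sample(0:6, 1), annotator_id = "a")
      b <- random_annset(sample(0:6, 1), annotator_id = "b")
      for (mode in c("exact", "relaxed")) {
        m <- match_spans(a, b, "X", mode)
        expect_identical(m$tp, max_matching_oracle(a, b, "X", mode))
      }
    }
  })
})

test_that("pairwise F1 obeys the harmonic-mean identity, symmetry and vacuous rule", {
  a <- ann(c("X", "X"), c(0, 20), c(5, 25))
  b <- ann(c("X", "X"), c(0, 30), c(5, 35), annotator_id = "b")
  s <- pairwise_f1(a, b, "X", "exact")
  expect_equal(c(s$tp, s$fp, s$fn), c(1L, 1L, 1L))
  expect_equal(c(s$precision, s$recall, s$f1), c(0.5, 0.5, 0.5))

  s_id <- pairwise_f1(a, a, "X", "exact")
  expect_equal(s_id$f1, 1)

  # disjoint categories score zero in both directions
  a <- ann("X", 0, 5)
  b <- ann("Y", 0, 5, annotator_id = "b")
  expect_equal(pairwise_f1(a, b, "X", "relaxed")$f1, 0)
  expect_equal(pairwise_f1(a, b, "Y", "relaxed")$f1, 0)

  # empty-vs-empty is vacuously perfect and flagged
  s_v <- pairwise_f1(a, b, "Z", "exact")
  expect_true(s_v$vacuous)
  expect_equal(s_v$f1, 1)

  # symmetry: F1 invariant, precision and recall swap
  withr::with_seed(99, {
    for (rep in 1:50) {
      a <- random_annset(sample(1:6, 1), annotator_id = "a")
      b <- random_annset(sample(1:6, 1), annotator_id = "b")
      for (mode in c("exact", "relaxed")) {
        ab <- pairwise_f1(a, b, "X", mode)
        ba <- pairwise_f1(b, a, "X", mode)
        expect_equal(ab$f1, ba$f1, tolerance = 1e-12)
        expect_equal(ab$precision, ba$recall, tolerance = 1e-12)
        expect_equal(ab$recall, ba$precision, tolerance = 1e-12)
      }
    }
  })
})

test_that("relaxed agreement never falls below exact agreement", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      a <- random_annset(sample(0:6, 1), annotator_id = "a")
      b <- random_annset(sample(0:6, 1), annotator_id = "b")
      for (cat in c("X", "Y")) {
        ex <- pairwise_f1(a, b, cat, "exact")
        rx <- pairwise_f1(a, b, cat, "relaxed")
        expect_gte(rx$f1, ex$f1)
        expect_gte(rx$precision, ex$precision)
        expect_gte(rx$recall, ex$recall)
      }
    }
  })
})

test_that("the agreement matrix pools counts across shared documents", {
  # doc1: (tp=1, fp=1, fn=0); doc2: (tp=1, fp=0, fn=1) -> P = R = 2/3
  scheme <- load_scheme("X")
  d1_a <- ann("X", 0, 5, doc_id = "doc1", annotator_id = "a")
  d1_b <- ann(c("X", "X"), c(0, 10), c(5, 15), doc_id = "doc1", annotator_id = "b")
  d2_a <- ann(c("X", "X"), c(0, 10), c(5, 15), doc_id = "doc2", annotator_id = "a")
  d2_b <- ann("X", 0, 5, doc_id = "doc2", annotator_id = "b")
  m <- iaa_matrix(dplyr::bind_rows(d1_a, d1_b, d2_a, d2_b),
                  mode = "exact", scheme = scheme)
  expect_equal(nrow(m), 1L)
  expect_equal(m$tp, 2)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$n_docs, 2L)
})

test_that("identical annotators agree perfectly over any number of documents", {
  sets <- purrr::map(1:3, function(d) {
    dplyr::bind_rows(
      ann("X", c(0, 10), c(5, 15), doc_id = paste0("doc", d), annotator_id = "a"),
      ann("X", c(0, 10), c(5, 15), doc_id = paste0("doc", d), annotator_id = "b")
    )
  })
  m <- iaa_matrix(dplyr::bind_rows(sets), mode = "exact", scheme = load_scheme("X"))
  expect_true(all(m$f1 == 1))
})

test_that("twelve annotators on one shared document yield 66 scored pairs", {
  anns <- purrr::map(sprintf("ann%02d", 1:12), function(aid) {
    ann("X", 0, 5, doc_id = "doc1", annotator_id = aid)
  })
  m <- iaa_matrix(dplyr::bind_rows(anns), mode = "exact", scheme = load_scheme("X"))
  pairs <- dplyr::distinct(m, annotator_a, annotator_b)
  expect_equal(nrow(pairs), 66L)
})

test_that("annotators with no shared document give an empty matrix with warning", {
  anns <- dplyr::bind_rows(
    ann("X", 0, 5, doc_id = "doc1", annotator_id = "a"),
    ann("X", 0, 5, doc_id = "doc2", annotator_id = "b")
  )
  expect_warning(m <- iaa_matrix(anns, scheme = load_scheme("X")), "shares")
  expect_equal(nrow(m), 0L)
})

test_that("distribution_summary matches the quantile-and-fence oracle", {
  s <- distribution_summary(0.5)
  expect_equal(s$median, 0.5)
  expect_equal(s$q1, 0.5)
  expect_equal(s$q3, 0.5)
  expect_equal(nrow(s$outliers[[1]]), 0L)

  s <- distribution_summary(c(1, 2, 3, 4, 100))
  expect_true(100 %in% s$outliers[[1]]$value)
  expect_equal(s$whisker_high, 4)

  same <- distribution_summary(rep(0.7, 9))
  expect_equal(same$iqr, 0)
  expect_equal(same$whisker_low, 0.7)
  expect_equal(same$whisker_high, 0.7)

  withr::with_seed(5, {
    for (rep in 1:100) {
      v <- round(stats::runif(sample(1:40, 1)), 3)
      got <- distribution_summary(v)
      want <- boxstats_oracle(v)
      expect_equal(got$median, want$median, tolerance = 1e-12)
      expect_equal(got$q1, want$q1, tolerance = 1e-12)
      expect_equal(got$q3, want$q3, tolerance = 1e-12)
      expect_equal(got$whisker_low, want$whisker_low)
      expect_equal(got$whisker_high, want$whisker_high)
      expect_equal(sort(got$outliers[[1]]$value), want$outliers)
    }
  })

  expect_error(distribution_summary(numeric()), class = "expocorpus_usage_error")
})

test_that("ranking splits annotators into equal primary/secondary groups", {
  withr::with_seed(808, {
    gold_spans <- seq(0, 110, by = 10)
    anns <- purrr::map(1:12, function(i) {
      # annotator i keeps each gold span independently w.p. declining in i
      keep <- which(stats::runif(12) < 1 - (i - 1) * 0.06)
      ann("X", gold_spans[keep], gold_spans[keep] + 5,
          doc_id = "doc1", annotator_id = sprintf("ann%02d", i))
    })
    m <- iaa_matrix(dplyr::bind_rows(anns), mode = "exact",
                    scheme = load_scheme("X"))
    grouping <- rank_and_group(m)
    expect_equal(sum(grouping$group == "primary"), 6L)
    expect_equal(sum(grouping$group == "secondary"), 6L)
    # every annotator's score is the brute-force mean over its pair list
    means <- pair_mean_f1(m)
    for (aid in grouping$annotator) {
      manual <- means[means$annotator_a == aid | means$annotator_b == aid, ]
      expect_equal(grouping$mean_f1[grouping$annotator == aid],
                   mean(manual$mean_f1))
    }
    # boundary ordering: every primary score >= every secondary score
    expect_gte(min(grouping$mean_f1[grouping$group == "primary"]),
               max(grouping$mean_f1[grouping$group == "secondary"]))
  })
})

test_that("an annotator dominating every pairwise score ranks first", {
  # "a" matches everyone fully; "b" and "c" disagree with each other
  anns <- dplyr::bind_rows(
    ann("X", c(0, 10, 20), c(5, 15, 25), doc_id = "doc1", annotator_id = "a"),
    ann("X", c(0, 10), c(5, 15), doc_id = "doc1", annotator_id = "b"),
    ann("X", c(20, 30), c(25, 35), doc_id = "doc1", annotator_id = "c")
  )
  m <- iaa_matrix(anns, mode = "exact", scheme = load_scheme("X"))
  means <- pair_mean_f1(m)
  score_of <- function(aid) {
    mean(means$mean_f1[means$annotator_a == aid | means$annotator_b == aid])
  }
  expect_true(score_of("a") > score_of("b") && score_of("a") > score_of("c"))
  g <- suppressWarnings(rank_and_group(m))
  expect_equal(g$annotator[g$rank == 1], "a")
})

test_that("tied annotators are ranked deterministically by id", {
  anns <- dplyr::bind_rows(
    ann("X", 0, 5, doc_id = "doc1", annotator_id = "b"),
    ann("X", 0, 5, doc_id = "doc1", annotator_id = "a")
  )
  m <- iaa_matrix(anns, mode = "exact", scheme = load_scheme("X"))
  g <- rank_and_group(m)
  expect_equal(g$annotator, c("a", "b"))
  expect_equal(g$group, c("primary", "secondary"))
})

test_that("odd annotator counts warn and put the extra member in primary", {
  anns <- purrr::map(c("a", "b", "c"), function(aid) {
    ann("X", 0, 5, doc_id = "doc1", annotator_id = aid)
  })
  m <- iaa_matrix(dplyr::bind_rows(anns), mode = "exact", scheme = load_scheme("X"))
  expect_warning(g <- rank_and_group(m), "Odd")
  expect_equal(sum(g$group == "primary"), 2L)
})
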