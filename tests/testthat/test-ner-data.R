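test_that("sentence segmentation and tokenization preserve offsets", {
  docs <- tibble::tibble(doc_id = "d1", text = "A b. C d.")
  toks <- segment_and_tokenize(docs)
  expect_equal(max(toks$sentence), 2L)
  expect_equal(toks$token[toks$sentence == 1], c("A", "b", "."))
  expect_equal(toks$token[toks$sentence == 2], c("C", "d", "."))
  b <- toks[toks$token == "b", ]
  expect_equal(b$start, 2L)
  expect_equal(b$end, 3L)
  # every token surface equals its slice of the document text
  expect_equal(substr(rep(docs$text, nrow(toks)), toks$start + 1, toks$end),
               toks$token)

  # internal hyphens and periods stay inside one token
  docs2 <- tibble::tibble(doc_id = "d1",
                          text = "A 10-mm cyclone and PM1.0 filter.")
  toks2 <- segment_and_tokenize(docs2)
  expect_true("10-mm" %in% toks2$token)
  expect_true("PM1.0" %in% toks2$token)
  expect_equal(max(toks2$sentence), 1L)
})

test_that("sentences never cross section boundaries", {
  text <- "alpha beta gamma delta"
  docs <- tibble::tibble(doc_id = "d1", text = text)
  secs <- tibble::tibble(doc_id = "d1", label = c("Abstract", "Methods"),
                         start = c(0L, 11L), end = c(10L, 22L))
  toks <- segment_and_tokenize(docs, secs)
  expect_equal(unique(toks$section[toks$token %in% c("alpha", "beta")]),
               "Abstract")
  expect_equal(unique(toks$section[toks$token %in% c("gamma", "delta")]),
               "Methods")
  expect_equal(max(toks$sentence), 2L)
})

test_that("the worked garage sentence encodes to the expected BIOE labels", {
  text <- "The primary activity at both garages was Diesel engine maintenance."
  docs <- tibble::tibble(doc_id = "d1", text = text)
  anns <- dplyr::bind_rows(
    ann("Industry/Workplace", 29, 36, text = text),
    ann("Job Task/Activity", 41, 66, text = text)
  )
  expect_equal(anns$surface, c("garages", "Diesel engine maintenance"))
  toks <- encode_bioe(segment_and_tokenize(docs), anns)
  expect_equal(
    toks$label,
    c("O", "O", "O", "O", "O", "B-Industry/Workplace", "O",
      "B-JobTask/Activity", "I-JobTask/Activity", "E-JobTask/Activity", "O")
  )
})

test_that("BIOE encoding handles empty, misaligned and overlapping input", {
  text <- "alpha beta gamma delta."
  docs <- tibble::tibble(doc_id = "d1", text = text)
  toks <- segment_and_tokenize(docs)

  plain <- encode_bioe(toks, NULL)
  expect_true(all(plain$label == "O"))

  # boundary inside a token snaps outward with a warning
  expect_warning(
    enc <- encode_bioe(toks, ann("X", 2, 9, text = text),
                       scheme = load_scheme("X")),
    "snapped"
  )
  expect_equal(enc$label, c("B-X", "E-X", "O", "O", "O"))

  # overlapping same-category annotations keep the longer span
  expect_message(
    enc2 <- encode_bioe(toks, ann(c("X", "X"), c(0, 6), c(16, 10), text = text),
                        scheme = load_scheme("X")),
    "discarded"
  )
  expect_equal(enc2$label, c("B-X", "I-X", "E-X", "O", "O"))
})

test_that("decode inverts encode for aligned annotations and repairs malformed runs", {
  withr::with_seed(23, {
    corp <- generate_corpus(generator_config(n_docs = 3, seed = 23))
    toks <- segment_and_tokenize(corp$documents, corp$sections)
    enc <- encode_bioe(toks, corp$annotations)
    dec <- decode_bioe(enc, corp$documents)
    key <- c("doc_id", "category", "start", "end", "surface")
    expect_equal(
      dplyr::arrange(dec[key], doc_id, start),
      dplyr::arrange(corp$annotations[key], doc_id, start)
    )
  })

  # lone B is a complete entity
  toks <- segment_and_tokenize(tibble::tibble(doc_id = "d1", text = "a b c."))
  toks$label <- c("B-X", "O", "O", "O")
  dec <- decode_bioe(toks, scheme = load_scheme("X"))
  expect_equal(nrow(dec), 1L)
  expect_equal(c(dec$start, dec$end), c(0L, 1L))

  # leading I/E without B starts an entity at token 0
  toks$label <- c("I-X", "E-X", "O", "O")
  dec <- decode_bioe(toks, scheme = load_scheme("X"))
  expect_equal(nrow(dec), 1L)
  expect_equal(c(dec$start, dec$end), c(0L, 3L))

  # category switch mid-run closes the previous entity
  toks$label <- c("B-X", "I-Y", "E-Y", "O")
  dec <- decode_bioe(toks, scheme = load_scheme(c("X", "Y")))
  expect_equal(dec$category, c("X", "Y"))

  toks$label <- rep("O", 4)
  expect_equal(nrow(decode_bioe(toks, scheme = load_scheme("X"))), 0L)
})

test_that("span enumeration matches the closed-form candidate count", {
  toks <- segment_and_tokenize(tibble::tibble(doc_id = "d1", text = "a b c d"))
  sp <- enumerate_spans(toks, NULL, max_width = 2)
  expect_equal(nrow(sp), 7L)  # 4 + 3

  for (n in 3:7) {
    text <- paste(letters[1:n], collapse = " ")
    toks <- segment_and_tokenize(tibble::tibble(doc_id = "d1", text = text))
    for (w in 1:n) {
      sp <- enumerate_spans(toks, NULL, max_width = w)
      expect_equal(nrow(sp), n * w - w * (w - 1) / 2)
    }
  }
})

test_that("span candidates carry gold labels only on exact token matches", {
  text <- "alpha beta gamma delta."
  toks <- segment_and_tokenize(tibble::tibble(doc_id = "d1", text = text))
  gold <- ann("X", 6, 16, text = text)  # "beta gamma"
  sp <- enumerate_spans(toks, gold, max_width = 3)
  hit <- sp[sp$label == "X", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(6L, 16L))

  # a 3-token gold entity has no positive candidate when max_width = 2
  gold3 <- ann("X", 0, 16, text = text)  # "alpha beta gamma"
  expect_message(sp2 <- enumerate_spans(toks, gold3, max_width = 2),
                 "no candidate")
  expect_true(all(sp2$label == "NONE"))
  expect_equal(attr(sp2, "truncated"), 1L)
})

test_that("folds partition sentences deterministically", {
  sentences <- tibble::tibble(doc_id = "d1", sentence = 1:100)
  f <- make_folds(sentences, k = 10, seed = 13)
  expect_equal(sum(is.na(f$fold)), 10L)
  expect_equal(as.integer(table(f$fold)), rep(9L, 10))
  expect_equal(sum(f$split == "test"), 10L)
  expect_equal(sum(f$split == "dev"), 10L)
  expect_equal(sum(f$split == "train"), 80L)

  f2 <- make_folds(sentences, k = 10, seed = 13)
  expect_identical(f, f2)
  f3 <- make_folds(sentences, k = 10, seed = 14)
  expect_false(identical(f$fold, f3$fold))

  # partition: folds + holdout cover all sentences exactly once
  expect_equal(nrow(f), 100L)
  expect_equal(dplyr::n_distinct(f$sentence), 100L)

  expect_error(make_folds(sentences[1:8, ], k = 10),
               class = "expocorpus_usage_error")
})

test_that("the dictionary tagger scans longest-first with frequency tie-breaks", {
  gaz <- tibble::tibble(
    category = "Occupation/Job Title", surface = "carpenters", freq = 3L
  )
  docs <- tibble::tibble(doc_id = "d1", text = "the carpenters worked.")
  pred <- apply_dictionary_tagger(gaz, docs)
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$surface, "carpenters")
  expect_equal(pred$category, "Occupation/Job Title")

  # longest match wins over its substring
  gaz2 <- dplyr::bind_rows(
    gaz,
    tibble::tibble(category = "Occupation/Job Title",
                   surface = "the carpenters", freq = 1L)
  )
  pred2 <- apply_dictionary_tagger(gaz2, docs)
  expect_equal(pred2$surface, "the carpenters")

  # ambiguous surface resolves by training frequency
  gaz3 <- tibble::tibble(
    category = c("Occupation/Job Title", "Industry/Workplace"),
    surface = "carpenters", freq = c(1L, 5L)
  )
  pred3 <- apply_dictionary_tagger(gaz3, docs)
  expect_equal(pred3$category, "Industry/Workplace")

  # frequency ties resolve by scheme order
  gaz4 <- dplyr::mutate(gaz3, freq = 2L)
  pred4 <- apply_dictionary_tagger(gaz4, docs)
  expect_equal(pred4$category, "Occupation/Job Title")

  expect_equal(nrow(apply_dictionary_tagger(train_dictionary_tagger(NULL), docs)), 0L)
})

test_that("gazetteer recall is bounded by the seen-span fraction", {
  withr::with_seed(41, {
    corp <- generate_corpus(generator_config(n_docs = 8, seed = 41))
    gold <- corp$annotations
    docs <- corp$documents$doc_id
    train_docs <- docs[1:6]
    test_docs <- docs[7:8]
    train <- dplyr::filter(gold, doc_id %in% train_docs)
    test <- dplyr::filter(gold, doc_id %in% test_docs)

    gaz <- train_dictionary_tagger(train)
    pred <- apply_dictionary_tagger(
      gaz, dplyr::filter(corp$documents, doc_id %in% test_docs),
      dplyr::filter(corp$sections, doc_id %in% test_docs)
    )
    report <- score_predictions(test, pred, "exact")
    unseen <- unseen_fraction(train, test)
    joined <- dplyr::inner_join(
      tibble::as_tibble(report), unseen, by = "category"
    )
    joined <- dplyr::filter(joined, !undefined)
    expect_true(all(joined$recall <= 1 - joined$unseen_fraction + 1e-12))
  })
})

test_that("CoNLL export writes one token per line and round-trips labels", {
  text <- "The primary activity at both garages was Diesel engine maintenance."
  docs <- tibble::tibble(doc_id = "d1", text = text)
  anns <- dplyr::bind_rows(
    ann("Industry/Workplace", 29, 36, text = text),
    ann("Job Task/Activity", 41, 66, text = text)
  )
  enc <- encode_bioe(segment_and_tokenize(docs), anns)
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(enc, path)
  lines <- readLines(path)
  expect_equal(lines[6], "garages\tB-Industry/Workplace")
  back <- read_conll(path)
  expect_equal(back$label, enc$label)
  expect_equal(back$token, enc$token)
})
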