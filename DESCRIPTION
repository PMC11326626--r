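Package: expocorpus
Title: Multi-Annotator Corpus Construction and Evaluation for Occupational Exposure NER
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multi-annotator named-entity
    corpora of occupational substance exposure literature. Reads and writes
    brat standoff annotation projects against a six-category exposure scheme
    (substances, occupations, industries and workplaces, job tasks,
    occupational-hygiene measurement devices, and evidence of personal
    sampling), computes pairwise inter-annotator agreement F1 under exact and
    relaxed span matching, summarises agreement distributions and ranks
    annotators into primary and secondary groups, consolidates annotator pairs
    into a gold standard through a configurable per-category rule policy,
    computes corpus descriptive statistics (unique-span frequencies,
    unseen-span fractions across splits), exports token-level BIOE and
    enumerated-span NER datasets with seeded cross-validation folds, scores
    predicted annotations against gold, and simulates noisy annotators on
    synthetic corpora so that the whole pipeline is testable end to end
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
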