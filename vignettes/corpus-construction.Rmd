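---
title: "Multi-annotator corpus construction and evaluation for exposure NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-annotator corpus construction and evaluation for exposure NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expocorpus)
library(dplyr)
```

## The problem

Named-entity recognition for occupational exposure studies needs an
annotated corpus: article text in which experts have marked up six
categories of mentions — the substance or exposure measured, the
occupation/job title of the people studied, the industry or workplace, the
job task or activity, the occupational-hygiene (OH) measurement device, and
evidence of personal sampling. Annotation is done by a team, each document
marked by at least two people, with annotations stored in the brat standoff
format (plain `.txt` plus tab-separated `.ann` records of category and
character offsets). The package covers the quantitative machinery around
that workflow: validating standoff projects, measuring agreement, grouping
annotators, consolidating pairs into a gold standard, describing the
corpus, exporting NER datasets and scoring predictions. A synthetic
simulator stands in for restricted article text.

## Span matching and agreement

All agreement and evaluation rests on one matching primitive. Two
annotations are *exact* matches when category, start and end coincide;
*relaxed* matches when categories coincide and the half-open character
intervals share at least one character. The overlap threshold of a single
character is the weakest defensible reading of "spans overlap"; anything
stricter (proportional overlap, token containment) would need a parameter
the method does not define.

Matching is one-to-one. Candidate pairs are ranked by descending character
overlap, ties broken by the earlier start in the reference set and then in
the response set, and accepted greedily; the greedy matching is then
extended along alternating augmenting paths so the number of matched pairs
is always the maximum cardinality achievable. The greedy stage makes the
*choice* of pairs deterministic and intuitive (longest overlaps first); the
augmentation stage guarantees that no ordering artefact ever costs a match.
On small sets the test suite checks the count against an exhaustive
enumeration of all one-to-one matchings.

Pairwise agreement is F1 over these counts, which is symmetric in the two
annotators (precision and recall swap). Per annotator pair and category,
counts are pooled across all shared documents before one score is computed
(micro pooling); averaging per-document F1 instead is available via
`pooling = "average"` since the original protocol does not state which was
used. When both annotators annotated nothing in a category over all shared
documents, agreement is vacuously perfect: the score is 1 and the row is
flagged `vacuous`, so downstream averages can exclude such rows
(`vacuous = "exclude"`) — another point the protocol leaves open.

Distributions of pairwise scores are summarised exactly as a box-and-whisker
plot defines them: median and quartiles by linear interpolation between
order statistics (quantile type 7 — the figure convention is not stated, so
R's default is used), whiskers at the most extreme data points within 1.5
interquartile ranges of the box, everything beyond listed as an outlier.

Annotator ranking averages each annotator's per-pair mean-over-categories
F1 across all partners (categories unweighted — support weighting would let
one dominant category decide the grouping). The top half forms the primary
group; ties break lexicographically by annotator id so reruns are stable,
and with an odd team the primary group takes the extra member.

## Consolidation

The rule set used by the original corpus builders to combine annotator
pairs is not publicly available, so consolidation is implemented as a
policy engine rather than a fixed algorithm. A policy maps each category
(optionally per annotator pair) to an action: keep the primary annotator's
spans only, take the union (overlapping same-category spans collapsed by a
configurable preference), or — the default — *augment_novel*: primary spans
plus those secondary spans that overlap no same-category primary span.
`derive_policy()` reconstructs the stated intent of pair- and
category-sensitive combination: augmentation is enabled for a category when
the pair's F1 on it reaches a threshold, defaulting to 0.70, the
conventional boundary for strong agreement on span annotation tasks. These
defaults are this package's reconstruction, not the original rules; the
policy is serialisable so an exact rule set can be dropped in. Cross-category
overlaps are always permitted — workplace and task mentions legitimately
co-occur in text. Every merged annotation carries provenance, and the merge
report reconciles exactly with the merged set.

## Corpus statistics

Span identity for uniqueness and unseen-ness is the exact lowercased
surface string with internal whitespace runs collapsed to one space (line
wrapping in extracted text would otherwise split identities); no
lemmatisation. The unique-span frequency is `total / unique` rounded to two
decimals, and surface-form shares are reported as whole percents, matching
how such tables are conventionally printed. Unseen fractions are computed
within category — a workplace "mines" in training does not make a task
"mines" seen — with a corpus-global variant behind `global = TRUE`.

## NER datasets

The tokenizer is rule-based and offset-preserving: maximal alphanumeric
runs keep internal hyphens, periods and apostrophes ("10-mm", "PM1.0",
"Dorr-Oliver"), and every other non-space character is its own token. This
choice is driven by device and substance mentions, which are rich in such
tokens; the original tokenizer is unnamed, so this contract is pinned down
by fixtures in the test suite. Sentences end at terminal punctuation
followed by whitespace and never cross section boundaries. Abbreviations
like "e.g." will split a sentence; for offset-based span work this is
harmless, since no downstream computation crosses sentence boundaries
except splitting, which only becomes marginally finer.

Token labels use the `{B, I, E, O}` alphabet: single-token entities are a
lone `B-c` (no `S` tag exists in this alphabet, and decoding treats a lone
`B` as a complete entity — the minimal consistent reading); multi-token
entities are `B-c (I-c)* E-c`. Label tags are category names with spaces
removed. Decoding repairs the malformed sequences real taggers emit: a
leading `I`/`E` opens an entity, a category switch closes the previous one,
and dangling runs close at sentence end. Annotation boundaries that split a
token are snapped *outward* to whole tokens, preserving the full mention at
the cost of occasional extra characters, and logged. Overlapping
same-category annotations keep the longer span.

Span enumeration lists all windows up to `max_width = 12` tokens — wide
enough for the longest device and task mentions discussed in this domain's
literature — and labels a window with the gold category only on an exact
token-boundary match.

Splits are sentence-level, mirroring the stated protocol ("sentences split
randomly"): a seeded shuffle first draws the 10% held-out set, the
remainder is dealt into 10 folds differing in size by at most one, and a
further 10% of the corpus forms the development set for the 80/10/10
protocol. The same seed always reproduces the same split. Document-level
splits can be had by passing document ids as the sentence unit.

The dictionary baseline is a gazetteer of normalised training surfaces per
category, applied by case-insensitive longest-match-first scanning;
ambiguous surfaces resolve by training frequency, then scheme order. It
exists to exercise the full data-to-score path and as a floor: its exact
recall in any category can never exceed one minus the unseen-span fraction,
a bound the tests assert. Transformer fine-tuning is out of scope here, and
published model scores are properties of the original (non-distributed)
corpus, so they are not reproduction targets.

Evaluation reuses the matching primitive asymmetrically (precision over
predictions, recall over gold). The overall row is the micro average —
pooled counts, chosen because overall scores in this setting sit near the
support-heavy categories — with macro behind a flag. Cross-fold aggregation
reports the mean and the population standard deviation (the folds are the
whole population of splits run; sample SD is a switch).

## The synthetic corpus and what it does (not) show

`generate_corpus()` builds template-generated English-like documents with
Abstract/Methods/Results structure. Defaults are chosen to echo the shape
of a consolidated exposure corpus at desk scale: 20 documents of 15
sentences; expected annotations per document of 12 / 4 / 5 / 3 / 1.5 / 1
for substances, occupations, industry/workplace, tasks, devices and
personal-sampling evidence respectively (substances dominate by the same
order-of-magnitude ratio as in real corpora of this kind); vocabulary sizes
of 30 / 25 / 35 / 40 / 16 / 5 distinct phrases, so substances and
personal-sampling phrases repeat heavily while task mentions are mostly
unique; mean span lengths between 1.5 and 2.5 tokens with a 6-token cap.
These are fixed study conditions, not tuning knobs.

`simulate_annotator()` models the disagreement phenomena seen between human
annotators: misses (`p_miss`), spurious spans (`lambda_spur` per sentence),
boundary jitter (`p_jit`, up to `max_shift` tokens, constrained so the
jittered span still overlaps the original mention — a human boundary
disagreement still covers the same mention, and this keeps jitter-only
noise invisible to relaxed matching by construction), and category
confusion (a row-stochastic matrix). Default rates (miss 0.10, spurious
0.05, jitter 0.15 with shift 1, no confusion) produce relaxed pairwise F1
in the 0.8 range between two independent annotators, i.e. a competent
annotation team. Each annotator's random stream derives from
`(seed, annotator_id)`, so simulating more annotators never perturbs an
existing one.

The simulator validates the *machinery*: parameter recovery (one minus
recall converges to `p_miss`), monotone degradation of agreement in every
noise rate, and end-to-end consistency of the pipeline. It does not
generate real prose, category-specific syntax, or annotator biases
correlated with text difficulty, so passing tests say nothing about
absolute agreement levels attainable on real articles — those are
properties of real annotators and guidelines.

## Numerical and degenerate-input choices

Precision, recall and F1 are 0 when their denominators vanish, except
vacuous agreement (both sides empty), which scores 1 and is flagged.
Duplicate standoff lines are deduplicated with a warning so agreement never
double-counts; discontinuous brat fragments are rejected; non-text-bound
lines (relations, events, notes) are ignored. Offsets are 0-based,
half-open, as the brat tool defines them. Surfaces are re-derived from
offsets at parse time and cross-checked against the recorded surface so a
desynchronised `.txt`/`.ann` pair fails immediately. Empty inputs return
empty tibbles of the canonical shape rather than errors wherever an empty
result is meaningful.

## Problem sizes

The test suite and the acceptance script run on synthetic corpora of 2–40
documents (up to ~1000 gold annotations for the parameter-recovery checks),
property sweeps of 200–1000 random fixtures, and 10-fold splits over ~150
sentences; these sizes give stable Monte-Carlo tolerances (3 standard
errors) while keeping a full run in minutes on one core.

## Known limitations

Section boundaries travel in a JSON sidecar because plain text carries no
section markup; whether the original project stored sections as one file or
several is unknown, and the sidecar covers both. The consolidation defaults
are a reconstruction (see above). The tokenizer and sentence splitter are
simple rule systems, adequate for offset bookkeeping but not linguistically
informed. No chance-corrected agreement coefficients are provided — the
protocol this follows uses F1 only — and no significance testing between
models is implemented.
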