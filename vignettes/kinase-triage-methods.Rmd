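---
title: "Literature triage for kinase curation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature triage for kinase curation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Curated protein databases are kept current by human curators who read the
literature and record, for each protein, its disease associations and the
biological processes it participates in. Before any annotation happens, the
curator must find the papers worth reading: *literature triage*. For a query
— here a (kinase, curation axis) pair, where the axis is either diseases or
GO biological processes — a triage system searches a citation collection and
returns a ranked list of documents, which is evaluated with standard
information-retrieval metrics against the set of papers curators actually
selected.

Two properties of real curation data shape everything in this package:

* **Judgments are positives-only.** Databases store the papers that were
  curated; papers screened and rejected are not recorded. Supervised
  ranking therefore needs *pseudo-negatives* — unlabeled documents drafted
  to stand in for the missing negative class.
* **The relevant set per query is small and skewed.** Curated papers per
  kinase run to a mean of about 22 and a median of about 15, i.e. a
  right-skewed count distribution, inside collections of millions of
  citations.

## The pipeline

`run_pipeline()` executes the following stages, each of which is also an
exported function:

1. **Corpus ingestion** (`read_bioc_collection()`, `filter_by_year()`).
   Collections arrive as BioC XML (collection → document → passage);
   title and abstract passages are recognised by their `type` infon, any
   other passage type becomes body text, and journal/year/publication-type
   metadata are read from configurable document infons (BioC producers
   disagree on key names, so they are parameters, defaulting to `journal`,
   `year`, `pub_types`). The year filter keeps documents published strictly
   before a cutoff (default 2014, matching a collection frozen when
   curation ended in 2013); documents with unknown year cannot be certified
   pre-cutoff and are dropped, with the count reported.

2. **Dictionary annotation** (`expand_synonyms()`, `build_matcher()`,
   `annotate()`). Kinase dictionaries are expanded with two rules —
   standalone Roman-numeral tokens I–XX become Arabic numerals, and
   internal spaces are removed — plus their combination ("casein kinase II"
   also matches as "casein kinase 2", "caseinkinaseII" and
   "caseinkinase2"). Matching is case-insensitive, token-level,
   longest-match, non-overlapping, resolved left to right: at each
   position the longest dictionary surface starting there wins and the
   scan resumes after it. The tokenizer splits on whitespace and strips
   only edge punctuation, because protein surface forms such as `c-kit`
   and `p145` must survive intact. Title, abstract and body are scanned as
   one token sequence. Kinase and axis matchers run independently, so a
   kinase mention may overlap an axis mention but two kinase annotations
   never overlap.

3. **Cross-reference validation** (`cross_reference_validate()`). A
   document is a candidate for a topic only if it mentions both sides of
   the query: the topic's kinase and at least one term of the topic's
   axis vocabulary. This is the coarse filter that turns a
   collection-scale problem into a candidate-scale one.

4. **Feature extraction** (`eng_features()`, `fit_bow_vocabulary()`,
   `bow_matrix()`, `extended_features()`). Two families:

   * Six *engineered* features per (topic, document): kinase score
     (kinase annotations / tokens), axis score, relevancy score (their
     product), proximity score (minimum token distance over all
     kinase–axis annotation pairs), and the counts of pairs within 10 and
     within 50 words. The distance between two spans (0-based,
     end-exclusive) is defined as the number of token positions strictly
     between their nearer ends — `max(0, start2 - end1 - 1)` — so
     adjacent or overlapping spans are at distance 0. Multi-token
     annotations count once. When a category is absent the proximity
     score takes a large finite sentinel (default 10 000) rather than
     infinity, keeping every feature matrix finite; the counts are 0.
   * *Bag-of-words* TFIDF over word 2- and 3-grams of stemmed,
     stop-word-filtered text. Weights use the smoothed IDF
     `ln((1+N)/(1+df)) + 1` with L2 normalization per document — the
     de-facto default of the ecosystem these systems were built in, which
     also avoids division by zero. Unigrams are excluded by default
     (2-/3-grams are the published configuration) but can be enabled via
     `ngram_range`. Stemming is a built-in implementation of the Porter
     (1980) algorithm, and the stop-word list is the Snowball English
     list shipped in the package, so preprocessing never depends on an
     external resource.

   A third family mirrors the frequency/position features of the
   one-class entrant: per-category mention counts and earliest mention
   position.

5. **Pseudo-negative assembly** (`sample_random_pseudo_negatives()`,
   `one_class_pseudo_negatives()`). Either a uniform random sample of a
   configurable fraction (default 0.15, inside the 10–20% range the track
   systems used) of the non-positive candidates, or one-class selection:
   fit a model of the positives and take the unlabeled instances least
   like them. The one-class default is a centroid-distance model after
   per-feature standardization — simple, deterministic and adequate for
   the separation this task exhibits — with a support-vector
   one-classifier selectable. If the rounded sample size is zero on a
   tiny pool, a single pseudo-negative is drawn: training requires both
   classes.

6. **Training and ranking** (`triage_scorer()`, `rank_topic()`). The
   scorer is a classic fitted-model object: a support-vector machine with
   linear or Gaussian kernel (via e1071/libsvm), or an elastic-net
   regularized logistic model (via glmnet), with `predict()` returning
   confidence scores. Defaults: cost 1.0; Gaussian bandwidth from the
   median pairwise-distance heuristic; elastic-net mixing 0.5 and penalty
   0.01; class weights balanced by inverse class frequency, since the
   positives/pseudo-negatives ratio is a design choice rather than a
   property of the population. One model is trained per axis, pooling all
   kinases of that axis (per-topic training is a flag): the published
   description of per-axis model inventories suggests pooled training,
   and pooling is also the only option for topics with few positives.
   Candidates are ranked by score, ties broken by document id descending
   — exactly the canonicalization used for run files, so a re-read run
   reproduces the ranking — and truncated at the evaluation depth
   (default 100).

7. **Evaluation** (`evaluate_run()`). P@10/30/100, R@30/100, maximum
   precision over ranks ("P at R0"), average precision and R-precision,
   per topic and macro-averaged, under the reference evaluator's
   conventions: average precision divides by the total number of relevant
   documents (unretrieved relevants contribute zero); topics with no
   relevant documents are excluded from macro averages; topics missing
   from a run score zero; precision at k keeps denominator k for short
   lists, while P at R0 is a maximum over the submitted list and needs no
   padding (padding could only lower trailing precisions, never the max).

## The synthetic benchmark

`generate_corpus()` builds a fully self-contained benchmark so that every
stage above is testable offline, with a *truth log* recording every planted
mention — tests see complete truth, while the ranker sees only what a real
system would (documents, dictionaries, positives-only qrels).

What it emulates, and the default study conditions:

* **Relevant-count distribution.** Papers per topic are drawn from a
  lognormal calibrated to mean 21.9 and median 15 (the disease-axis
  statistics of the motivating benchmark; `sdlog = sqrt(2 ln(mean/median))`
  follows from those two targets), rounded and clipped at 1. The
  biological-process axis printed 20.6/17; either pair can be requested.
* **Mention structure.** Every relevant document plants
  `1 + Poisson(2)` kinase–axis mention pairs for its topic — positives
  always contain both terms, which is what positives-only gold standards
  imply — and each pair lands within the co-mention window `w` (default
  10 tokens) with probability `p_comention_relevant` (default 0.9),
  otherwise well outside it. Background documents become mentioners of
  one random kinase and axis term with probability
  `p_comention_background` (default 0.05), planting `1 + Poisson(0)`
  pairs under the same within-window conditional. Relevance is thus
  signalled two ways: presence (which cross-reference validation
  exploits) and density/proximity (which the scorer exploits). Setting
  the background rate and pair rate equal to the relevant ones removes
  the signal entirely: filter-passing candidates become exchangeable, so
  a trained ranker can do no better than chance — the package's null
  control.
* **Text.** Background tokens are Zipf-distributed synthetic words, not
  English: document-frequency statistics are fully controlled (useful for
  TFIDF tests) and nothing needs downloading. Kinase and axis surfaces
  use disjoint letter alphabets so they cannot collide with background
  text; synonym lists are constructed to exercise every expansion rule
  (a Roman-numeral form and a spaced multi-token form per kinase).
* **Metadata.** Journals come from a small skewed categorical
  distribution and years from 1995–2013, with a few percent of background
  documents published 2014+ or with unknown year, so the year filter has
  something to do. Relevant documents are always pre-cutoff.
* **Attrition.** `degrade_to_fulltext_benchmark()` binomially thins the
  collection to a keep fraction (e.g. 0.10, the open-access availability
  of full texts in the motivating track), dropping qrels positives with
  their documents — relevant-per-topic counts fall proportionally in
  expectation, reproducing the abstract-task → full-text-task drop
  qualitatively.

What it does **not** emulate: English syntax, MeSH indexing, abbreviation
ambiguity, homonymous gene symbols, citation structure, or topic drift over
time. Passing tests on this benchmark demonstrate that the machinery is
correct and that the pipeline recovers a known signal; they say nothing
about absolute performance on real MEDLINE, where name ambiguity and
vocabulary mismatch dominate.

## Numerical and design choices

* **Tie-breaking** everywhere (runs, rankings, pseudo-negative selection)
  is deterministic: score descending, then document id descending, using
  byte-order (radix) sorting so results do not depend on the locale.
* **Determinism.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state; a configuration fully determines its
  run file, byte for byte.
* **Degenerate inputs.** Documents with no tokens annotate to nothing;
  documents with no in-vocabulary n-grams keep an all-zero TFIDF row
  (norm left at 0); a topic whose candidates are all filtered out yields
  an empty ranked list, not an error; training with a single class, or
  with non-finite features, fails with a pointed error.
* **Problem sizes.** The package's own verification runs the full
  pipeline on a 50-topic, 20 000-document benchmark (signal and null
  configurations), checks the metric suite against a brute-force oracle
  on 1000 random run/qrels instances, the engineered features against a
  pairwise oracle on 10 000 fuzzed annotation sets, and the matcher
  against an exhaustive-scan oracle on 500 random corpora. These sizes
  were chosen to exercise collection-scale code paths (e.g. vectorized
  XML reading, linear-time matching) while remaining comfortable on a
  single CPU.
* **Word distances** are measured on the annotation tokenizer's raw token
  positions, never on the stemmed/stop-word-filtered stream: proximity
  features must not change when the stop-word list does.

## Limitations

* The matcher performs no disambiguation: a surface form maps to the
  first concept that claims it. Real gene-name homonymy needs an entity
  linker, which is out of scope.
* The one-class "several others" feature set of the original systems is
  only partially recoverable from published descriptions; frequency and
  position features are implemented.
* The evaluator handles binary relevance only — the track's cancelled
  snippet task (graded 0/0.5/1) is not implemented.
* No learning-to-rank objectives and no neural models: the published
  comparisons found the margin/elastic-net family at least as good on
  this task, and they keep the toolkit dependency-light and
  deterministic.
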