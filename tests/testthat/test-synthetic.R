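test_that("generated lexicons exercise every expansion rule and are seeded", {
  lex <- generate_lexicons(n_kinases = 1, n_axis_terms = 4, seed = 3)
  kl <- lex$kinase_lexicon
  expect_gte(nrow(kl), 2)
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
             "XI", "XII")
  has_roman <- any(vapply(strsplit(kl$surface, " "), function(t)
    any(t %in% roman), TRUE))
  expect_true(has_roman)
  expect_true(any(grepl(" ", kl$surface)))  # a spaced multi-token form

  expect_identical(generate_lexicons(5, 6, seed = 9),
                   generate_lexicons(5, 6, seed = 9))
  expect_error(generate_lexicons(1, 0), "n_axis_terms")
})

test_that("corpus generation is a pure function of its params", {
  p <- sim_params(n_topics = 4, n_docs = 150, doc_length_mean = 40, seed = 21)
  b1 <- generate_corpus(p)
  b2 <- generate_corpus(p)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_benchmark(b1, d1); write_benchmark(b2, d2)
  f <- "collection.bioc.xml"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_identical(b1$truth_log, b2$truth_log)
})

test_that("with no background co-mentions the filter accepts exactly the relevant docs", {
  p <- sim_params(n_topics = 5, n_docs = 400, p_comention_relevant = 1,
                  p_comention_background = 0, seed = 8)
  bm <- generate_corpus(p)
  # expanded kinase dictionary, as the pipeline's dictionary loader builds it
  ex <- do.call(rbind, lapply(unique(bm$kinase_lexicon$concept_id), function(k) {
    data.frame(concept_id = k,
               surface = expand_synonyms(
                 bm$kinase_lexicon$surface[bm$kinase_lexicon$concept_id == k]),
               stringsAsFactors = FALSE)
  }))
  km <- build_matcher(lexicon(ex$concept_id, ex$surface, "KINASE"))
  am <- build_matcher(lexicon(bm$axis_lexicon$concept_id,
                              bm$axis_lexicon$surface, "AXIS"))
  ann <- annotate_collection(bm$documents, km, am)
  surv <- vapply(split(ann$annotations, ann$annotations$doc_id),
                 cross_reference_validate, TRUE)
  accepted <- names(surv)[surv]
  relevant <- unique(bm$qrels$judgments$doc_id)
  expect_setequal(accepted, relevant)  # recall 1.0, false-positive rate 0.0
})

test_that("every qrels positive carries both planted mention categories", {
  bm <- generate_corpus(sim_params(n_topics = 5, n_docs = 300,
                                   p_comention_relevant = 0.5, seed = 14))
  tl <- bm$truth_log
  for (i in seq_len(nrow(bm$qrels$judgments))) {
    d <- bm$qrels$judgments$doc_id[i]
    expect_true(any(tl$doc_id == d & tl$category == "KINASE"))
    expect_true(any(tl$doc_id == d & tl$category == "AXIS"))
  }
})

test_that("relevant-count distribution is calibrated to the curated-papers statistics", {
  counts <- kintriage:::.rel_counts(500, 21.9, 15)
  m <- mean(counts)
  expect_lt(abs(m - 21.9) / 21.9, 0.15)
  expect_lt(stats::median(counts), m)  # right skew: median below mean
  expect_true(all(counts >= 1))
})

test_that("annotation recovers essentially all planted mentions", {
  set.seed(1)
  bm <- generate_corpus(sim_params(n_topics = 6, n_docs = 500, seed = 33))
  # expanded kinase dictionary, per concept, as the pipeline builds it
  ex <- do.call(rbind, lapply(unique(bm$kinase_lexicon$concept_id), function(k) {
    data.frame(concept_id = k,
               surface = expand_synonyms(
                 bm$kinase_lexicon$surface[bm$kinase_lexicon$concept_id == k]),
               stringsAsFactors = FALSE)
  }))
  km <- build_matcher(lexicon(ex$concept_id, ex$surface, "KINASE"))
  am <- build_matcher(lexicon(bm$axis_lexicon$concept_id,
                              bm$axis_lexicon$surface, "AXIS"))
  ann <- annotate_collection(bm$documents, km, am)$annotations
  key <- function(df) paste(df$doc_id, df$token_start, df$token_end,
                            df$concept_id)
  recovered <- mean(key(bm$truth_log) %in% key(ann))
  expect_gte(recovered, 0.99)
})

test_that("full-text attrition thins positives binomially", {
  bm <- generate_corpus(sim_params(n_topics = 20, n_docs = 1500, seed = 44))
  thin <- degrade_to_fulltext_benchmark(bm, 0.10, seed = 45)
  n0 <- nrow(bm$qrels$judgments)
  n1 <- nrow(thin$qrels$judgments)
  # binomial thinning: mean 0.1 * n0, sd sqrt(n0 * 0.1 * 0.9)
  expect_lt(abs(n1 - 0.1 * n0), 3 * sqrt(n0 * 0.1 * 0.9))
  expect_true(all(thin$qrels$judgments$doc_id %in% thin$documents$doc_id))
  expect_identical(degrade_to_fulltext_benchmark(bm, 1), bm)
  expect_error(degrade_to_fulltext_benchmark(bm, 0), "keep_fraction")
})
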