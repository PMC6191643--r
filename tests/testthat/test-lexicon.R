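test_that("synonym expansion produces Roman-numeral and space-removed variants", {
  ex <- expand_synonyms("casein kinase II")
  expect_true("casein kinase 2" %in% ex)
  expect_true("caseinkinaseII" %in% ex)
  expect_true("caseinkinase2" %in% ex)  # combined variant
  expect_identical(ex[1], "casein kinase II")  # originals first

  expect_true("p145c-kit" %in% expand_synonyms("p145 c-kit"))
  expect_identical(expand_synonyms("ABL1"), "ABL1")  # no rule fires
})

test_that("synonym expansion is idempotent", {
  for (syn in list("casein kinase II", c("p145 c-kit", "MAP kinase IV"),
                   "protein kinase XX alpha")) {
    once <- expand_synonyms(syn)
    expect_setequal(expand_synonyms(once), once)
  }
})

test_that("token normalization folds case and strips edge punctuation only", {
  expect_identical(normalize_token("CD117"), "cd117")
  expect_identical(normalize_token("c-Kit"), "c-kit")
  expect_identical(normalize_token("(p145),"), "p145")
  expect_identical(normalize_token(""), "")
})

test_that("matcher prefers the longest match and scans left to right", {
  m <- build_matcher(lexicon(c("K1", "K1"), c("kit", "c-kit"), "KINASE"))
  ann <- annotate(tokenize("the c-kit receptor"), kinase_matcher = m,
                  doc_id = "d")
  expect_equal(nrow(ann), 1L)
  expect_identical(ann$surface, "c-kit")

  long <- build_matcher(lexicon(
    c("K1", "K1"), c("stem cell factor receptor kit", "kit"), "KINASE"))
  ann2 <- annotate(tokenize("the stem cell factor receptor kit gene"),
                   kinase_matcher = long, doc_id = "d")
  expect_equal(nrow(ann2), 1L)
  expect_identical(ann2$surface, "stem cell factor receptor kit")

  expect_equal(nrow(annotate(character(0), kinase_matcher = m, doc_id = "d")),
               0L)
  # a single stop-like surface is still matchable
  m2 <- build_matcher(lexicon("K2", "II", "KINASE"))
  expect_equal(nrow(annotate(tokenize("type II receptor"),
                             kinase_matcher = m2, doc_id = "d")), 1L)
})

test_that("kinase and axis annotations come from independent matchers", {
  km <- build_matcher(lexicon("K1", "kit", "KINASE"))
  am <- build_matcher(lexicon("A1", "mastocytosis", "AXIS"))
  doc <- document_set(doc_id = "1", title = "KIT mutations cause mastocytosis")
  ann <- annotate(doc, km, am)
  expect_equal(sum(ann$category == "KINASE"), 1L)
  expect_equal(sum(ann$category == "AXIS"), 1L)
  expect_equal(nrow(annotate(document_set(doc_id = "2", title = "nothing here"),
                             km, am)), 0L)
})

test_that("matcher agrees with the exhaustive-scan longest-match oracle", {
  set.seed(91)
  vocab <- c(sprintf("w%02d", 1:20), "kit", "c-kit", "receptor", "kinase",
             "ii", "factor")
  for (rep in 1:60) {
    n_entries <- sample(3:12, 1)
    surfaces <- vapply(seq_len(n_entries), function(i)
      paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " "), "")
    entries <- lexicon(paste0("C", seq_len(n_entries)), surfaces, "KINASE")
    m <- build_matcher(entries)
    tokens <- sample(vocab, sample(5:60, 1), replace = TRUE)
    got <- annotate(tokens, kinase_matcher = m, doc_id = "d")
    want <- oracle_match(tokens, entries)
    expect_equal(got[c("token_start", "token_end", "concept_id")], want,
                 ignore_attr = TRUE)
  }
})

test_that("annotation spans always lie within the document", {
  set.seed(17)
  bm <- generate_corpus(sim_params(n_topics = 4, n_docs = 300,
                                   doc_length_mean = 40, seed = 17))
  km <- build_matcher(lexicon(bm$kinase_lexicon$concept_id,
                              bm$kinase_lexicon$surface, "KINASE"))
  toks <- tokenize_documents(bm$documents)
  for (i in sample(length(toks), 30)) {
    ann <- annotate(toks[[i]], kinase_matcher = km, doc_id = names(toks)[i])
    if (nrow(ann)) {
      expect_true(all(ann$token_start >= 0))
      expect_true(all(ann$token_end <= length(toks[[i]])))
      expect_true(all(ann$token_start < ann$token_end))
    }
  }
})

test_that("cross-reference validation requires both a kinase and an axis term", {
  mk <- function(cats) data.frame(
    doc_id = rep("d", length(cats)), token_start = seq_along(cats) * 2L,
    token_end = seq_along(cats) * 2L + 1L, surface = rep("s", length(cats)),
    concept_id = rep("c", length(cats)), category = cats,
    stringsAsFactors = FALSE)
  expect_true(cross_reference_validate(mk(c("KINASE", "KINASE", "AXIS"))))
  expect_false(cross_reference_validate(mk(c("KINASE", "KINASE", "KINASE"))))
  expect_false(cross_reference_validate(mk(character(0))))
})

test_that("dictionary loader expands kinase entries and keeps axis labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("K1\tcasein kinase II", "K1\tCSNK2"), path)
  lex <- read_dictionary(path, "KINASE", expand = TRUE)
  expect_true("casein kinase 2" %in% lex$surface)
  expect_true(all(lex$concept_id == "K1"))

  apath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A1\tmastocytosis\tDISEASE", "A2\tapoptosis\tBIOPROC"), apath)
  alex <- read_dictionary(apath, "AXIS", expand = FALSE)
  expect_equal(alex$axis, c("DISEASE", "BIOPROC"))

  entries <- lexicon(c("K1", "K2"), c("kit", "  ,, "), "KINASE")
  expect_warning(m <- build_matcher(entries), "skipped")
  expect_equal(m$n_entries, 1L)
})
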