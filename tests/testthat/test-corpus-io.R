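test_that("BioC round trip preserves documents, metadata and passage types", {
  docs <- document_set(
    doc_id = c("111", "222"),
    title = c("KIT mutations in mastocytosis", "A title only"),
    abstract = c("The c-kit receptor & its ligand <SCF>", ""),
    journal = c("J. Biol. Chem.", "Blood"),
    year = c(2001L, NA),
    pub_types = c("Journal Article", "Review"))
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioc_collection(docs, path)
  back <- read_bioc_collection(path)
  expect_equal(back$doc_id, docs$doc_id)
  expect_equal(back$title, docs$title)
  expect_equal(back$abstract, docs$abstract)  # incl. escaped &, <, >
  expect_equal(back$journal, docs$journal)
  expect_equal(back$year, docs$year)
  expect_equal(back$pub_types, docs$pub_types)
})

test_that("a document lacking an abstract passage reads back with empty abstract", {
  docs <- document_set(doc_id = "9", title = "only a title", abstract = "")
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioc_collection(docs, path)
  back <- read_bioc_collection(path)
  expect_identical(back$abstract, "")
  expect_identical(back$title, "only a title")
})

test_that("duplicate PMIDs and malformed XML are rejected", {
  expect_error(document_set(doc_id = c("123", "123"), title = "t"),
               "duplicate doc_id")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<?xml version='1.0'?>", "<collection><document><id>123</id>",
               "<passage><infon key='type'>title</infon><text>a</text></passage></document>",
               "<document><id>123</id>",
               "<passage><infon key='type'>title</infon><text>b</text></passage></document>",
               "</collection>"), path)
  expect_error(read_bioc_collection(path), "duplicate doc_id")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<collection><document>", bad)
  expect_error(read_bioc_collection(bad), "malformed")
})

test_that("full-text XML is reduced to paragraphs in document order", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<article id='PMC1'>",
               "<front><article-title>Kinase review</article-title>",
               "<abstract>An abstract.</abstract></front>",
               "<body><sec><p>First paragraph.</p><p>Second one.</p></sec>",
               "<sec><p>Third.</p></sec></body></article>"), path)
  doc <- read_fulltext_xml(path)
  expect_identical(doc$doc_id, "PMC1")
  expect_identical(doc$body, "First paragraph. Second one. Third.")
  expect_identical(doc$title, "Kinase review")
})

test_that("year filter keeps strictly pre-cutoff papers and counts unknowns", {
  docs <- document_set(doc_id = as.character(1:4), title = "t",
                       year = c(2012L, 2013L, 2014L, 2015L))
  kept <- filter_by_year(docs, 2014)
  expect_equal(kept$doc_id, c("1", "2"))
  expect_identical(attr(kept, "dropped_missing_year"), 0L)

  expect_equal(nrow(filter_by_year(docs[0, ], 2014)), 0L)

  unk <- document_set(doc_id = "x", title = "t", year = NA)
  out <- filter_by_year(unk, 2014)
  expect_equal(nrow(out), 0L)
  expect_identical(attr(out, "dropped_missing_year"), 1L)
})

test_that("year filter is monotone in the cutoff", {
  set.seed(31)
  docs <- document_set(doc_id = as.character(1:50), title = "t",
                       year = sample(c(NA, 1990:2020), 50, replace = TRUE))
  for (i in 1:10) {
    c1 <- sample(1990:2020, 1); c2 <- sample(c1:2021, 1)
    expect_true(all(filter_by_year(docs, c1)$doc_id %in%
                      filter_by_year(docs, c2)$doc_id))
  }
})

test_that("topic files parse synonyms and axes; bad axes are format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("T1\tKIT-P10721\tdisease\tKIT|PBT|CD117",
               "T2\tCSNK2A1-P68400\tBIOLOGICAL_PROCESS\tcasein kinase II"),
             path)
  tp <- read_topics(path)
  expect_equal(tp$topic_id, c("T1", "T2"))
  expect_equal(tp$axis, c("DISEASE", "BIOPROC"))
  expect_equal(tp$synonyms[[1]], c("KIT", "PBT", "CD117"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("T1\tK\tdisease\ta", "T2\tK\tsubstrate\tb"), bad)
  expect_error(read_topics(bad), "line 2")
  empty_syn <- withr::local_tempfile(fileext = ".tsv")
  writeLines("T1\tK\tdisease\t|", empty_syn)
  expect_error(read_topics(empty_syn), "empty synonym")
})

test_that("qrels parse, binarize, default to zero, and round-trip", {
  path <- withr::local_tempfile()
  writeLines(c("T1 0 111 1", "T1 0 222 2", "T2 0 111 0"), path)
  qr <- read_qrels(path)
  expect_identical(qrels_relevance(qr, "T1", "111"), 1L)
  expect_identical(qrels_relevance(qr, "T1", "222"), 1L)  # binarized
  expect_identical(qrels_relevance(qr, "T2", "111"), 0L)
  expect_identical(qrels_relevance(qr, "T1", "999"), 0L)  # unlisted pair

  bad <- withr::local_tempfile()
  writeLines("T1 0 111 high", bad)
  expect_error(read_qrels(bad), "non-integer")

  set.seed(7)
  qr2 <- qrels(topic_id = paste0("T", sample(5, 100, TRUE)),
               doc_id = as.character(sample(1000, 100)))
  out <- withr::local_tempfile()
  write_qrels(qr2, out)
  back <- read_qrels(out)
  expect_equal(back$judgments[order(back$judgments$topic_id, back$judgments$doc_id), ],
               qr2$judgments[order(qr2$judgments$topic_id, qr2$judgments$doc_id), ],
               ignore_attr = TRUE)
})

test_that("run canonicalization sorts by score then doc id descending and is idempotent", {
  run <- data.frame(topic_id = "T1", doc_id = c("a", "b", "c"),
                    score = c(0.9, 0.9, 0.5), stringsAsFactors = FALSE)
  canon <- canonicalize_run(run)
  expect_equal(canon$doc_id, c("b", "a", "c"))  # tie broken by doc_id desc
  expect_equal(canon$rank, 1:3)
  expect_identical(canonicalize_run(canon)[names(canon)], canon)

  single <- canonicalize_run(data.frame(topic_id = "T1", doc_id = "x", score = 1))
  expect_identical(single$rank, 1L)

  dup <- data.frame(topic_id = "T1", doc_id = c("d1", "d1"), score = c(1, 2))
  expect_error(canonicalize_run(dup), "duplicate")
})

test_that("run files round-trip through the TREC format", {
  set.seed(11)
  run <- data.frame(topic_id = paste0("T", sample(3, 30, TRUE)),
                    doc_id = as.character(sample(1000, 30)),
                    score = round(runif(30), 4), stringsAsFactors = FALSE)
  run <- run[!duplicated(run[c("topic_id", "doc_id")]), ]
  canon <- canonicalize_run(run)
  path <- withr::local_tempfile()
  write_run(canon, path)
  back <- read_run(path)
  expect_equal(back, canon)
})
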