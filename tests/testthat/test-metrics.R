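test_that("precision and recall at k reproduce the track's worked examples", {
  # 10 submitted, 4 relevant
  expect_equal(precision_at_k(paste0("d", 1:10), paste0("d", 1:4), 10), 0.4)
  # 20 relevant in the collection, 10 of them in the top 30
  ranked <- c(paste0("r", 1:10), paste0("n", 1:20))
  relevant <- paste0("r", 1:20)
  expect_equal(recall_at_k(ranked, relevant, 30), 0.5)

  expect_equal(precision_at_k(character(0), "d1", 10), 0)
  # short lists are padded with non-relevant
  expect_equal(precision_at_k(paste0("d", 1:5), paste0("d", 1:5), 10), 0.5)
  expect_error(precision_at_k("d1", "d1", 0), "k must be")
  expect_equal(recall_at_k(paste0("d", 1:3), paste0("d", 1:3), 30), 1)
  expect_true(is.na(recall_at_k("d1", character(0), 30)))
})

test_that("P at R0 is the maximum precision over submitted ranks", {
  # relevant at ranks 2 and 3 of 5: max(0, 1/2, 2/3, 2/4, 2/5)
  expect_equal(p_at_r0(c("a", "b", "c", "d", "e"), c("b", "c")), 2 / 3)
  expect_equal(p_at_r0(c("b", "a"), "b"), 1)
  expect_equal(p_at_r0(c("a", "b"), "z"), 0)
})

test_that("average precision divides by total relevant (trec_eval convention)", {
  expect_equal(average_precision(c("a", "b"), c("a", "b")), 1)
  # 2 relevant, one retrieved at rank 2: (1/2) / 2
  expect_equal(average_precision(c("x", "a"), c("a", "q")), 0.25)
  expect_equal(average_precision(c("x", "y"), c("a", "b")), 0)
})

test_that("R-precision is precision at the number of relevant documents", {
  ranked <- paste0("d", 1:20)
  relevant <- c(paste0("d", 1:9), paste0("q", 1:6))  # 15 relevant
  expect_equal(r_precision(ranked, relevant),
               precision_at_k(ranked, relevant, 15))
  expect_equal(r_precision(c("a", "b"), c("b", "a")), 1)
  expect_equal(r_precision(c("x", "y"), c("a", "b")), 0)
})

test_that("evaluate_run macro-averages per topic and zero-fills missing topics", {
  qr <- qrels(c("T1", "T1", "T2"), c("a", "b", "c"))
  run <- data.frame(topic_id = c("T1", "T1"), doc_id = c("a", "b"),
                    score = c(2, 1), stringsAsFactors = FALSE)
  rep <- evaluate_run(run, qr)
  expect_equal(rep$n_topics_evaluated, 2L)
  # T1 has AP 1, T2 missing from the run scores 0
  expect_equal(rep$means[["average_precision"]], 0.5)
  t2 <- rep$per_topic[rep$per_topic$topic_id == "T2", ]
  expect_equal(t2$p10 + t2$r100 + t2$p_at_r0 + t2$r_prec, 0)

  run_extra <- rbind(run, data.frame(topic_id = "T9", doc_id = "z", score = 1))
  expect_warning(evaluate_run(run_extra, qr), "absent from qrels")
})

test_that("all metrics agree with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:150) {
    inst <- random_run_instance()
    qr <- qrels(inst$rel$topic_id, inst$rel$doc_id)
    rep <- suppressWarnings(evaluate_run(inst$run, qr))
    by_topic <- split(canonicalize_run(inst$run)$doc_id,
                      canonicalize_run(inst$run)$topic_id)
    for (t in rep$per_topic$topic_id) {
      ranked <- if (t %in% names(by_topic)) by_topic[[t]] else character(0)
      rel <- inst$rel$doc_id[inst$rel$topic_id == t]
      row <- rep$per_topic[rep$per_topic$topic_id == t, ]
      expect_equal(row$p10, oracle_precision_at_k(ranked, rel, 10), tolerance = 1e-12)
      expect_equal(row$p30, oracle_precision_at_k(ranked, rel, 30), tolerance = 1e-12)
      expect_equal(row$r30, oracle_recall_at_k(ranked, rel, 30), tolerance = 1e-12)
      expect_equal(row$r100, oracle_recall_at_k(ranked, rel, 100), tolerance = 1e-12)
      expect_equal(row$p_at_r0, oracle_p_at_r0(ranked, rel), tolerance = 1e-12)
      expect_equal(row$average_precision, oracle_average_precision(ranked, rel),
                   tolerance = 1e-12)
      expect_equal(row$r_prec, oracle_r_precision(ranked, rel), tolerance = 1e-12)
    }
  }
})

test_that("metric identities hold on fuzzed rankings", {
  set.seed(55)
  for (i in 1:200) {
    docs <- paste0("d", 1:60)
    rel <- sample(docs, sample(1:20, 1))
    ranked <- sample(docs, sample(1:60, 1))
    ap <- average_precision(ranked, rel)
    pr0 <- p_at_r0(ranked, rel)
    expect_lte(ap, pr0 + 1e-12)
    expect_lte(recall_at_k(ranked, rel, 30), recall_at_k(ranked, rel, 100))
    p100 <- precision_at_k(ranked, rel, 100)
    if (p100 * 100 <= length(rel))
      expect_equal(recall_at_k(ranked, rel, 100), p100 * 100 / length(rel))
  }
})

test_that("metrics are invariant under consistent doc-id relabeling", {
  set.seed(77)
  inst <- random_run_instance()
  qr <- qrels(inst$rel$topic_id, inst$rel$doc_id)
  # distinct scores so tie-breaking by doc id cannot reorder under relabeling
  inst$run$score <- seq_len(nrow(inst$run))
  all_ids <- unique(c(inst$run$doc_id, inst$rel$doc_id))
  remap <- stats::setNames(paste0("Z", sample(length(all_ids))), all_ids)
  qr2 <- qrels(inst$rel$topic_id, unname(remap[inst$rel$doc_id]))
  run2 <- inst$run; run2$doc_id <- unname(remap[inst$run$doc_id])
  m1 <- suppressWarnings(evaluate_run(inst$run, qr))
  m2 <- suppressWarnings(evaluate_run(run2, qr2))
  expect_equal(m1$means, m2$means, tolerance = 1e-12)
})
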