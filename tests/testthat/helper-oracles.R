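# Independent brute-force oracles used to check the implementation paths.
# These deliberately re-derive everything from first principles (naive loops
# over definitions) and share no code with the package internals.

# --- retrieval metrics, naive O(n^2) from the definitions -------------------

oracle_precision_at_k <- function(ranked, relevant, k) {
  hits <- 0
  for (i in seq_len(min(k, length(ranked)))) {
    if (ranked[i] %in% relevant) hits <- hits + 1
  }
  hits / k
}

oracle_recall_at_k <- function(ranked, relevant, k) {
  if (length(relevant) == 0) return(NA_real_)
  hits <- 0
  for (i in seq_len(min(k, length(ranked)))) {
    if (ranked[i] %in% relevant) hits <- hits + 1
  }
  hits / length(relevant)
}

oracle_p_at_r0 <- function(ranked, relevant) {
  best <- 0
  for (i in seq_along(ranked)) {
    hits <- sum(ranked[seq_len(i)] %in% relevant)
    if (hits > 0) best <- max(best, hits / i)
  }
  best
}

oracle_average_precision <- function(ranked, relevant) {
  if (length(relevant) == 0) return(NA_real_)
  total <- 0
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% relevant) {
      total <- total + sum(ranked[seq_len(i)] %in% relevant) / i
    }
  }
  total / length(relevant)
}

oracle_r_precision <- function(ranked, relevant) {
  if (length(relevant) == 0) return(NA_real_)
  oracle_precision_at_k(ranked, relevant, length(relevant))
}

# random (run, qrels) instance for oracle-equivalence checks
random_run_instance <- function(n_topics_max = 8, n_docs_max = 40) {
  n_topics <- sample(n_topics_max, 1)
  topics <- paste0("T", seq_len(n_topics))
  docs <- paste0("d", sample(1000, sample(5:n_docs_max, 1)))
  run <- do.call(rbind, lapply(topics, function(t) {
    ret <- sample(docs, sample(0:length(docs), 1))
    if (length(ret) == 0) return(NULL)
    data.frame(topic_id = t, doc_id = ret, score = round(stats::runif(length(ret)), 2),
               stringsAsFactors = FALSE)
  }))
  if (is.null(run))
    run <- data.frame(topic_id = character(0), doc_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  rel <- do.call(rbind, lapply(topics, function(t) {
    r <- sample(docs, sample(0:min(10, length(docs)), 1))
    if (length(r) == 0) return(NULL)
    data.frame(topic_id = t, doc_id = r, stringsAsFactors = FALSE)
  }))
  list(run = run, rel = rel, topics = topics)
}

# --- dictionary matching, exhaustive window scan ----------------------------

# every window of every length is tested against the normalized dictionary;
# matches are then resolved left to right, keeping at each uncovered start
# the longest match beginning exactly there
oracle_match <- function(tokens, entries) {
  dict <- list()
  for (i in seq_len(nrow(entries))) {
    key_toks <- kintriage::tokenize(entries$surface[i])
    if (length(key_toks) == 0) next
    key <- paste(key_toks, collapse = " ")
    if (is.null(dict[[key]])) dict[[key]] <- entries$concept_id[i]
  }
  n <- length(tokens)
  all_matches <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      key <- paste(tokens[s:e], collapse = " ")
      if (!is.null(dict[[key]])) {
        all_matches[[length(all_matches) + 1]] <-
          list(start = s, end = e, id = dict[[key]])
      }
    }
  }
  out <- data.frame(token_start = integer(0), token_end = integer(0),
                    concept_id = character(0), stringsAsFactors = FALSE)
  pos <- 1
  while (pos <= n) {
    here <- Filter(function(m) m$start == pos, all_matches)
    if (length(here) == 0) { pos <- pos + 1; next }
    best <- here[[which.max(vapply(here, function(m) m$end, 0))]]
    out <- rbind(out, data.frame(token_start = best$start - 1L,
                                 token_end = best$end,
                                 concept_id = best$id,
                                 stringsAsFactors = FALSE))
    pos <- best$end + 1
  }
  out
}

# --- engineered features, double loop over annotation pairs -----------------

oracle_pair_distances <- function(kin, axi) {
  d <- c()
  for (i in seq_len(nrow(kin))) {
    for (j in seq_len(nrow(axi))) {
      s1 <- kin$token_start[i]; e1 <- kin$token_end[i]
      s2 <- axi$token_start[j]; e2 <- axi$token_end[j]
      gap <- if (e1 <= s2) s2 - e1 else if (e2 <= s1) s1 - e2 else 0
      d <- c(d, max(0, gap - 1))
    }
  }
  d
}

random_annotations <- function(n_tokens, n_max = 8) {
  n <- sample(0:n_max, 1)
  if (n == 0)
    return(data.frame(doc_id = character(0), token_start = integer(0),
                      token_end = integer(0), surface = character(0),
                      concept_id = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  start <- sample(0:(n_tokens - 1), n, replace = TRUE)
  len <- sample(1:3, n, replace = TRUE)
  end <- pmin(start + len, n_tokens)
  data.frame(doc_id = "d", token_start = as.integer(start),
             token_end = as.integer(end), surface = "s",
             concept_id = "c",
             category = sample(c("KINASE", "AXIS"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# --- tiny fixture pipeline helpers ------------------------------------------

write_small_benchmark <- function(dir, n_topics = 6, n_docs = 600, seed = 5,
                                  ...) {
  p <- kintriage::sim_params(n_topics = n_topics, n_docs = n_docs,
                             seed = seed, ...)
  bm <- kintriage::generate_corpus(p)
  kintriage::write_benchmark(bm, dir)
  bm
}

small_config <- function(dir, ...) {
  kintriage::run_config(
    collection = file.path(dir, "collection.bioc.xml"),
    topics = file.path(dir, "topics.tsv"),
    qrels = file.path(dir, "qrels.txt"),
    kinase_dict = file.path(dir, "kinase_dict.tsv"),
    axis_dict = file.path(dir, "axis_dict.tsv"),
    out_dir = file.path(dir, "out"),
    feature_set = "ENG", ...)
}
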