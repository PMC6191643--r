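# Self-contained synthetic benchmark with a planted kinase/axis co-mention
# signal: lexicons whose synonyms exercise the expansion rules, Zipf
# background text, topics, positives-only qrels, and a truth log recording
# every planted mention for filter/annotation tests.

#' Simulation parameters for the synthetic benchmark
#'
#' Defaults emulate the study conditions of a kinase-curation triage
#' benchmark: a right-skewed number of curated papers per kinase (lognormal
#' calibrated to mean 21.9 and median 15 papers per topic, the disease-axis
#' distribution; the biological-process axis printed 20.6/17), short
#' abstract-like token documents, and a co-mention signal in which relevant
#' documents always mention their topic's kinase and an axis term --
#' positives-only gold standards imply as much -- with the mention pair
#' falling within `window_w` tokens with probability `p_comention_relevant`.
#' Background documents mention a random kinase and axis term with
#' probability `p_comention_background` (same within-window placement
#' conditional), so setting the background parameters equal to the relevant
#' ones removes the signal among filter-passing candidates entirely.
#'
#' @param n_topics number of (kinase, axis) topics.
#' @param n_docs collection size.
#' @param vocab_size background Zipf vocabulary size.
#' @param doc_length_mean mean document length in tokens.
#' @param relevant_per_topic_mean,relevant_per_topic_median targets for the
#'   lognormal relevant-count distribution.
#' @param p_comention_relevant probability a planted pair in a relevant
#'   document lies within `window_w` tokens.
#' @param p_comention_background probability a background document carries a
#'   planted kinase/axis pair at all.
#' @param pairs_rate_relevant,pairs_rate_background Poisson rates; a
#'   planting document carries `1 + rpois(rate)` mention pairs, so relevant
#'   documents have elevated co-mention density by default.
#' @param window_w co-mention window in tokens.
#' @param seed integer seed; generation is a pure function of the params.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_topics = 20L, n_docs = 2000L, vocab_size = 5000L,
                       doc_length_mean = 80L,
                       relevant_per_topic_mean = 21.9,
                       relevant_per_topic_median = 15,
                       p_comention_relevant = 0.9,
                       p_comention_background = 0.05,
                       pairs_rate_relevant = 2,
                       pairs_rate_background = 0,
                       window_w = 10L, seed = 1L) {
  p <- list(n_topics = as.integer(n_topics), n_docs = as.integer(n_docs),
            vocab_size = as.integer(vocab_size),
            doc_length_mean = as.integer(doc_length_mean),
            relevant_per_topic_mean = relevant_per_topic_mean,
            relevant_per_topic_median = relevant_per_topic_median,
            p_comention_relevant = p_comention_relevant,
            p_comention_background = p_comention_background,
            pairs_rate_relevant = pairs_rate_relevant,
            pairs_rate_background = pairs_rate_background,
            window_w = as.integer(window_w), seed = as.integer(seed))
  if (p$p_comention_background > p$p_comention_relevant)
    stop("p_comention_background must not exceed p_comention_relevant")
  if (p$n_docs < p$n_topics * p$relevant_per_topic_mean)
    stop("infeasible params: n_docs < n_topics * relevant_per_topic_mean")
  structure(p, class = "sim_params")
}

# distinctive letter-only name stock so synthetic kinase/axis surfaces never
# collide with the background vocabulary (which is w<digits>)
.syn_name <- function(prefix, i) sprintf("%s%s", prefix, paste0(
  letters[(i %/% 26L) %% 26L + 1L], letters[i %% 26L + 1L], "q", i))

#' Generate kinase and axis lexicons
#'
#' Every kinase receives 2--6 synonyms including a multi-token spaced form
#' and a Roman-numeral form (e.g. `"<name> kinase II"`), so the synonym
#' expansion rules are exercised by construction.
#'
#' @param n_kinases,n_axis_terms counts (>= 1).
#' @param seed integer seed.
#' @return list with `kinase_lexicon` and `axis_lexicon` data frames; the
#'   axis lexicon carries an `axis` column splitting the terms between the
#'   DISEASE and BIOPROC vocabularies.
#' @export
generate_lexicons <- function(n_kinases, n_axis_terms, seed = 1L) {
  stopifnot(n_kinases >= 1L)
  if (n_axis_terms < 1L) stop("n_axis_terms must be >= 1")
  with_seed(seed, {
    roman <- c("II", "III", "IV", "VII", "IX", "XI")
    kin <- lapply(seq_len(n_kinases), function(i) {
      base <- .syn_name("kin", i)
      syns <- c(base,
                paste(base, "kinase", sample(roman, 1L)),
                paste(toupper(substr(base, 1L, 5L)), sample(99L, 1L)))
      extra <- sample(0L:3L, 1L)
      if (extra > 0L)
        syns <- c(syns, vapply(seq_len(extra), function(k)
          paste0(base, "-", sample(letters, 1L), sample(9L, 1L)), ""))
      data.frame(concept_id = sprintf("K%03d", i), surface = syns,
                 category = "KINASE", source = "synthetic",
                 stringsAsFactors = FALSE)
    })
    ax_axis <- rep(c("DISEASE", "BIOPROC"), length.out = n_axis_terms)
    ax <- data.frame(
      concept_id = sprintf("A%03d", seq_len(n_axis_terms)),
      surface = ifelse(ax_axis == "DISEASE",
                       paste(.syn_name("dis", seq_len(n_axis_terms)),
                             "syndrome"),
                       paste(.syn_name("bp", seq_len(n_axis_terms)),
                             "signaling")),
      category = "AXIS", source = "synthetic", axis = ax_axis,
      stringsAsFactors = FALSE)
    list(kinase_lexicon = do.call(rbind, kin), axis_lexicon = ax)
  })
}

# inverse-CDF categorical sampling; R's sample(prob=) scans the probability
# vector per draw, which is quadratic at corpus scale
.zipf_sample <- function(n, values, cumprob) {
  values[findInterval(stats::runif(n), cumprob) + 1L]
}

# lognormal count distribution calibrated from mean/median targets,
# rounded and clipped >= 1
.rel_counts <- function(n, mean_target, median_target) {
  mu <- log(median_target)
  sdlog <- sqrt(max(0, 2 * log(mean_target / median_target)))
  pmax(1L, as.integer(round(stats::rlnorm(n, mu, sdlog))))
}

#' Generate a synthetic triage benchmark
#'
#' Builds the complete fixture: documents (Zipf background tokens with
#' planted kinase and axis-term mentions), topics, positives-only qrels,
#' both lexicons, and a truth log of every planted span. Mention surfaces
#' are drawn from the expanded synonym set so dictionary expansion is
#' exercised end to end. Journals and years are sampled from small
#' categorical distributions (relevant documents always pre-2014, a small
#' fraction of background documents in 2014+ or with unknown year) so the
#' year filter is exercised too.
#'
#' @param params a [sim_params()] object.
#' @return object of class `synthetic_benchmark`: list with `documents`,
#'   `topics`, `qrels`, `kinase_lexicon`, `axis_lexicon`, `truth_log`,
#'   `params`.
#' @export
generate_corpus <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    lex <- generate_lexicons(p$n_topics, max(10L, p$n_topics), seed = NULL)
    kin_lex <- lex$kinase_lexicon; ax_lex <- lex$axis_lexicon
    kin_ids <- unique(kin_lex$concept_id)
    topics <- data.frame(
      topic_id = sprintf("T%03d", seq_len(p$n_topics)),
      kinase_id = kin_ids,
      axis = rep(c("DISEASE", "BIOPROC"), length.out = p$n_topics),
      stringsAsFactors = FALSE)
    topics$synonyms <- lapply(kin_ids, function(k)
      kin_lex$surface[kin_lex$concept_id == k])

    n_rel <- .rel_counts(p$n_topics, p$relevant_per_topic_mean,
                         p$relevant_per_topic_median)
    if (sum(n_rel) > p$n_docs)
      stop("infeasible params: fewer documents than drawn relevant counts")
    doc_ids <- sprintf("%07d", seq_len(p$n_docs))
    rel_topic <- rep(NA_character_, p$n_docs)
    rel_idx <- sample(p$n_docs, sum(n_rel))
    rel_topic[rel_idx] <- rep(topics$topic_id, times = n_rel)

    # background text
    zipf_p <- (1 / seq_len(p$vocab_size)); zipf_p <- zipf_p / sum(zipf_p)
    zipf_cum <- cumsum(zipf_p)
    vocab <- sprintf("w%05d", seq_len(p$vocab_size))
    lens <- pmax(20L, stats::rpois(p$n_docs, p$doc_length_mean))
    all_bg <- .zipf_sample(sum(lens), vocab, zipf_cum)
    bg <- split(all_bg, rep.int(seq_len(p$n_docs), lens))

    # which documents plant mentions, and of what
    is_rel <- !is.na(rel_topic)
    bg_mention <- !is_rel & stats::runif(p$n_docs) < p$p_comention_background
    expanded <- lapply(split(kin_lex$surface, kin_lex$concept_id),
                       expand_synonyms)
    ax_by_axis <- split(seq_len(nrow(ax_lex)), ax_lex$axis)

    truth <- vector("list", p$n_docs)
    tok <- bg
    for (i in which(is_rel | bg_mention)) {
      if (is_rel[i]) {
        tr <- match(rel_topic[i], topics$topic_id)
        kid <- topics$kinase_id[tr]
        axis <- topics$axis[tr]
        n_pairs <- 1L + stats::rpois(1L, p$pairs_rate_relevant)
        p_prox <- p$p_comention_relevant
      } else {
        kid <- sample(kin_ids, 1L)
        axis <- sample(names(ax_by_axis), 1L)
        n_pairs <- 1L + stats::rpois(1L, p$pairs_rate_background)
        p_prox <- p$p_comention_relevant
      }
      bg_toks <- tok[[i]]
      nb <- length(bg_toks)
      n_pairs <- min(n_pairs, nb)
      segs <- vector("list", n_pairs)
      klen <- alen <- gaps <- integer(n_pairs)
      aids <- character(n_pairs)
      for (q in seq_len(n_pairs)) {
        ksurf <- tokenize(sample(expanded[[kid]], 1L))
        arow <- ax_by_axis[[axis]][sample(length(ax_by_axis[[axis]]), 1L)]
        asurf <- tokenize(ax_lex$surface[arow])
        gap <- if (stats::runif(1L) < p_prox) sample(0:p$window_w, 1L)
               else p$window_w + 10L + sample(10L, 1L)
        segs[[q]] <- c(ksurf, .zipf_sample(gap, vocab, zipf_cum), asurf)
        klen[q] <- length(ksurf); alen[q] <- length(asurf); gaps[q] <- gap
        aids[q] <- ax_lex$concept_id[arow]
      }
      # distinct insertion anchors keep earlier plants' positions exact and
      # guarantee plants never interleave
      anchors <- sort(sample(nb, n_pairs))
      pieces <- vector("list", 2L * n_pairs + 1L)
      last <- 0L
      for (q in seq_len(n_pairs)) {
        pieces[[2L * q - 1L]] <- bg_toks[(last + 1L):anchors[q]]
        pieces[[2L * q]] <- segs[[q]]
        last <- anchors[q]
      }
      if (last < nb) pieces[[2L * n_pairs + 1L]] <- bg_toks[(last + 1L):nb]
      tok[[i]] <- unlist(pieces, use.names = FALSE)
      seg_starts <- anchors + c(0L, cumsum(lengths(segs)))[seq_len(n_pairs)]
      truth[[i]] <- data.frame(
        doc_id = doc_ids[i],
        topic_id = if (is_rel[i]) rel_topic[i] else NA_character_,
        concept_id = as.vector(rbind(rep(kid, n_pairs), aids)),
        category = rep(c("KINASE", "AXIS"), n_pairs),
        token_start = as.vector(rbind(seg_starts,
                                      seg_starts + klen + gaps)),
        token_end = as.vector(rbind(seg_starts + klen,
                                    seg_starts + klen + gaps + alen)),
        surface = as.vector(rbind(
          vapply(seq_len(n_pairs), function(q)
            paste(segs[[q]][seq_len(klen[q])], collapse = " "), ""),
          vapply(seq_len(n_pairs), function(q)
            paste(segs[[q]][(klen[q] + gaps[q] + 1L):(klen[q] + gaps[q] + alen[q])],
                  collapse = " "), ""))),
        within_window = rep(gaps <= p$window_w, each = 2L),
        stringsAsFactors = FALSE)
    }
    truth_log <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    if (is.null(truth_log))
      truth_log <- data.frame(doc_id = character(0), topic_id = character(0),
                              concept_id = character(0), category = character(0),
                              token_start = integer(0), token_end = integer(0),
                              surface = character(0), within_window = logical(0),
                              stringsAsFactors = FALSE)
    rownames(truth_log) <- NULL

    journals <- sprintf("J. Synth. Biol. %d", 1:10)
    jprob <- (10:1) / sum(10:1)
    jr <- sample(journals, p$n_docs, replace = TRUE, prob = jprob)
    year <- sample(1995:2013, p$n_docs, replace = TRUE)
    late <- !is_rel & stats::runif(p$n_docs) < 0.03
    year[late] <- sample(2014:2016, sum(late), replace = TRUE)
    missing_year <- !is_rel & !late & stats::runif(p$n_docs) < 0.02
    year[missing_year] <- NA_integer_

    title_len <- pmin(8L, lengths(tok))
    titles <- vapply(seq_len(p$n_docs), function(i)
      paste(tok[[i]][seq_len(title_len[i])], collapse = " "), "")
    abstracts <- vapply(seq_len(p$n_docs), function(i)
      paste(tok[[i]][-seq_len(title_len[i])], collapse = " "), "")
    docs <- document_set(doc_id = doc_ids, title = titles,
                         abstract = abstracts, journal = jr, year = year,
                         pub_types = sample(c("Journal Article", "Review"),
                                            p$n_docs, TRUE, prob = c(.9, .1)))
    qr <- qrels(topic_id = rel_topic[is_rel], doc_id = doc_ids[is_rel])
    structure(list(documents = docs, topics = topics, qrels = qr,
                   kinase_lexicon = kin_lex, axis_lexicon = ax_lex,
                   truth_log = truth_log, params = p),
              class = "synthetic_benchmark")
  })
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("synthetic_benchmark:", nrow(x$documents), "documents,",
      nrow(x$topics), "topics,",
      sum(x$qrels$judgments$relevance), "positive judgments\n")
  invisible(x)
}

#' Thin a benchmark to emulate full-text availability
#'
#' Uniformly subsamples the collection to `keep_fraction` (binomial
#' thinning), dropping qrels positives and truth-log entries with the
#' removed documents -- the open-access attrition that shrinks
#' relevant-per-topic counts proportionally in expectation. Kept documents
#' get their abstract copied into the body to mimic full-text input.
#'
#' @param benchmark a `synthetic_benchmark`.
#' @param keep_fraction fraction of documents to keep, in (0, 1].
#' @param seed integer seed.
#' @return a new `synthetic_benchmark`.
#' @export
degrade_to_fulltext_benchmark <- function(benchmark, keep_fraction, seed = 1L) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  if (keep_fraction == 1) return(benchmark)
  docs <- benchmark$documents
  keep <- with_seed(seed, stats::runif(nrow(docs)) < keep_fraction)
  kept_ids <- docs$doc_id[keep]
  docs <- docs[keep, , drop = FALSE]
  docs$body <- docs$abstract
  rownames(docs) <- NULL
  j <- benchmark$qrels$judgments
  j <- j[j$doc_id %in% kept_ids, , drop = FALSE]
  out <- benchmark
  out$documents <- docs
  out$qrels <- qrels(j$topic_id, j$doc_id, j$relevance)
  out$truth_log <- benchmark$truth_log[
    benchmark$truth_log$doc_id %in% kept_ids, , drop = FALSE]
  out
}

#' Write a benchmark fixture directory
#'
#' Emits `collection.bioc.xml`, `topics.tsv`, `qrels.txt`,
#' `kinase_dict.tsv`, `axis_dict.tsv`, `truth_log.tsv` and `params.json`.
#'
#' @param benchmark a `synthetic_benchmark`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bioc_collection(benchmark$documents,
                        file.path(dir, "collection.bioc.xml"),
                        source = "kintriage-synthetic")
  write_topics(benchmark$topics, file.path(dir, "topics.tsv"))
  write_qrels(benchmark$qrels, file.path(dir, "qrels.txt"))
  kl <- benchmark$kinase_lexicon
  writeLines(sprintf("%s\t%s", kl$concept_id, kl$surface),
             file.path(dir, "kinase_dict.tsv"), useBytes = TRUE)
  al <- benchmark$axis_lexicon
  writeLines(sprintf("%s\t%s\t%s", al$concept_id, al$surface, al$axis),
             file.path(dir, "axis_dict.tsv"), useBytes = TRUE)
  utils::write.table(benchmark$truth_log, file.path(dir, "truth_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(unclass(benchmark$params), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA),
             file.path(dir, "params.json"))
  invisible(dir)
}
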