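# End-to-end orchestration: annotate -> cross-reference filter -> featurize
# -> pseudo-negative sampling -> train -> rank -> run file -> evaluation.

#' Pipeline configuration
#'
#' All seeds are explicit (no wall-clock defaults) so a configuration fully
#' determines its outputs; the configuration is echoed into the output
#' directory as JSON.
#'
#' @param collection,topics,qrels,kinase_dict,axis_dict input file paths
#'   (`qrels` may be `NULL`: the run is still produced, evaluation skipped).
#' @param out_dir output directory.
#' @param cutoff_year drop documents published in this year or later
#'   (`NULL` disables the filter). Default 2014: the benchmark collection
#'   was frozen when curation ended in 2013.
#' @param model_family,feature_set scorer configuration (see
#'   [triage_scorer()], [pair_features()]).
#' @param sampling `"random"` or `"one_class"` pseudo-negative strategy.
#' @param sampling_fraction fraction of non-positive candidates used as
#'   pseudo-negatives (the track systems used 10--20%).
#' @param per_topic train one model per topic instead of pooled per axis.
#' @param cross_reference restrict each topic's candidates to documents
#'   passing cross-reference validation (escape hatch for ranking the whole
#'   collection).
#' @param depth ranking depth (matches the deepest evaluation rank).
#' @param expand_kinase_dict apply synonym expansion to the kinase
#'   dictionary.
#' @param min_df,ngram_min,ngram_max bag-of-words vocabulary controls.
#' @param cost,gamma,alpha,lambda scorer hyperparameters.
#' @param seed master seed for sampling and training.
#' @param tag run tag written into the TREC run file.
#' @return list of class `run_config`.
#' @export
run_config <- function(collection, topics, kinase_dict, axis_dict,
                       qrels = NULL, out_dir = tempfile("kintriage_run_"),
                       cutoff_year = 2014L,
                       model_family = c("margin_linear", "margin_gaussian",
                                        "elastic_net"),
                       feature_set = c("ENG", "EXTENDED", "BOW",
                                       "BOW_PLUS_ENG"),
                       sampling = c("random", "one_class"),
                       sampling_fraction = 0.15, per_topic = FALSE,
                       cross_reference = TRUE, depth = 100L,
                       expand_kinase_dict = TRUE, min_df = 2L,
                       ngram_min = 2L, ngram_max = 3L,
                       cost = 1, gamma = NULL, alpha = 0.5, lambda = 0.01,
                       seed = 1L, tag = "kintriage") {
  cfg <- list(collection = collection, topics = topics, qrels = qrels,
              kinase_dict = kinase_dict, axis_dict = axis_dict,
              out_dir = out_dir, cutoff_year = cutoff_year,
              model_family = match.arg(model_family),
              feature_set = match.arg(feature_set),
              sampling = match.arg(sampling),
              sampling_fraction = sampling_fraction,
              per_topic = isTRUE(per_topic),
              cross_reference = isTRUE(cross_reference),
              depth = as.integer(depth),
              expand_kinase_dict = isTRUE(expand_kinase_dict),
              min_df = as.integer(min_df), ngram_min = as.integer(ngram_min),
              ngram_max = as.integer(ngram_max),
              cost = cost, gamma = gamma, alpha = alpha, lambda = lambda,
              seed = as.integer(seed), tag = tag)
  if (cfg$sampling_fraction <= 0 || cfg$sampling_fraction > 1)
    stop("config-validation error: sampling_fraction must be in (0, 1]")
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' @param path JSON file.
#' @return [read_config()] returns a `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, TRUE)])
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              pretty = TRUE, null = "null", digits = NA),
             path)
  invisible(path)
}

# candidate (topic, doc) pairs after cross-reference validation, from
# collection-level annotations; axis annotations carry their axis label
.topic_candidates <- function(topics, annotations, all_doc_ids,
                              cross_reference = TRUE) {
  if (!cross_reference) {
    return(stats::setNames(rep(list(all_doc_ids), nrow(topics)),
                           topics$topic_id))
  }
  kin <- annotations[annotations$category == "KINASE", , drop = FALSE]
  axi <- annotations[annotations$category == "AXIS", , drop = FALSE]
  kin_docs <- split(kin$doc_id, kin$concept_id)
  axi_docs <- split(axi$doc_id, axi$axis)
  out <- lapply(seq_len(nrow(topics)), function(i) {
    k <- unique(kin_docs[[topics$kinase_id[i]]])
    a <- unique(axi_docs[[topics$axis[i]]])
    sort(intersect(k, a))
  })
  stats::setNames(out, topics$topic_id)
}

#' Run the full triage pipeline
#'
#' Executes annotation, cross-reference filtering, feature extraction,
#' pseudo-negative sampling, training (pooled per axis by default), ranking
#' and, when qrels are supplied, evaluation. Per-stage counts are logged via
#' `message()`; the TREC run file, per-stage TSV artifacts and the echoed
#' configuration are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `run` (canonical
#'   run data frame), `report` (`metrics_report` or `NULL`), `candidates`
#'   (per-topic candidate lists), `scorers`, and `counts` (named per-stage
#'   tallies).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- function(...) message("[kintriage] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(config$out_dir, "config.json"))

  docs <- read_bioc_collection(config$collection)
  topics <- read_topics(config$topics)
  qr <- if (!is.null(config$qrels)) read_qrels(config$qrels) else NULL
  log("collection: ", nrow(docs), " documents, ", nrow(topics), " topics")

  n_docs_in <- nrow(docs)
  if (!is.null(config$cutoff_year)) {
    docs <- filter_by_year(docs, config$cutoff_year)
    log("year filter (< ", config$cutoff_year, "): ", nrow(docs),
        " kept, ", attr(docs, "dropped_missing_year"), " with unknown year")
  }

  kin_lex <- read_dictionary(config$kinase_dict, "KINASE",
                             expand = config$expand_kinase_dict)
  ax_lex <- read_dictionary(config$axis_dict, "AXIS", expand = FALSE)
  kin_m <- build_matcher(kin_lex)
  ax_m <- build_matcher(ax_lex)

  tokens <- tokenize_documents(docs)
  ann <- annotate_collection(docs, kin_m, ax_m, tokens = tokens)
  annotations <- ann$annotations
  # axis annotations carry their vocabulary's axis label for per-topic
  # filtering; without one, any axis term validates any topic
  if ("axis" %in% names(ax_lex)) {
    annotations$axis <- NA_character_
    ai <- annotations$category == "AXIS"
    annotations$axis[ai] <- ax_lex$axis[match(annotations$concept_id[ai],
                                              ax_lex$concept_id)]
  }
  log("annotation: ", sum(annotations$category == "KINASE"), " kinase + ",
      sum(annotations$category == "AXIS"), " axis mentions in ",
      length(unique(annotations$doc_id)), " documents")
  utils::write.table(annotations, file.path(config$out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  candidates <- .topic_candidates(topics, annotations, docs$doc_id,
                                  config$cross_reference)
  log("cross-reference filter: ", sum(lengths(candidates)),
      " (topic, doc) candidates over ", nrow(topics), " topics")

  pairs <- data.frame(
    topic_id = rep(names(candidates), lengths(candidates)),
    doc_id = unlist(candidates, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) stop("stage candidates: no documents passed the filter")

  bow <- NULL
  if (config$feature_set %in% c("BOW", "BOW_PLUS_ENG")) {
    cand_docs <- unique(pairs$doc_id)
    idx <- match(cand_docs, docs$doc_id)
    ptoks <- lapply(idx, function(i)
      preprocess(c(docs$title[i], docs$abstract[i], docs$body[i])))
    names(ptoks) <- cand_docs
    vocab <- fit_bow_vocabulary(ptoks, min_df = config$min_df,
                                ngram_range = c(config$ngram_min,
                                                config$ngram_max))
    bow <- list(vocabulary = vocab, tokens = ptoks)
    log("bow vocabulary: ", length(vocab$terms), " n-grams")
  }
  x <- pair_features(pairs, topics, annotations, ann$n_tokens,
                     feature_set = config$feature_set, bow = bow)
  if (config$feature_set %in% c("ENG", "EXTENDED"))
    utils::write.table(cbind(pairs, as.data.frame(as.matrix(x))),
                       file.path(config$out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  scorers <- list()
  run_rows <- list()
  if (is.null(qr)) {
    # no judgments to train on: fall back to the unsupervised concept-density
    # heuristic (co-mention density and proximity), evaluation skipped
    log("notice: no qrels supplied; unsupervised density ranking, ",
        "evaluation skipped")
    xf <- pair_features(pairs, topics, annotations, ann$n_tokens, "ENG")
    scores <- xf[, "relevancy_score"] + xf[, "proximity10_count"] +
      0.1 * xf[, "proximity50_count"] - xf[, "proximity_score"] / 1e6
    for (tid in unique(pairs$topic_id)) {
      sel <- which(pairs$topic_id == tid)
      run_rows[[tid]] <- rank_topic(NULL, tid, pairs$doc_id[sel],
                                    depth = config$depth,
                                    scores = scores[sel])
    }
    run <- do.call(rbind, run_rows)
    run$tag <- config$tag
    run <- canonicalize_run(run)
    write_run(run, file.path(config$out_dir, "run.txt"))
    return(structure(list(run = run, report = NULL, candidates = candidates,
                          scorers = scorers,
                          counts = c(docs_in = n_docs_in,
                                     docs_after_year = nrow(docs),
                                     candidates = nrow(pairs),
                                     positives = NA_integer_)),
                     class = "pipeline_result"))
  }

  groups <- if (config$per_topic) split(seq_len(nrow(pairs)), pairs$topic_id)
            else split(seq_len(nrow(pairs)),
                       topics$axis[match(pairs$topic_id, topics$topic_id)])
  rel <- qrels_relevance(qr, pairs$topic_id, pairs$doc_id)

  for (g in names(groups)) {
    gi <- groups[[g]]
    gpos <- gi[rel[gi] == 1L]
    gneg_pool <- gi[rel[gi] == 0L]
    if (length(gpos) == 0L)
      stop("stage training (", g, "): no gold positives among candidates")
    key <- function(i) paste0(pairs$topic_id[i], "\r", pairs$doc_id[i])
    if (length(gneg_pool) == 0L)
      stop("stage training (", g, "): no non-positive candidates to sample ",
           "pseudo-negatives from; enlarge the collection or disable ",
           "cross-reference filtering")
    if (config$sampling == "random") {
      picked <- sample_random_pseudo_negatives(
        key(gneg_pool), key(gpos), config$sampling_fraction,
        seed = config$seed + match(g, names(groups)))
      gneg <- gneg_pool[match(picked, key(gneg_pool))]
      if (length(gneg) == 0L) {
        # the sampling fraction rounded to zero on a tiny pool: training
        # still needs both classes, so take a single pseudo-negative
        gneg <- gneg_pool[with_seed(config$seed + match(g, names(groups)),
                                    sample(length(gneg_pool), 1L))]
      }
    } else {
      n_sel <- max(1L, round(config$sampling_fraction * length(gneg_pool)))
      xm <- as.matrix(x)
      unl <- xm[gneg_pool, , drop = FALSE]
      rownames(unl) <- as.character(gneg_pool)
      picked <- one_class_pseudo_negatives(
        xm[gpos, , drop = FALSE], unl, n_select = n_sel,
        seed = config$seed + match(g, names(groups)))
      gneg <- as.integer(picked)
    }
    log("training group ", g, ": ", length(gpos), " positives, ",
        length(gneg), " pseudo-negatives (", config$sampling, ")")
    ti <- c(gpos, gneg)
    scorer <- triage_scorer(x[ti, , drop = FALSE],
                            labels = c(rep(1L, length(gpos)),
                                       rep(-1L, length(gneg))),
                            family = config$model_family,
                            cost = config$cost, gamma = config$gamma,
                            alpha = config$alpha, lambda = config$lambda,
                            seed = config$seed)
    scorers[[g]] <- scorer
    gtopics <- unique(pairs$topic_id[gi])
    for (tid in gtopics) {
      sel <- gi[pairs$topic_id[gi] == tid]
      run_rows[[tid]] <- rank_topic(scorer, tid, pairs$doc_id[sel],
                                    x[sel, , drop = FALSE],
                                    depth = config$depth)
    }
  }
  run <- do.call(rbind, run_rows)
  run$tag <- config$tag
  run <- canonicalize_run(run)
  run_path <- file.path(config$out_dir, "run.txt")
  write_run(run, run_path)
  log("run: ", nrow(run), " entries -> ", run_path)

  report <- NULL
  if (!is.null(qr)) {
    report <- evaluate_run(run, qr)
    log("evaluation: MAP ", sprintf("%.4f", report$means[["average_precision"]]),
        " over ", report$n_topics_evaluated, " topics")
    utils::write.table(report$per_topic,
                       file.path(config$out_dir, "metrics_per_topic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(run = run, report = report, candidates = candidates,
                 scorers = scorers,
                 counts = c(docs_in = n_docs_in, docs_after_year = nrow(docs),
                            candidates = nrow(pairs),
                            positives = sum(rel == 1L))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$counts[["candidates"]], "candidates ranked,",
      length(x$scorers), "scorer(s)\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
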