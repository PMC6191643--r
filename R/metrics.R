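# TREC evaluation metrics with trec_eval conventions: precision/recall at
# fixed ranks, maximum precision over ranks ("P at R0"), average precision
# dividing by the total number of relevant documents, and R-precision.

.rel_flags <- function(ranked_doc_ids, relevant) {
  as.integer(ranked_doc_ids %in% relevant)
}

#' Precision at rank k
#'
#' Fraction of the top `k` ranked documents that are relevant. Lists shorter
#' than `k` are treated as padded with non-relevant documents: the
#' denominator stays `k`.
#'
#' @param ranked_doc_ids character vector of doc ids in rank order.
#' @param relevant character vector of relevant doc ids (or a `qrels` object
#'   together with `topic_id`).
#' @param k rank cutoff, `>= 1`.
#' @param topic_id topic to look up when `relevant` is a `qrels` object.
#' @return precision in `[0, 1]`.
#' @export
precision_at_k <- function(ranked_doc_ids, relevant, k, topic_id = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  relevant <- .as_relevant(relevant, topic_id)
  top <- utils::head(ranked_doc_ids, k)
  sum(.rel_flags(top, relevant)) / k
}

.as_relevant <- function(relevant, topic_id) {
  if (inherits(relevant, "qrels")) {
    if (is.null(topic_id)) stop("topic_id required with a qrels object")
    j <- relevant$judgments
    j$doc_id[j$topic_id == topic_id & j$relevance == 1L]
  } else as.character(relevant)
}

#' Recall at rank k
#'
#' Fraction of all relevant documents retrieved in the top `k`. Undefined
#' (returns `NA`) for topics with no relevant documents; such topics are
#' excluded from macro averages.
#'
#' @inheritParams precision_at_k
#' @return recall in `[0, 1]`, or `NA` when there are no relevant documents.
#' @export
recall_at_k <- function(ranked_doc_ids, relevant, k, topic_id = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  relevant <- .as_relevant(relevant, topic_id)
  if (length(relevant) == 0L) return(NA_real_)
  sum(.rel_flags(utils::head(ranked_doc_ids, k), relevant)) / length(relevant)
}

#' Maximum precision over all ranks (P at R0)
#'
#' The maximum of precision-at-k over the actual submitted list (no
#' padding); 0 when no relevant document is retrieved. For binary
#' judgments this equals interpolated precision at recall 0.
#'
#' @inheritParams precision_at_k
#' @return value in `[0, 1]`.
#' @export
p_at_r0 <- function(ranked_doc_ids, relevant, topic_id = NULL) {
  relevant <- .as_relevant(relevant, topic_id)
  n <- length(ranked_doc_ids)
  if (n == 0L) return(0)
  flags <- .rel_flags(ranked_doc_ids, relevant)
  if (!any(flags == 1L)) return(0)
  max(cumsum(flags) / seq_len(n))
}

#' Average precision
#'
#' Sum of precision at each rank holding a relevant document, divided by the
#' total number of relevant documents for the topic (the trec_eval
#' convention: relevant documents never retrieved contribute zero).
#'
#' @inheritParams precision_at_k
#' @return value in `[0, 1]`, or `NA` when there are no relevant documents.
#' @export
average_precision <- function(ranked_doc_ids, relevant, topic_id = NULL) {
  relevant <- .as_relevant(relevant, topic_id)
  if (length(relevant) == 0L) return(NA_real_)
  n <- length(ranked_doc_ids)
  if (n == 0L) return(0)
  flags <- .rel_flags(ranked_doc_ids, relevant)
  prec <- cumsum(flags) / seq_len(n)
  sum(prec[flags == 1L]) / length(relevant)
}

#' R-precision
#'
#' Precision at rank r, where r is the topic's number of relevant documents.
#'
#' @inheritParams precision_at_k
#' @return value in `[0, 1]`, or `NA` when there are no relevant documents.
#' @export
r_precision <- function(ranked_doc_ids, relevant, topic_id = NULL) {
  relevant <- .as_relevant(relevant, topic_id)
  if (length(relevant) == 0L) return(NA_real_)
  precision_at_k(ranked_doc_ids, relevant, length(relevant))
}

#' Evaluate a run against qrels
#'
#' Computes the full metric suite (P@10/30/100, R@30/100, P at R0, average
#' precision, R-precision) per topic and macro-averaged. Every topic present
#' in the qrels with at least one relevant document is evaluated; topics
#' missing from the run score zero throughout. Topics appearing in the run
#' but not in the qrels are ignored with a warning.
#'
#' @param run run data frame (see [read_run()]); canonicalized before
#'   scoring.
#' @param qr a `qrels` object.
#' @return object of class `metrics_report`: list with `per_topic` (data
#'   frame), `means` (named numeric vector) and `n_topics_evaluated`.
#' @export
evaluate_run <- function(run, qr) {
  stopifnot(inherits(qr, "qrels"))
  run <- canonicalize_run(run)
  pos <- qrels_positives(qr)
  pos <- pos[lengths(pos) > 0L]
  extra <- setdiff(unique(run$topic_id), names(pos))
  if (length(extra))
    warning("run topics absent from qrels ignored: ",
            paste(extra, collapse = ", "))
  by_topic <- split(run$doc_id, run$topic_id)
  rows <- lapply(names(pos), function(tid) {
    ranked <- if (tid %in% names(by_topic)) by_topic[[tid]] else character(0)
    rel <- pos[[tid]]
    data.frame(
      topic_id = tid,
      p10 = precision_at_k(ranked, rel, 10),
      p30 = precision_at_k(ranked, rel, 30),
      p100 = precision_at_k(ranked, rel, 100),
      r30 = recall_at_k(ranked, rel, 30),
      r100 = recall_at_k(ranked, rel, 100),
      p_at_r0 = p_at_r0(ranked, rel),
      average_precision = average_precision(ranked, rel),
      r_prec = r_precision(ranked, rel),
      n_relevant = length(rel),
      n_retrieved = length(ranked),
      stringsAsFactors = FALSE
    )
  })
  per_topic <- do.call(rbind, rows)
  metric_cols <- c("p10", "p30", "p100", "r30", "r100", "p_at_r0",
                   "average_precision", "r_prec")
  if (is.null(per_topic)) {
    per_topic <- data.frame(topic_id = character(0))
    for (m in metric_cols) per_topic[[m]] <- numeric(0)
    per_topic$n_relevant <- integer(0); per_topic$n_retrieved <- integer(0)
  }
  means <- colMeans(per_topic[, metric_cols, drop = FALSE])
  structure(list(per_topic = per_topic, means = means,
                 n_topics_evaluated = nrow(per_topic)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Evaluation over", x$n_topics_evaluated, "topics\n")
  lab <- c(p10 = "P10", p30 = "P30", p100 = "P100", r30 = "R30",
           r100 = "R100", p_at_r0 = "P_at_R0", average_precision = "MAP",
           r_prec = "R-prec")
  for (m in names(lab))
    cat(sprintf("  %-8s\t%.4f\n", lab[[m]], x$means[[m]]))
  invisible(x)
}
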