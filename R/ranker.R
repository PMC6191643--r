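# Supervised triage ranking: pseudo-negative assembly (random or one-class),
# a margin-based / elastic-net scorer behind a classic fitted-model S3
# object, per-topic ranking, and the two reference baselines.

#' Sample random pseudo-negatives
#'
#' Curated gold standards store accepted papers only, so negatives for
#' training are drawn from the unlabeled pool: a uniform sample without
#' replacement of `round(fraction * n)` of the non-positive candidates
#' (the 10--20% random-sampling strategy).
#'
#' @param candidates character vector of candidate doc ids (documents that
#'   passed cross-reference validation).
#' @param positives character vector (or set) of gold-positive doc ids.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed; the sample is a pure function of it.
#' @return character vector of sampled doc ids (never a gold positive).
#' @export
sample_random_pseudo_negatives <- function(candidates, positives, fraction,
                                           seed) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  pool <- setdiff(as.character(candidates), as.character(positives))
  n <- round(fraction * length(pool))
  if (n == 0L) return(character(0))
  with_seed(seed, sample(pool, n))
}

#' One-class pseudo-negative selection
#'
#' Fits a one-class model on the positive feature vectors and selects the
#' unlabeled instances least like the positives. The default model scores an
#' unlabeled vector by its negative Euclidean distance to the positive
#' centroid after per-feature standardization; a support-vector one-class
#' variant (`method = "svm"`) is available.
#'
#' @param positive_x numeric matrix of positive feature vectors (>= 5 rows).
#' @param unlabeled_x numeric matrix of unlabeled feature vectors with
#'   rownames as doc ids.
#' @param n_select number of pseudo-negatives to return.
#' @param seed integer seed (used by the SVM variant; selection is
#'   deterministic given it).
#' @param method `"centroid"` (default) or `"svm"`.
#' @return doc ids of the `n_select` lowest-scoring unlabeled instances,
#'   ordered most-unlike-positives first.
#' @export
one_class_pseudo_negatives <- function(positive_x, unlabeled_x, n_select,
                                       seed = 1L,
                                       method = c("centroid", "svm")) {
  method <- match.arg(method)
  positive_x <- as.matrix(positive_x); unlabeled_x <- as.matrix(unlabeled_x)
  if (nrow(positive_x) < 5L) stop("need >= 5 positive vectors")
  if (n_select > nrow(unlabeled_x)) stop("n_select exceeds unlabeled pool")
  if (all(apply(positive_x, 2, function(col) length(unique(col)) == 1L)))
    stop("degenerate positives (all identical); use random sampling instead")
  if (n_select == 0L) return(character(0))
  ids <- rownames(unlabeled_x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(unlabeled_x)))
  if (method == "centroid") {
    mu <- colMeans(positive_x)
    sdv <- apply(positive_x, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    z <- sweep(sweep(unlabeled_x, 2, mu), 2, sdv, "/")
    score <- -sqrt(rowSums(z^2))
  } else {
    fit <- with_seed(seed, e1071::svm(positive_x, y = NULL,
                                      type = "one-classification",
                                      kernel = "radial"))
    score <- as.numeric(attr(stats::predict(fit, unlabeled_x,
                                            decision.values = TRUE),
                             "decision.values"))
  }
  o <- order(score, ids, method = "radix")  # doc id breaks exact ties
  ids[o][seq_len(n_select)]
}

#' Fit a triage scorer
#'
#' Trains the binary relevance scorer on a labeled feature matrix: a
#' margin-based classifier (support-vector machine with linear or Gaussian
#' kernel) or an elastic-net regularized logistic model. Returns a fitted
#' model object whose `predict()` method yields confidence scores (higher =
#' more relevant); only the score ordering matters for ranking.
#'
#' @param x numeric feature matrix (rows = training instances); sparse
#'   matrices are accepted for bag-of-words features.
#' @param labels vector in \{+1, -1\} (or logical).
#' @param family `"margin_linear"`, `"margin_gaussian"` or `"elastic_net"`.
#' @param cost regularization strength C for the margin families.
#' @param gamma Gaussian kernel bandwidth; default `NULL` uses the median
#'   pairwise-distance heuristic.
#' @param alpha elastic-net mixing (1 = lasso, 0 = ridge).
#' @param lambda elastic-net penalty.
#' @param class_weights `"balanced"` (inverse class frequency) or a named
#'   vector for classes `"1"` and `"-1"`.
#' @param seed integer seed stored with the model; training is deterministic
#'   given it.
#' @return object of class `triage_scorer`.
#' @export
triage_scorer <- function(x, labels,
                          family = c("margin_linear", "margin_gaussian",
                                     "elastic_net"),
                          cost = 1, gamma = NULL, alpha = 0.5, lambda = 0.01,
                          class_weights = "balanced", seed = 1L) {
  family <- match.arg(family)
  y <- if (is.logical(labels)) ifelse(labels, 1L, -1L) else as.integer(labels)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop("single-class input: both labels required")
  nas <- which(apply(x, 1, function(r) any(!is.finite(r))))
  if (length(nas)) {
    offender <- if (!is.null(rownames(x))) rownames(x)[nas[1]] else nas[1]
    stop("non-finite feature values in instance ", offender)
  }
  w <- if (identical(class_weights, "balanced")) {
    tab <- table(factor(y, levels = c(-1L, 1L)))
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else class_weights
  fit <- if (family == "elastic_net") {
    xm <- if (inherits(x, "sparseMatrix")) x else as.matrix(x)
    obs_w <- w[as.character(y)]
    with_seed(seed, glmnet::glmnet(xm, factor(y, levels = c(-1L, 1L)),
                                   family = "binomial", alpha = alpha,
                                   lambda = lambda, weights = obs_w,
                                   standardize = TRUE))
  } else {
    xm <- as.matrix(x)
    if (family == "margin_gaussian" && is.null(gamma)) {
      d <- stats::dist(xm[with_seed(seed, sample(nrow(xm),
                                                 min(nrow(xm), 200L))), ,
                          drop = FALSE])
      med <- stats::median(d[d > 0])
      if (!is.finite(med) || med == 0) med <- 1
      gamma <- 1 / (2 * med^2)
    }
    with_seed(seed, e1071::svm(
      xm, factor(y, levels = c(-1L, 1L)),
      kernel = if (family == "margin_linear") "linear" else "radial",
      cost = cost, gamma = if (is.null(gamma)) 1 / ncol(xm) else gamma,
      class.weights = w, scale = apply(xm, 2, function(c) stats::sd(c) > 0)))
  }
  structure(list(family = family, fit = fit, cost = cost, gamma = gamma,
                 alpha = alpha, lambda = lambda, class_weights = w,
                 seed = seed, n_features = ncol(x),
                 feature_names = colnames(x),
                 n_pos = sum(y == 1L), n_neg = sum(y == -1L)),
            class = "triage_scorer")
}

#' @export
print.triage_scorer <- function(x, ...) {
  cat("triage_scorer (", x$family, "): ", x$n_pos, " positives, ", x$n_neg,
      " pseudo-negatives, ", x$n_features, " features\n", sep = "")
  invisible(x)
}

#' @export
summary.triage_scorer <- function(object, ...) {
  print(object)
  if (object$family == "elastic_net") {
    cf <- coef(object)
    cat("nonzero coefficients:", sum(cf != 0), "of", length(cf), "\n")
  } else {
    cat("support vectors:", object$fit$tot.nSV, "\n")
  }
  invisible(object)
}

#' @export
coef.triage_scorer <- function(object, ...) {
  if (object$family == "elastic_net") {
    cf <- as.matrix(stats::coef(object$fit))[, 1]
    return(cf)
  }
  if (object$family == "margin_linear") {
    # w = t(coefs) %*% SV in the svm's scaled space; report raw weights
    sv <- object$fit
    w <- crossprod(sv$coefs, sv$SV)[1, ]
    return(stats::setNames(as.numeric(w), colnames(sv$SV)))
  }
  stop("coefficients are not defined for the Gaussian-kernel scorer")
}

#' Score new documents
#'
#' @param object a fitted `triage_scorer`.
#' @param newx feature matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of confidence scores, higher = more relevant.
#' @export
predict.triage_scorer <- function(object, newx, ...) {
  if (object$family == "elastic_net") {
    xm <- if (inherits(newx, "sparseMatrix")) newx else as.matrix(newx)
    as.numeric(stats::predict(object$fit, xm, type = "link"))
  } else {
    p <- stats::predict(object$fit, as.matrix(newx), decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # libsvm orients the decision value by the first training label; flip so
    # that higher always means the +1 class
    sgn <- if (colnames(dv)[1] == "-1/1") -1 else 1
    sgn * as.numeric(dv[, 1])
  }
}

#' Rank a topic's candidate documents
#'
#' Scores candidates with a fitted scorer and returns them ordered by score
#' descending, ties broken by doc id descending (matching the run-file
#' canonicalization), truncated to `depth`.
#'
#' @param scorer a `triage_scorer` (or `NULL` together with `scores`).
#' @param topic_id topic identifier.
#' @param doc_ids candidate doc ids (should have passed cross-reference
#'   validation for this topic).
#' @param x candidate feature matrix, rows aligned with `doc_ids`.
#' @param depth maximum list length (the evaluation depth; default 100).
#' @param scores pre-computed scores, bypassing the scorer.
#' @return data frame `topic_id`, `doc_id`, `rank`, `score`.
#' @export
rank_topic <- function(scorer, topic_id, doc_ids, x = NULL, depth = 100L,
                       scores = NULL) {
  if (length(doc_ids) == 0L)
    return(data.frame(topic_id = character(0), doc_id = character(0),
                      rank = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  if (is.null(scores)) scores <- predict(scorer, x)
  o <- order(as.numeric(scores), as.character(doc_ids),
             decreasing = c(TRUE, TRUE), method = "radix")
  o <- utils::head(o, depth)
  data.frame(topic_id = topic_id, doc_id = as.character(doc_ids)[o],
             rank = seq_along(o), score = as.numeric(scores)[o],
             stringsAsFactors = FALSE)
}

#' Baseline: random permutation run
#'
#' Ranks, for every topic, a random permutation of the supplied document
#' pool truncated at `depth`. With the full collection as the pool this is
#' the no-knowledge reference system; with per-topic candidate sets it
#' isolates the contribution of the trained scorer from that of the
#' cross-reference filter.
#'
#' @param pool character vector of doc ids, or a named list of per-topic
#'   candidate vectors.
#' @param topic_ids topics to cover (defaults to `names(pool)` for a list).
#' @param depth list depth.
#' @param seed integer seed.
#' @return run data frame.
#' @export
baseline_random_run <- function(pool, topic_ids = NULL, depth = 100L,
                                seed = 1L) {
  if (is.list(pool)) {
    if (is.null(topic_ids)) topic_ids <- names(pool)
  } else stopifnot(!is.null(topic_ids))
  with_seed(seed, {
    rows <- lapply(topic_ids, function(tid) {
      p <- if (is.list(pool)) pool[[tid]] else pool
      picked <- utils::head(sample(p, length(p)), depth)
      if (length(picked) == 0L) return(NULL)
      data.frame(topic_id = tid, doc_id = picked,
                 rank = seq_along(picked),
                 score = rev(seq_along(picked)) / length(picked),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Baseline: journal-frequency run
#'
#' Scores every document in the pool by how often its journal appears among
#' the gold-positive documents of the training qrels, then ranks per topic.
#' A crude prior -- curated papers concentrate in a few journals -- used as a
#' reference point for the trained ranker.
#'
#' @param docs document data frame (for the journal lookup).
#' @param pool doc ids to rank (vector, or named per-topic list).
#' @param topic_ids topics to cover.
#' @param train_qrels `qrels` supplying the positives whose journals define
#'   the frequency table.
#' @param depth list depth.
#' @return run data frame.
#' @export
baseline_journal_run <- function(docs, pool, topic_ids = NULL, train_qrels,
                                 depth = 100L) {
  if (is.list(pool) && is.null(topic_ids)) topic_ids <- names(pool)
  pos_docs <- unique(train_qrels$judgments$doc_id[
    train_qrels$judgments$relevance == 1L])
  jtab <- table(docs$journal[docs$doc_id %in% pos_docs])
  jscore <- function(ids) {
    j <- docs$journal[match(ids, docs$doc_id)]
    s <- as.numeric(jtab[j])
    s[is.na(s)] <- 0
    s
  }
  rows <- lapply(topic_ids, function(tid) {
    p <- if (is.list(pool)) pool[[tid]] else pool
    if (length(p) == 0L) return(NULL)
    rank_topic(NULL, tid, p, depth = depth, scores = jscore(p))
  })
  do.call(rbind, rows)
}
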