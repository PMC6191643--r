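# Feature families for the ranker: six engineered kinase/axis proximity
# features, 2-/3-gram TFIDF bag-of-words vectors, and entity
# frequency/position features.

#' Engineered kinase--axis features
#'
#' Computes the six engineered features from one document's annotations:
#' kinase score (kinase annotations per token), axis score, relevancy score
#' (their product), proximity score (minimum token distance over all
#' kinase-axis annotation pairs), and the number of pairs within 10 and
#' within 50 words. The distance between two spans (0-based, end-exclusive)
#' is the number of token positions strictly between their nearer ends, so
#' adjacent or overlapping spans are at distance 0. Multi-token annotations
#' count once.
#'
#' @param annotations annotation data frame for one document (see
#'   [annotate()]).
#' @param n_tokens total token count of the document; must be positive.
#' @param sentinel value reported as the proximity score when either
#'   category is absent; a large finite constant rather than `Inf` so
#'   downstream feature matrices stay finite.
#' @return named numeric vector with elements `kinase_score`, `axis_score`,
#'   `relevancy_score`, `proximity_score`, `proximity10_count`,
#'   `proximity50_count`.
#' @export
eng_features <- function(annotations, n_tokens, sentinel = 10000) {
  if (!is.numeric(n_tokens) || length(n_tokens) != 1L || n_tokens <= 0)
    stop("n_tokens must be a positive scalar")
  kin <- annotations[annotations$category == "KINASE", , drop = FALSE]
  axi <- annotations[annotations$category == "AXIS", , drop = FALSE]
  ks <- nrow(kin) / n_tokens
  as_ <- nrow(axi) / n_tokens
  if (nrow(kin) == 0L || nrow(axi) == 0L) {
    return(c(kinase_score = ks, axis_score = as_, relevancy_score = ks * as_,
             proximity_score = sentinel, proximity10_count = 0,
             proximity50_count = 0))
  }
  # pairwise span distances, vectorized over the kinase x axis grid
  g <- expand.grid(i = seq_len(nrow(kin)), j = seq_len(nrow(axi)))
  d <- pmax(0L, pmax(axi$token_start[g$j] - kin$token_end[g$i],
                     kin$token_start[g$i] - axi$token_end[g$j]) - 1L)
  c(kinase_score = ks, axis_score = as_, relevancy_score = ks * as_,
    proximity_score = min(d),
    proximity10_count = sum(d <= 10L),
    proximity50_count = sum(d <= 50L))
}

#' Entity frequency and first-position features
#'
#' @param annotations annotation data frame for one document.
#' @param n_tokens total token count of the document.
#' @param sentinel first-position value reported when a category is absent.
#' @return named numeric vector `kinase_count`, `axis_count`,
#'   `kinase_first_position`, `axis_first_position`.
#' @export
extended_features <- function(annotations, n_tokens, sentinel = 10000) {
  if (!is.numeric(n_tokens) || length(n_tokens) != 1L || n_tokens <= 0)
    stop("n_tokens must be a positive scalar")
  first_pos <- function(cat) {
    s <- annotations$token_start[annotations$category == cat]
    if (length(s) == 0L) sentinel else min(s)
  }
  c(kinase_count = sum(annotations$category == "KINASE"),
    axis_count = sum(annotations$category == "AXIS"),
    kinase_first_position = first_pos("KINASE"),
    axis_first_position = first_pos("AXIS"))
}

.ngrams <- function(tokens, n_min, n_max) {
  n <- length(tokens)
  out <- character(0)
  for (k in n_min:n_max) {
    if (n < k) next
    m <- n - k + 1L
    g <- tokens[1:m]
    if (k > 1L) for (j in 2:k) g <- paste(g, tokens[j:(m + j - 1L)])
    out <- c(out, g)
  }
  out
}

#' Fit a bag-of-words n-gram vocabulary
#'
#' Collects all word n-grams (2- and 3-grams by default; unigrams can be
#' added) from a corpus of preprocessed token lists, keeps those appearing
#' in at least `min_df` documents, and stores document frequencies for the
#' IDF weights.
#'
#' @param token_lists list of character vectors (see [preprocess()]).
#' @param min_df minimum document frequency.
#' @param ngram_range integer vector `c(min, max)` of n-gram sizes.
#' @return object of class `bow_vocabulary`.
#' @export
fit_bow_vocabulary <- function(token_lists, min_df = 1L,
                               ngram_range = c(2L, 3L)) {
  if (length(token_lists) == 0L) stop("empty corpus")
  per_doc <- lapply(token_lists, function(t)
    unique(.ngrams(t, ngram_range[1], ngram_range[2])))
  df <- table(unlist(per_doc, use.names = FALSE))
  df <- df[df >= min_df]
  terms <- sort(names(df))
  structure(list(terms = terms,
                 df = as.integer(df[terms]),
                 n_docs = length(token_lists),
                 ngram_range = as.integer(ngram_range)),
            class = "bow_vocabulary")
}

#' @export
print.bow_vocabulary <- function(x, ...) {
  cat("bow_vocabulary:", length(x$terms), "n-grams (",
      paste(x$ngram_range, collapse = "-"), ") over", x$n_docs, "documents\n")
  invisible(x)
}

#' TFIDF vectors for documents
#'
#' Weight of term t in document d is `tf(t,d) * (ln((1+N)/(1+df(t))) + 1)`
#' (smoothed IDF), followed by L2 normalization per document; documents with
#' no in-vocabulary n-grams stay all-zero. Out-of-vocabulary n-grams are
#' ignored.
#'
#' @param token_lists list of preprocessed token vectors (or a single
#'   vector for [bow_vector()]).
#' @param vocabulary a fitted [fit_bow_vocabulary()] object.
#' @return [bow_matrix()]: a sparse `dgCMatrix` (documents x terms);
#'   [bow_vector()]: a named numeric vector of the nonzero weights.
#' @export
bow_matrix <- function(token_lists, vocabulary) {
  stopifnot(inherits(vocabulary, "bow_vocabulary"))
  nr <- lapply(token_lists, function(t)
    .ngrams(t, vocabulary$ngram_range[1], vocabulary$ngram_range[2]))
  idf <- log((1 + vocabulary$n_docs) / (1 + vocabulary$df)) + 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(nr)) {
    tf <- table(nr[[d]])
    j <- match(names(tf), vocabulary$terms)
    keep <- !is.na(j)
    if (!any(keep)) next
    w <- as.numeric(tf)[keep] * idf[j[keep]]
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    ii <- c(ii, rep.int(d, sum(keep))); jj <- c(jj, j[keep]); xx <- c(xx, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(nr), length(vocabulary$terms)),
                       dimnames = list(names(token_lists), vocabulary$terms))
}

#' @rdname bow_matrix
#' @export
bow_vector <- function(token_lists, vocabulary) {
  m <- bow_matrix(list(token_lists), vocabulary)
  v <- as.numeric(m[1, ])
  names(v) <- colnames(m)
  v[v != 0]
}

#' Feature matrix for (topic, document) candidate pairs
#'
#' Assembles the per-pair design matrix used by the ranker: ENG features
#' computed from the candidate document's annotations restricted to the
#' topic's kinase and the topic's axis, optionally extended
#' frequency/position features, optionally TFIDF bag-of-words columns.
#'
#' @param pairs data frame with columns `topic_id`, `doc_id`.
#' @param topics topic data frame (see [read_topics()]).
#' @param annotations collection-level annotation data frame where axis
#'   annotations carry an `axis` column (see [run_pipeline()] internals) or
#'   plain category annotations.
#' @param n_tokens named integer vector of document token counts.
#' @param feature_set one of `"ENG"`, `"EXTENDED"`, `"BOW"`,
#'   `"BOW_PLUS_ENG"`.
#' @param bow optional list with elements `vocabulary` and `tokens` (named
#'   list of preprocessed token vectors) when BOW columns are requested.
#' @param sentinel proximity sentinel passed to [eng_features()].
#' @return matrix (dense for ENG/EXTENDED, `dgCMatrix` when BOW columns are
#'   present) with one row per pair, rownames `topic_id\\rdoc_id`.
#' @export
pair_features <- function(pairs, topics, annotations, n_tokens,
                          feature_set = c("ENG", "EXTENDED", "BOW",
                                          "BOW_PLUS_ENG"),
                          bow = NULL, sentinel = 10000) {
  feature_set <- match.arg(feature_set)
  need_eng <- feature_set %in% c("ENG", "BOW_PLUS_ENG")
  need_ext <- feature_set == "EXTENDED"
  ann_by_doc <- split(seq_len(nrow(annotations)), annotations$doc_id)
  topic_row <- match(pairs$topic_id, topics$topic_id)
  eng <- NULL
  if (need_eng || need_ext) {
    rows <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      idx <- ann_by_doc[[pairs$doc_id[i]]]
      a <- annotations[idx, , drop = FALSE]
      tr <- topic_row[i]
      keep <- (a$category == "KINASE" & a$concept_id == topics$kinase_id[tr]) |
        (a$category == "AXIS" &
           (if ("axis" %in% names(a)) a$axis == topics$axis[tr] else TRUE))
      a <- a[keep, , drop = FALSE]
      nt <- n_tokens[[pairs$doc_id[i]]]
      rows[[i]] <- if (need_ext) extended_features(a, nt, sentinel)
                   else eng_features(a, nt, sentinel)
    }
    eng <- do.call(rbind, rows)
  }
  out <- eng
  if (feature_set %in% c("BOW", "BOW_PLUS_ENG")) {
    if (is.null(bow)) stop("BOW features requested but no bow vocabulary given")
    bm <- bow_matrix(bow$tokens[pairs$doc_id], bow$vocabulary)
    out <- if (is.null(out)) bm else cbind(Matrix::Matrix(out, sparse = TRUE), bm)
  }
  rownames(out) <- paste0(pairs$topic_id, "\r", pairs$doc_id)
  out
}
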