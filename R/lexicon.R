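# Dictionary construction, synonym expansion, longest-match annotation and
# the cross-reference validation filter.

.ROMAN <- c(I = "1", II = "2", III = "3", IV = "4", V = "5", VI = "6",
            VII = "7", VIII = "8", IX = "9", X = "10", XI = "11", XII = "12",
            XIII = "13", XIV = "14", XV = "15", XVI = "16", XVII = "17",
            XVIII = "18", XIX = "19", XX = "20")

.roman_to_arabic <- function(s) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  hit <- toupper(toks) %in% names(.ROMAN)
  toks[hit] <- .ROMAN[toupper(toks[hit])]
  paste(toks, collapse = " ")
}

#' Expand protein-name synonyms
#'
#' For each synonym, adds (i) a variant with each standalone Roman-numeral
#' token I--XX replaced by its Arabic value, (ii) a variant with internal
#' spaces removed, and (iii) their combination. Duplicates (up to
#' normalization) are removed; the original synonyms come first with variants
#' appended, and the operation is idempotent.
#'
#' @param synonyms non-empty character vector.
#' @return character vector, a superset of the input.
#' @examples
#' expand_synonyms("casein kinase II")
#' expand_synonyms("p145 c-kit")
#' @export
expand_synonyms <- function(synonyms) {
  if (length(synonyms) == 0L) stop("expand_synonyms: empty synonym list")
  synonyms <- as.character(synonyms)
  out <- character(0)
  for (s in synonyms) {
    rom <- .roman_to_arabic(s)
    variants <- c(s, rom, gsub(" ", "", s, fixed = TRUE),
                  gsub(" ", "", rom, fixed = TRUE))
    out <- c(out, variants)
  }
  keys <- vapply(out, function(v) paste(tokenize(v), collapse = " "), "")
  out[!duplicated(keys) & nzchar(keys)]
}

#' Construct lexicon entries
#'
#' @param concept_id character, concept identifiers (recycled).
#' @param surface character, surface forms.
#' @param category `"KINASE"` or `"AXIS"`.
#' @param source which dictionary the entry came from.
#' @return data frame with columns `concept_id`, `surface`, `category`,
#'   `source`.
#' @export
lexicon <- function(concept_id, surface, category = c("KINASE", "AXIS"),
                    source = "user") {
  category <- match.arg(category)
  df <- data.frame(concept_id = as.character(concept_id),
                   surface = as.character(surface),
                   category = category,
                   source = rep_len(as.character(source), length(surface)),
                   stringsAsFactors = FALSE)
  df[!duplicated(df[c("concept_id", "surface")]), , drop = FALSE]
}

#' Read a dictionary file
#'
#' TSV with two columns (`concept_id`, `surface`) or three (plus an axis
#' label per entry for axis dictionaries mixing the two vocabularies).
#' Synonym expansion ([expand_synonyms()]) is applied per concept when
#' `expand = TRUE`, the convention for kinase dictionaries.
#'
#' @param path TSV file.
#' @param category `"KINASE"` or `"AXIS"`.
#' @param expand apply synonym expansion per concept.
#' @return lexicon data frame; for 3-column axis files an `axis` column is
#'   retained.
#' @export
read_dictionary <- function(path, category = c("KINASE", "AXIS"),
                            expand = (match.arg(category) == "KINASE")) {
  category <- match.arg(category)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("dictionary format error at line ", bad[1], ": expected >= 2 fields")
  df <- data.frame(concept_id = vapply(parts, `[[`, "", 1L),
                   surface = vapply(parts, `[[`, "", 2L),
                   category = category, source = basename(path),
                   stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 3L))
    df$axis <- .parse_axis(vapply(parts, `[[`, "", 3L))
  if (expand) {
    pieces <- lapply(split(seq_len(nrow(df)), df$concept_id), function(i) {
      sub <- df[i, , drop = FALSE]
      ex <- expand_synonyms(sub$surface)
      out <- sub[rep(1L, length(ex)), , drop = FALSE]
      out$surface <- ex
      out
    })
    df <- do.call(rbind, pieces)
    rownames(df) <- NULL
  }
  df[!duplicated(df[c("concept_id", "surface")]), , drop = FALSE]
}

#' Build a token-sequence matcher
#'
#' Normalizes and tokenizes every surface form and indexes the resulting
#' token sequences for case-insensitive longest-match lookup. Entries whose
#' surface normalizes to nothing are skipped and counted.
#'
#' @param entries lexicon data frame ([lexicon()] / [read_dictionary()]).
#' @return an object of class `matcher`.
#' @export
build_matcher <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0L)
  tokseqs <- lapply(entries$surface, tokenize)
  len <- lengths(tokseqs)
  skipped <- sum(len == 0L)
  if (skipped > 0L)
    warning(skipped, " dictionary entries with empty normalized surface skipped")
  keep <- len > 0L
  keys <- vapply(tokseqs[keep], paste, "", collapse = " ")
  idx <- !duplicated(keys)  # first entry wins for identical normalized surfaces
  tab <- new.env(parent = emptyenv(), size = sum(idx) * 2L)
  ids <- entries$concept_id[keep][idx]
  kk <- keys[idx]
  for (i in seq_along(kk)) assign(kk[i], ids[i], envir = tab)
  structure(list(table = tab,
                 first_tokens = unique(vapply(strsplit(kk, " ", fixed = TRUE),
                                              `[[`, "", 1L)),
                 max_len = max(len[keep]),
                 category = entries$category[1],
                 n_entries = sum(idx),
                 n_skipped = skipped),
            class = "matcher")
}

#' @export
print.matcher <- function(x, ...) {
  cat("matcher:", x$n_entries, x$category, "surfaces, max length",
      x$max_len, "tokens\n")
  invisible(x)
}

# longest-match, non-overlapping, left-to-right greedy scan over a token
# vector; returns a data.frame of spans (0-based, end-exclusive)
.match_tokens <- function(tokens, matcher) {
  n <- length(tokens)
  starts <- integer(0); ends <- integer(0); ids <- character(0)
  if (n == 0L) {
    return(data.frame(token_start = starts, token_end = ends,
                      concept_id = ids, stringsAsFactors = FALSE))
  }
  cand <- which(tokens %in% matcher$first_tokens)
  tab <- matcher$table
  covered_until <- 0L  # 1-based index of last consumed token
  for (i in cand) {
    if (i <= covered_until) next
    maxL <- min(matcher$max_len, n - i + 1L)
    for (L in maxL:1L) {
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      id <- tab[[key]]
      if (!is.null(id)) {
        starts <- c(starts, i - 1L); ends <- c(ends, i + L - 1L)
        ids <- c(ids, id)
        covered_until <- i + L - 1L
        break
      }
    }
  }
  data.frame(token_start = starts, token_end = ends, concept_id = ids,
             stringsAsFactors = FALSE)
}

#' Annotate a document with kinase and axis dictionaries
#'
#' Scans the document's title, abstract and body as one token sequence and
#' emits all longest, non-overlapping matches per matcher. Kinase and axis
#' annotations come from independent matchers and may overlap each other.
#'
#' @param doc a one-row document data frame, or a pre-tokenized character
#'   vector (then `doc_id` must be given).
#' @param kinase_matcher,axis_matcher matchers from [build_matcher()]; either
#'   may be `NULL` to skip that category.
#' @param doc_id identifier used when `doc` is a token vector.
#' @return annotation data frame with columns `doc_id`, `token_start`
#'   (0-based inclusive), `token_end` (0-based exclusive), `surface`,
#'   `concept_id`, `category`.
#' @export
annotate <- function(doc, kinase_matcher = NULL, axis_matcher = NULL,
                     doc_id = NULL) {
  if (is.data.frame(doc)) {
    stopifnot(nrow(doc) == 1L)
    tokens <- tokenize(c(doc$title, doc$abstract, doc$body))
    doc_id <- doc$doc_id
  } else {
    tokens <- as.character(doc)
    if (is.null(doc_id)) stop("doc_id required for token-vector input")
  }
  one <- function(m, category) {
    if (is.null(m)) return(NULL)
    sp <- .match_tokens(tokens, m)
    if (nrow(sp) == 0L) return(NULL)
    data.frame(doc_id = doc_id, token_start = sp$token_start,
               token_end = sp$token_end,
               surface = vapply(seq_len(nrow(sp)), function(i)
                 paste(tokens[(sp$token_start[i] + 1L):sp$token_end[i]],
                       collapse = " "), ""),
               concept_id = sp$concept_id, category = category,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(kinase_matcher, "KINASE"), one(axis_matcher, "AXIS"))
  if (is.null(out))
    out <- data.frame(doc_id = character(0), token_start = integer(0),
                      token_end = integer(0), surface = character(0),
                      concept_id = character(0), category = character(0),
                      stringsAsFactors = FALSE)
  out
}

#' Annotate a whole collection
#'
#' @param docs document data frame.
#' @param kinase_matcher,axis_matcher matchers from [build_matcher()].
#' @param tokens optional pre-computed token list from
#'   [tokenize_documents()]; supplied once and shared with feature
#'   extraction so spans refer to the same positions.
#' @return list with `annotations` (one annotation data frame for the whole
#'   collection) and `n_tokens` (named integer vector of document lengths).
#' @export
annotate_collection <- function(docs, kinase_matcher = NULL,
                                axis_matcher = NULL, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize_documents(docs)
  res <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    res[[i]] <- annotate(tokens[[i]], kinase_matcher, axis_matcher,
                         doc_id = names(tokens)[i])
  }
  ann <- do.call(rbind, res)
  rownames(ann) <- NULL
  list(annotations = ann,
       n_tokens = stats::setNames(lengths(tokens), names(tokens)))
}

#' Cross-reference validation
#'
#' A document survives the filter only if it mentions both sides of the
#' query: at least one kinase annotation and at least one axis-term
#' annotation.
#'
#' @param annotations annotation data frame for one document.
#' @return `TRUE` iff both a KINASE and an AXIS annotation are present.
#' @export
cross_reference_validate <- function(annotations) {
  nrow(annotations) > 0L &&
    any(annotations$category == "KINASE") &&
    any(annotations$category == "AXIS")
}
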