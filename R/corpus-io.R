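#' Construct a document collection
#'
#' A collection is a plain data frame with one row per citation or full text.
#' Publication types are stored pipe-joined in a single character column.
#'
#' @param doc_id character, unique non-empty identifiers (PMID-like).
#' @param title,abstract,body character vectors (may be empty strings; `body`
#'   is empty for abstract-only collections).
#' @param journal character.
#' @param year integer calendar year, `NA` when unknown; must exceed 1800
#'   when present.
#' @param pub_types character, publication types pipe-joined.
#' @return data frame with the columns above.
#' @export
document_set <- function(doc_id, title = "", abstract = "", body = "",
                         journal = "", year = NA_integer_, pub_types = "") {
  doc_id <- as.character(doc_id)
  n <- length(doc_id)
  if (any(!nzchar(doc_id))) stop("doc_id must be non-empty")
  if (anyDuplicated(doc_id))
    stop("duplicate doc_id in collection: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "))
  year <- as.integer(year)
  if (any(!is.na(year) & year <= 1800L)) stop("year must be > 1800 when present")
  docs <- data.frame(
    doc_id = doc_id,
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n),
    body = rep_len(as.character(body), n),
    journal = rep_len(as.character(journal), n),
    year = rep_len(year, n),
    pub_types = rep_len(as.character(pub_types), n),
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(docs$abstract) & !nzchar(docs$title)
  if (any(bad))
    stop("documents with empty abstract must have a title: ",
         paste(docs$doc_id[bad], collapse = ", "))
  docs
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a collection as BioC XML
#'
#' Emits collection/document/passage BioC structure: a `title` passage, an
#' `abstract` passage (when non-empty) and a `fulltext` passage (when a body
#' is present); journal, year and publication types are document infons.
#'
#' @param docs document data frame ([document_set()]).
#' @param path output file.
#' @param source collection-level source string.
#' @return `path`, invisibly.
#' @export
write_bioc_collection <- function(docs, path, source = "kintriage") {
  esc <- function(col) .xml_escape(ifelse(is.na(col), "", as.character(col)))
  title_p <- sprintf(
    "    <passage><infon key=\"type\">title</infon><offset>0</offset><text>%s</text></passage>",
    esc(docs$title))
  abs_p <- ifelse(nzchar(esc(docs$abstract)), sprintf(
    "\n    <passage><infon key=\"type\">abstract</infon><offset>0</offset><text>%s</text></passage>",
    esc(docs$abstract)), "")
  body_p <- ifelse(nzchar(esc(docs$body)), sprintf(
    "\n    <passage><infon key=\"type\">fulltext</infon><offset>0</offset><text>%s</text></passage>",
    esc(docs$body)), "")
  infons <- sprintf(paste0(
    "    <infon key=\"journal\">%s</infon>\n",
    "    <infon key=\"year\">%s</infon>\n",
    "    <infon key=\"pub_types\">%s</infon>"),
    esc(docs$journal), esc(docs$year), esc(docs$pub_types))
  doc_xml <- sprintf("  <document>\n    <id>%s</id>\n%s\n%s%s%s\n  </document>",
                     esc(docs$doc_id), infons, title_p, abs_p, body_p)
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           "<collection>",
           sprintf("  <source>%s</source>", .xml_escape(source)),
           doc_xml,
           "</collection>")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a BioC XML collection
#'
#' Maps each BioC `<document>` to one row of a document data frame. Title and
#' abstract passages are recognised by their `type` infon; any other passage
#' types (e.g. `fulltext`, `paragraph`) are concatenated into the body.
#' Metadata infon keys are configurable because BioC producers differ.
#'
#' @param path BioC XML file.
#' @param journal_key,year_key,pubtype_key names of the document infons
#'   carrying journal, year and publication types.
#' @return document data frame.
#' @export
read_bioc_collection <- function(path, journal_key = "journal",
                                 year_key = "year", pubtype_key = "pub_types") {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) stop("malformed BioC XML in '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  doc_nodes <- xml2::xml_find_all(x, "//document")
  n <- length(doc_nodes)
  # xml_find_first over a nodeset evaluates per node in C and yields NA for
  # missing fields, so the whole collection is read without an R-level loop
  field <- function(xp) {
    v <- xml2::xml_text(xml2::xml_find_first(doc_nodes, xp))
    ifelse(is.na(v), "", v)
  }
  ids <- field("./id")
  titles <- field("./passage[infon[@key='type']='title']/text")
  abstracts <- field("./passage[infon[@key='type']='abstract']/text")
  journals <- field(sprintf("./infon[@key='%s']", journal_key))
  years <- field(sprintf("./infon[@key='%s']", year_key))
  pts <- field(sprintf("./infon[@key='%s']", pubtype_key))
  bodies <- character(n)
  body_xp <- "//document/passage[infon[@key='type']!='title' and infon[@key='type']!='abstract']/text"
  bnodes <- xml2::xml_find_all(x, body_xp)
  if (length(bnodes)) {
    owner <- xml2::xml_text(xml2::xml_find_first(
      xml2::xml_parent(xml2::xml_parent(bnodes)), "./id"))
    btxt <- vapply(split(xml2::xml_text(bnodes), owner), paste, "",
                   collapse = " ")
    hit <- match(names(btxt), ids)
    bodies[hit[!is.na(hit)]] <- btxt[!is.na(hit)]
  }
  if (anyDuplicated(ids))
    stop("collection-integrity error: duplicate doc_id ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  year <- suppressWarnings(as.integer(years))
  document_set(doc_id = ids, title = titles, abstract = abstracts,
               body = bodies, journal = journals, year = year, pub_types = pts)
}

#' Read a simplified full-text XML file
#'
#' Accepts a JATS-like article: the article title, the abstract, and all
#' `<p>` paragraph elements in document order concatenated into the body.
#'
#' @param path XML file containing one `<article>`.
#' @param doc_id identifier to assign; defaults to the article `id`
#'   attribute or element when present.
#' @return one-row document data frame with a populated `body`.
#' @export
read_fulltext_xml <- function(path, doc_id = NULL) {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) stop("malformed full-text XML in '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  first_text <- function(xp) {
    v <- xml2::xml_find_first(x, xp)
    if (inherits(v, "xml_missing")) "" else xml2::xml_text(v)
  }
  if (is.null(doc_id)) {
    doc_id <- xml2::xml_attr(xml2::xml_root(x), "id")
    if (is.na(doc_id)) doc_id <- first_text("//article-id")
  }
  if (is.null(doc_id) || !nzchar(doc_id))
    stop("full-text article has no identifier; supply doc_id")
  title <- first_text("//article-title | //title")
  abstract <- first_text("//abstract")
  paras <- xml2::xml_text(xml2::xml_find_all(x, "//p"))
  year <- suppressWarnings(as.integer(first_text("//year")))
  document_set(doc_id = doc_id, title = title, abstract = abstract,
               body = paste(paras, collapse = " "),
               journal = first_text("//journal-title"), year = year)
}

#' Filter a collection by publication year
#'
#' Keeps documents published strictly before `cutoff_year`, preserving input
#' order. Documents with unknown year cannot be certified pre-cutoff and are
#' dropped; their count is attached as the `"dropped_missing_year"` attribute.
#'
#' @param docs document data frame.
#' @param cutoff_year integer > 1800; e.g. 2014 keeps papers published 2013
#'   and earlier.
#' @return filtered document data frame with attribute
#'   `dropped_missing_year`.
#' @export
filter_by_year <- function(docs, cutoff_year) {
  stopifnot(is.numeric(cutoff_year), length(cutoff_year) == 1L, cutoff_year > 1800)
  keep <- !is.na(docs$year) & docs$year < cutoff_year
  out <- docs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_missing_year") <- sum(is.na(docs$year))
  out
}

.AXIS_LEVELS <- c("DISEASE", "BIOPROC")

.parse_axis <- function(x) {
  key <- toupper(trimws(x))
  key[key %in% c("BIOLOGICAL_PROCESS", "BIOLOGICAL PROCESS", "GO_BP", "GOBP",
                 "BP", "BIOPROC")] <- "BIOPROC"
  key[key == "DISEASE"] <- "DISEASE"
  key
}

#' Read a topic file
#'
#' Tab-separated, one topic per line: topic id, kinase id, axis, pipe-joined
#' synonym list. The axis is matched case-insensitively
#' (`disease` -> `DISEASE`; `bioproc`/`biological_process` -> `BIOPROC`).
#'
#' @param path TSV file.
#' @return data frame with columns `topic_id`, `kinase_id`, `axis` and a
#'   list-column `synonyms`.
#' @export
read_topics <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty topic file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad))
    stop("topic format error at line ", bad[1], ": expected 4 tab-separated fields")
  topic_id <- vapply(parts, `[[`, "", 1L)
  kinase_id <- vapply(parts, `[[`, "", 2L)
  axis <- .parse_axis(vapply(parts, `[[`, "", 3L))
  unknown <- which(!(axis %in% .AXIS_LEVELS))
  if (length(unknown))
    stop("topic format error at line ", unknown[1], ": unknown axis '",
         vapply(parts, `[[`, "", 3L)[unknown[1]], "'")
  synonyms <- strsplit(vapply(parts, `[[`, "", 4L), "|", fixed = TRUE)
  synonyms <- lapply(synonyms, function(s) trimws(s[nzchar(trimws(s))]))
  empty <- which(lengths(synonyms) == 0L)
  if (length(empty))
    stop("topic format error at line ", empty[1], ": empty synonym list")
  out <- data.frame(topic_id = topic_id, kinase_id = kinase_id, axis = axis,
                    stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  out
}

#' Write a topic file
#'
#' @param topics topic data frame as returned by [read_topics()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_topics <- function(topics, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s", topics$topic_id, topics$kinase_id,
                     topics$axis,
                     vapply(topics$synonyms, paste, "", collapse = "|")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Relevance judgments (qrels)
#'
#' Constructs a qrels object from parallel vectors of topic and document
#' identifiers. Relevance is binarized (any value >= 1 is relevant). The
#' track's gold standard stores positives only; negatives may be supplied
#' explicitly for testing but pairs absent from the qrels are simply
#' non-relevant.
#'
#' @param topic_id,doc_id character vectors.
#' @param relevance integer vector, binarized to \{0, 1\}.
#' @return an object of class `qrels`.
#' @export
qrels <- function(topic_id, doc_id, relevance = 1L) {
  topic_id <- as.character(topic_id); doc_id <- as.character(doc_id)
  relevance <- as.integer(relevance)
  if (anyNA(relevance)) stop("qrels format error: non-integer relevance")
  relevance <- as.integer(relevance >= 1L)
  df <- data.frame(topic_id = topic_id, doc_id = rep_len(doc_id, length(topic_id)),
                   relevance = rep_len(relevance, length(topic_id)),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("topic_id", "doc_id")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(judgments = df), class = "qrels")
}

#' @export
print.qrels <- function(x, ...) {
  pos <- x$judgments[x$judgments$relevance == 1L, , drop = FALSE]
  cat("qrels:", nrow(pos), "positive judgments over",
      length(unique(pos$topic_id)), "topics\n")
  invisible(x)
}

#' Look up relevance of (topic, document) pairs
#'
#' @param qr a `qrels` object.
#' @param topic_id,doc_id character vectors (recycled to common length).
#' @return integer vector of 0/1 relevances; unlisted pairs are 0.
#' @export
qrels_relevance <- function(qr, topic_id, doc_id) {
  stopifnot(inherits(qr, "qrels"))
  key <- paste0(topic_id, "\r", doc_id)
  jk <- paste0(qr$judgments$topic_id, "\r", qr$judgments$doc_id)
  i <- match(key, jk)
  out <- qr$judgments$relevance[i]
  out[is.na(out)] <- 0L
  out
}

#' Positive documents per topic
#'
#' @param qr a `qrels` object.
#' @return named list mapping topic id to the character vector of relevant
#'   doc ids.
#' @export
qrels_positives <- function(qr) {
  stopifnot(inherits(qr, "qrels"))
  pos <- qr$judgments[qr$judgments$relevance == 1L, , drop = FALSE]
  split(pos$doc_id, pos$topic_id)
}

#' Read / write TREC qrels files
#'
#' Whitespace-separated lines `topic_id 0 doc_id relevance`. Relevance is
#' binarized on reading; writing then reading reproduces the same judgments.
#'
#' @param path qrels file.
#' @return [read_qrels()] returns a `qrels` object.
#' @export
read_qrels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(qrels(character(0), character(0), integer(0)))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("qrels format error at line ", bad[1], ": expected 4 fields")
  rel <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L)))
  if (anyNA(rel))
    stop("qrels format error: non-integer relevance at line ", which(is.na(rel))[1])
  qrels(topic_id = vapply(parts, `[[`, "", 1L),
        doc_id = vapply(parts, `[[`, "", 3L), relevance = rel)
}

#' @rdname read_qrels
#' @param qr a `qrels` object.
#' @export
write_qrels <- function(qr, path) {
  stopifnot(inherits(qr, "qrels"))
  j <- qr$judgments
  writeLines(sprintf("%s 0 %s %d", j$topic_id, j$doc_id, j$relevance), path,
             useBytes = TRUE)
  invisible(path)
}

#' Canonicalize a run
#'
#' Sorts entries per topic by score descending with ties broken by doc id
#' descending (the trec_eval convention, so metric values match the
#' reference evaluator) and re-assigns ranks 1..n per topic. Idempotent.
#'
#' @param run data frame with columns `topic_id`, `doc_id`, `score` and
#'   optionally `tag`.
#' @return canonical run data frame with columns `topic_id`, `doc_id`,
#'   `rank`, `score`, `tag`.
#' @export
canonicalize_run <- function(run) {
  stopifnot(all(c("topic_id", "doc_id", "score") %in% names(run)))
  if (nrow(run) == 0L)
    return(data.frame(topic_id = character(0), doc_id = character(0),
                      rank = integer(0), score = numeric(0),
                      tag = character(0), stringsAsFactors = FALSE))
  if (anyDuplicated(run[c("topic_id", "doc_id")])) {
    d <- run[duplicated(run[c("topic_id", "doc_id")]), c("topic_id", "doc_id")]
    stop("duplicate run entry for (", d$topic_id[1], ", ", d$doc_id[1], ")")
  }
  tag <- if ("tag" %in% names(run)) as.character(run$tag) else "kintriage"
  o <- order(as.character(run$topic_id), as.numeric(run$score),
             as.character(run$doc_id),
             decreasing = c(FALSE, TRUE, TRUE), method = "radix")
  out <- data.frame(topic_id = as.character(run$topic_id)[o],
                    doc_id = as.character(run$doc_id)[o],
                    rank = NA_integer_,
                    score = as.numeric(run$score)[o],
                    tag = rep_len(tag, nrow(run))[o],
                    stringsAsFactors = FALSE)
  out$rank <- stats::ave(seq_len(nrow(out)), out$topic_id,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Read / write TREC run files
#'
#' Run lines are `topic_id Q0 doc_id rank score tag`. Entries are
#' canonicalized before writing (see [canonicalize_run()]); a write/read
#' round trip on canonical input is the identity.
#'
#' @param path run file.
#' @return [read_run()] returns a run data frame.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(topic_id = character(0), doc_id = character(0),
                      rank = integer(0), score = numeric(0), tag = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    stop("run format error at line ", bad[1], ": expected 6 fields")
  run <- data.frame(topic_id = vapply(parts, `[[`, "", 1L),
                    doc_id = vapply(parts, `[[`, "", 3L),
                    rank = as.integer(vapply(parts, `[[`, "", 4L)),
                    score = as.numeric(vapply(parts, `[[`, "", 5L)),
                    tag = vapply(parts, `[[`, "", 6L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(run[c("topic_id", "doc_id")]))
    stop("duplicate run entry in ", path)
  run
}

#' @rdname read_run
#' @param run run data frame (will be canonicalized).
#' @export
write_run <- function(run, path) {
  run <- canonicalize_run(run)
  writeLines(sprintf("%s Q0 %s %d %.10g %s", run$topic_id, run$doc_id,
                     run$rank, run$score, run$tag), path, useBytes = TRUE)
  invisible(path)
}
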