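#' Normalize a token
#'
#' Case-folds a token and strips leading and trailing punctuation while
#' keeping internal punctuation (hyphens, digits), so protein surface forms
#' such as `"c-Kit"` or `"p145"` survive normalization intact.
#'
#' @param x character vector of raw tokens.
#' @return character vector of normalized tokens (possibly empty strings).
#' @examples
#' normalize_token(c("CD117,", "c-Kit", "(p145)"))
#' @export
normalize_token <- function(x) {
  x <- tolower(enc2utf8(as.character(x)))
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
}

#' Tokenize text for annotation
#'
#' Splits on whitespace, normalizes each token with [normalize_token()] and
#' drops tokens that normalize to the empty string. Token positions returned
#' by the annotator refer to this token sequence.
#'
#' @param text character vector; elements are concatenated in order (title,
#'   abstract, body) before tokenization so a document is scanned as one
#'   token sequence.
#' @return character vector of normalized tokens.
#' @export
tokenize <- function(text) {
  text <- paste(text[!is.na(text)], collapse = " ")
  if (!nzchar(trimws(text))) return(character(0))
  toks <- normalize_token(strsplit(trimws(text), "[[:space:]]+")[[1]])
  toks[nzchar(toks)]
}

#' Tokenize every document in a collection
#'
#' @param docs a document data frame (see [document_set()]).
#' @return named list of token vectors, one per `doc_id`.
#' @export
tokenize_documents <- function(docs) {
  stopifnot(is.data.frame(docs))
  txt <- paste(ifelse(is.na(docs$title), "", docs$title),
               ifelse(is.na(docs$abstract), "", docs$abstract),
               ifelse(is.na(docs$body), "", docs$body))
  raw <- strsplit(trimws(txt), "[[:space:]]+")
  out <- lapply(raw, function(t) {
    if (length(t) == 1L && !nzchar(t)) return(character(0))
    t <- normalize_token(t)
    t[nzchar(t)]
  })
  names(out) <- docs$doc_id
  out
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that results
# are pure functions of their explicit seed arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
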