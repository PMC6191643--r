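# Porter stemming and stop-word removal used by the bag-of-words features.
# The stemmer is the original Porter (1980) algorithm (with the author's
# later bli->ble / logi->log departures); the stop-word list is the Snowball
# English list, inlined so results never depend on an external resource.

# consonant/vowel classification: y is a vowel when preceded by a consonant
.porter_cons <- function(ch) {
  n <- length(ch)
  cons <- !(ch %in% c("a", "e", "i", "o", "u"))
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (ch[i] == "y") cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    }
  }
  cons
}

# measure m of a stem: [C](VC)^m[V]
.porter_m <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return(0L)
  runs <- rle(.porter_cons(ch))$values
  sum(runs[-1] & !runs[-length(runs)])
}

.porter_has_vowel <- function(stem) {
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  length(ch) > 0L && any(!.porter_cons(ch))
}

.porter_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1L] && .porter_cons(ch)[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  cons <- .porter_cons(ch)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(ch[n] %in% c("w", "x", "y"))
}

.ends <- function(w, suf) {
  nchar(w) > nchar(suf) && substring(w, nchar(w) - nchar(suf) + 1L) == suf
}
.chop <- function(w, suf) substring(w, 1L, nchar(w) - nchar(suf))

# ordered (longest-first) suffix maps; longest matching suffix is tried and,
# pass or fail on the m-condition, no shorter suffix is considered (Porter's
# rule-selection convention)
.porter_step2 <- c(
  ization = "ize", iveness = "ive", fulness = "ful", ousness = "ous",
  ational = "ate", tional = "tion", biliti = "ble", aliti = "al",
  iviti = "ive", ation = "ate", alism = "al", ousli = "ous", entli = "ent",
  anci = "ance", enci = "ence", izer = "ize", alli = "al", ator = "ate",
  logi = "log", bli = "ble", eli = "e"
)
.porter_step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
                   ical = "ic", ness = "", ful = "")
.porter_step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                   "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
                   "al", "er", "ic", "ou")

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.ends(w, "sses")) w <- paste0(.chop(w, "sses"), "ss")
  else if (.ends(w, "ies")) w <- paste0(.chop(w, "ies"), "i")
  else if (!.ends(w, "ss") && .ends(w, "s")) w <- .chop(w, "s")

  # step 1b
  fired <- FALSE
  if (.ends(w, "eed")) {
    if (.porter_m(.chop(w, "eed")) > 0L) w <- .chop(w, "d")
  } else if (.ends(w, "ed") && .porter_has_vowel(.chop(w, "ed"))) {
    w <- .chop(w, "ed"); fired <- TRUE
  } else if (.ends(w, "ing") && .porter_has_vowel(.chop(w, "ing"))) {
    w <- .chop(w, "ing"); fired <- TRUE
  }
  if (fired) {
    if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) w <- paste0(w, "e")
    else if (.porter_double_cons(w) &&
             !(substring(w, nchar(w)) %in% c("l", "s", "z")))
      w <- substring(w, 1L, nchar(w) - 1L)
    else if (.porter_m(w) == 1L && .porter_cvc(w)) w <- paste0(w, "e")
  }

  # step 1c
  if (.ends(w, "y") && .porter_has_vowel(.chop(w, "y")))
    w <- paste0(.chop(w, "y"), "i")

  # step 2
  for (suf in names(.porter_step2)) {
    if (.ends(w, suf)) {
      stem <- .chop(w, suf)
      if (.porter_m(stem) > 0L) w <- paste0(stem, .porter_step2[[suf]])
      break
    }
  }

  # step 3
  for (suf in names(.porter_step3)) {
    if (.ends(w, suf)) {
      stem <- .chop(w, suf)
      if (.porter_m(stem) > 0L) w <- paste0(stem, .porter_step3[[suf]])
      break
    }
  }

  # step 4
  for (suf in .porter_step4) {
    if (.ends(w, suf)) {
      stem <- .chop(w, suf)
      ok <- .porter_m(stem) > 1L
      if (suf == "ion") ok <- ok && substring(stem, nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.ends(w, "e")) {
    stem <- .chop(w, "e")
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }

  # step 5b
  if (.porter_m(w) > 1L && .porter_double_cons(w) &&
      .ends(w, "l")) w <- substring(w, 1L, nchar(w) - 1L)
  w
}

#' Porter-stem a vector of words
#'
#' @param words character vector of lower-case words.
#' @return character vector of stems.
#' @examples
#' porter_stem(c("kinases", "phosphorylate", "substrates"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  u <- unique(words)
  stems <- vapply(u, .porter_one, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}

#' English stop words
#'
#' The Snowball English stop-word list shipped with the package, so stop-word
#' removal is reproducible and independent of any external resource.
#'
#' @return character vector of stop words.
#' @export
stopwords_en <- function() .stopwords_en

.stopwords_en <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you", "your",
  "yours", "yourself", "yourselves", "he", "him", "his", "himself", "she",
  "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
  "theirs", "themselves", "what", "which", "who", "whom", "this", "that",
  "these", "those", "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "would",
  "should", "could", "ought", "a", "an", "the", "and", "but", "if", "or",
  "because", "as", "until", "while", "of", "at", "by", "for", "with",
  "about", "against", "between", "into", "through", "during", "before",
  "after", "above", "below", "to", "from", "up", "down", "in", "out", "on",
  "off", "over", "under", "again", "further", "then", "once", "here",
  "there", "when", "where", "why", "how", "all", "any", "both", "each",
  "few", "more", "most", "other", "some", "such", "no", "nor", "not",
  "only", "own", "same", "so", "than", "too", "very", "can", "will",
  "just", "don", "now"
)

#' Preprocess text for bag-of-words features
#'
#' Tokenizes (same tokenizer as the annotator), removes stop words and
#' applies Porter stemming. Deterministic for fixed input.
#'
#' @param text character vector (concatenated before tokenization).
#' @return character vector of stemmed tokens.
#' @examples
#' preprocess("Kinases phosphorylate the substrates")
#' @export
preprocess <- function(text) {
  toks <- tokenize(text)
  toks <- toks[!(toks %in% .stopwords_en)]
  porter_stem(toks)
}
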