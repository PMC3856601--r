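# Annotation-text normalization: lowercasing, splitting, English stopword
# removal and Porter (1980) suffix stripping. The stemmer is implemented
# here in full; tokens containing digits ("60s", "l7") pass through
# unstemmed, since the consonant/vowel rules are defined only for letters.

cw_stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "did", "do",
  "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "herself", "him", "himself", "his", "how", "i", "if", "in", "into", "is",
  "it", "its", "itself", "just", "me", "more", "most", "my", "myself",
  "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
  "other", "our", "ours", "ourselves", "out", "over", "own", "same", "she",
  "should", "so", "some", "such", "than", "that", "the", "their", "theirs",
  "them", "themselves", "then", "there", "these", "they", "this", "those",
  "through", "to", "too", "under", "until", "up", "very", "was", "we",
  "were", "what", "when", "where", "which", "while", "who", "whom", "why",
  "will", "with", "you", "your", "yours", "yourself", "yourselves"
)

# --- Porter stemmer -------------------------------------------------------

p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!p_is_cons(chars, i - 1L))
  }
  TRUE
}

p_shape <- function(word) {
  chars <- strsplit(word, "")[[1]]
  vapply(seq_along(chars), function(i) p_is_cons(chars, i), logical(1))
}

# m in the [C](VC)^m[V] decomposition
p_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- p_shape(word)
  runs <- rle(cons)$values
  sum(!runs[-length(runs)] & runs[-1])
}

p_has_vowel <- function(word) nzchar(word) && any(!p_shape(word))

p_double_cons <- function(word) {
  k <- nchar(word)
  k >= 2L &&
    substr(word, k, k) == substr(word, k - 1L, k - 1L) &&
    p_shape(word)[k]
}

# ...cvc where the final c is not w, x or y
p_cvc <- function(word) {
  k <- nchar(word)
  if (k < 3L) return(FALSE)
  cons <- p_shape(word)
  cons[k - 2L] && !cons[k - 1L] && cons[k] &&
    !substr(word, k, k) %in% c("w", "x", "y")
}

p_chop <- function(word, n) substr(word, 1L, nchar(word) - n)

# Apply the longest matching rule of a (suffix -> replacement) table,
# guarded by a measure condition on the remaining stem.
p_rule_set <- function(word, rules, min_m) {
  sfx <- names(rules)
  match <- sfx[endsWith(word, sfx)]
  if (length(match) == 0L) return(word)
  s <- match[which.max(nchar(match))]
  stem <- p_chop(word, nchar(s))
  if (p_measure(stem) > min_m) paste0(stem, rules[[s]]) else word
}

porter_stem <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- word

  # step 1a
  if (endsWith(w, "sses")) w <- p_chop(w, 2L)
  else if (endsWith(w, "ies")) w <- paste0(p_chop(w, 3L), "i")
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- p_chop(w, 1L)

  # step 1b
  fired <- FALSE
  if (endsWith(w, "eed")) {
    if (p_measure(p_chop(w, 3L)) > 0L) w <- p_chop(w, 1L)
  } else if (endsWith(w, "ed") && p_has_vowel(p_chop(w, 2L))) {
    w <- p_chop(w, 2L); fired <- TRUE
  } else if (endsWith(w, "ing") && p_has_vowel(p_chop(w, 3L))) {
    w <- p_chop(w, 3L); fired <- TRUE
  }
  if (fired) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (p_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- p_chop(w, 1L)
    } else if (p_measure(w) == 1L && p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (endsWith(w, "y") && p_has_vowel(p_chop(w, 1L))) {
    w <- paste0(p_chop(w, 1L), "i")
  }

  # step 2
  w <- p_rule_set(w, c(
    ization = "ize", iveness = "ive", fulness = "ful", ousness = "ous",
    ational = "ate", biliti = "ble", tional = "tion", ousli = "ous",
    entli = "ent", aliti = "al", iviti = "ive", ation = "ate",
    alism = "al", enci = "ence", anci = "ance", izer = "ize",
    abli = "able", alli = "al", ator = "ate", eli = "e"
  ), 0L)

  # step 3
  w <- p_rule_set(w, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), 0L)

  # step 4
  sfx4 <- c(
    "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion",
    "ism", "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
  )
  match <- sfx4[endsWith(w, sfx4)]
  if (length(match) > 0L) {
    s <- match[which.max(nchar(match))]
    stem <- p_chop(w, nchar(s))
    ok <- p_measure(stem) > 1L &&
      (s != "ion" || substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
    if (ok) w <- stem
  }

  # step 5a
  if (endsWith(w, "e")) {
    stem <- p_chop(w, 1L)
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_cvc(stem))) w <- stem
  }
  # step 5b
  if (p_measure(w) > 1L && p_double_cons(w) && endsWith(w, "l")) {
    w <- p_chop(w, 1L)
  }
  w
}

#' Normalize free text into search tokens
#'
#' Lowercases, splits on non-alphanumeric characters, drops a fixed English
#' stopword list, and Porter-stems purely alphabetic tokens. Token order is
#' preserved. This is the single normalization applied both when indexing
#' annotation descriptions and when parsing query terms, so the two always
#' agree.
#'
#' @param text Character vector of free text.
#' @return Character vector of normalized tokens (empty for empty text).
#' @examples
#' tokenize("60S ribosomal protein L7")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character())
  raw <- unlist(strsplit(tolower(paste(text, collapse = " ")), "[^a-z0-9]+"))
  raw <- raw[nzchar(raw)]
  raw <- raw[!raw %in% cw_stopwords]
  vapply(raw, function(tok) {
    if (grepl("^[a-z]+$", tok)) porter_stem(tok) else tok
  }, character(1), USE.NAMES = FALSE)
}
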