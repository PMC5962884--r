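#' English suffix stemming (Porter algorithm)
#'
#' Reduces English words to stems for topic modelling, e.g. `"energy"` to
#' `"energi"` and `"balance"` to `"balanc"`. The classic five-step suffix
#' stripper; no stemming dictionary is consulted.
#'
#' @param words Character vector of lower-case words.
#' @return Character vector of stems, same length as `words`.
#' @export
#' @examples
#' porter_stem(c("energy", "balance", "exercise"))
porter_stem <- function(words) {
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# TRUE if letter i of w is a consonant ('y' after a consonant acts as a vowel)
.pt_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_cons(w, i - 1L))
  }
  TRUE
}

# the measure m: number of VC runs in C?(VC)^m V?
.pt_measure <- function(w) {
  n <- length(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .pt_cons(w, i), logical(1))
  rle_t <- rle(types)$values
  sum(rle_t[-length(rle_t)] == FALSE & rle_t[-1] == TRUE)
}

.pt_has_vowel <- function(w) {
  any(!vapply(seq_along(w), function(i) .pt_cons(w, i), logical(1)))
}

.pt_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && .pt_cons(w, n)
}

# consonant-vowel-consonant ending, final consonant not w, x or y
.pt_cvc <- function(w) {
  n <- length(w)
  n >= 3L && .pt_cons(w, n) && !.pt_cons(w, n - 1L) && .pt_cons(w, n - 2L) &&
    !(w[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(w, suf) {
  s <- strsplit(suf, "")[[1]]
  n <- length(w)
  length(s) <= n && identical(w[(n - length(s) + 1L):n], s)
}

.pt_stem_part <- function(w, suf) w[seq_len(length(w) - nchar(suf))]

porter_stem1 <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- strsplit(word, "")[[1]]

  # step 1a
  if (.pt_ends(w, "sses")) w <- .pt_stem_part(w, "es")
  else if (.pt_ends(w, "ies")) w <- .pt_stem_part(w, "es")
  else if (.pt_ends(w, "ss")) w <- w
  else if (.pt_ends(w, "s")) w <- .pt_stem_part(w, "s")

  # step 1b
  step1b2 <- FALSE
  if (.pt_ends(w, "eed")) {
    if (.pt_measure(.pt_stem_part(w, "eed")) > 0L) w <- .pt_stem_part(w, "d")
  } else if (.pt_ends(w, "ed")) {
    stem <- .pt_stem_part(w, "ed")
    if (.pt_has_vowel(stem)) { w <- stem; step1b2 <- TRUE }
  } else if (.pt_ends(w, "ing")) {
    stem <- .pt_stem_part(w, "ing")
    if (.pt_has_vowel(stem)) { w <- stem; step1b2 <- TRUE }
  }
  if (step1b2) {
    if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
      w <- c(w, "e")
    } else if (.pt_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- w[-length(w)]
    } else if (.pt_measure(w) == 1L && .pt_cvc(w)) {
      w <- c(w, "e")
    }
  }

  # step 1c
  if (.pt_ends(w, "y") && .pt_has_vowel(w[-length(w)])) w[length(w)] <- "i"

  # step 2 (m > 0)
  map2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
            izer = "ize", abli = "able", alli = "al", entli = "ent",
            eli = "e", ousli = "ous", ization = "ize", ation = "ate",
            ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
            ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(map2)) {
    if (.pt_ends(w, suf)) {
      stem <- .pt_stem_part(w, suf)
      if (.pt_measure(stem) > 0L) w <- c(stem, strsplit(map2[[suf]], "")[[1]])
      break
    }
  }

  # step 3 (m > 0)
  map3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
            ical = "ic", ful = "", ness = "")
  for (suf in names(map3)) {
    if (.pt_ends(w, suf)) {
      stem <- .pt_stem_part(w, suf)
      if (.pt_measure(stem) > 0L) w <- c(stem, strsplit(map3[[suf]], "")[[1]])
      break
    }
  }

  # step 4 (m > 1)
  sufs4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
             "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive",
             "ize")
  for (suf in sufs4) {
    if (.pt_ends(w, suf)) {
      stem <- .pt_stem_part(w, suf)
      if (suf == "ion" &&
          !(length(stem) > 0L && stem[length(stem)] %in% c("s", "t"))) next
      if (.pt_measure(stem) > 1L) w <- stem
      break
    }
  }

  # step 5a
  if (.pt_ends(w, "e")) {
    stem <- .pt_stem_part(w, "e")
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) w <- stem
  }
  # step 5b
  if (.pt_double_cons(w) && w[length(w)] == "l" && .pt_measure(w) > 1L) {
    w <- w[-length(w)]
  }

  paste(w, collapse = "")
}

#' English stopword list
#'
#' The snowball English stopword list used by default when preprocessing
#' abstracts.
#'
#' @return Character vector of stopwords.
#' @export
stop_words_en <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
    "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
    "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
    "being", "have", "has", "had", "having", "do", "does", "did", "doing",
    "would", "should", "could", "ought", "a", "an", "the", "and", "but",
    "if", "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down", "in",
    "out", "on", "off", "over", "under", "again", "further", "then", "once",
    "here", "there", "when", "where", "why", "how", "all", "any", "both",
    "each", "few", "more", "most", "other", "some", "such", "no", "nor",
    "not", "only", "own", "same", "so", "than", "too", "very", "can",
    "will", "just", "don", "now")
}
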