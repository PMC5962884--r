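#' Normalise author name renderings into comparable keys
#'
#' Folds case, diacritics and punctuation, splits hyphenated surnames, and
#' parses both `"Surname, Given"` and `"Given Surname"` orders into the same
#' key, so that e.g. `"J. Sievenpiper"` and `"Sievenpiper, J."` are
#' indistinguishable downstream. Normalisation is deliberately separate from
#' I/O: readers never alter text.
#'
#' @param raw Character vector of author renderings as printed.
#' @return A tibble with one row per rendering: `raw`, `surname` (folded,
#'   hyphen-split, tokens sorted), `given` (folded given tokens, in order),
#'   `full` (surname then given) and `key` (surname and given joined by
#'   `"|"`). Renderings whose surname is empty after folding get `NA` keys and
#'   are listed in the `rejected` attribute.
#' @export
#' @examples
#' normalize_name(c("Müller, Jürgen", "J. Sievenpiper", "Sievenpiper, J."))
normalize_name <- function(raw) {
  stopifnot(is.character(raw))
  parsed <- lapply(raw, parse_one_name)
  out <- tibble::tibble(
    raw = raw,
    surname = vapply(parsed, `[[`, character(1), "surname"),
    given = vapply(parsed, `[[`, character(1), "given")
  )
  out$full <- stringr::str_squish(paste(out$surname, out$given))
  out$key <- paste(out$surname, out$given, sep = "|")
  bad <- !nzchar(out$surname)
  if (any(bad)) {
    out$key[bad] <- NA_character_
    attr(out, "rejected") <- which(bad)
    warn(sprintf("%d rendering(s) rejected: empty surname after folding", sum(bad)))
  }
  out
}

# fold to lower-case ASCII word tokens; hyphens become token breaks
fold_name_tokens <- function(x) {
  x <- fold_chr(x)
  x <- stringr::str_replace_all(x, "[-']", " ")
  x <- stringr::str_replace_all(x, "[^a-z ]", " ")
  tokens <- strsplit(stringr::str_squish(x), " ", fixed = TRUE)[[1]]
  tokens[nzchar(tokens)]
}

is_initial_token <- function(tok) nchar(tok) == 1L

parse_one_name <- function(raw) {
  if (is.na(raw) || !nzchar(stringr::str_squish(raw))) {
    return(list(surname = "", given = ""))
  }
  if (grepl(",", raw, fixed = TRUE)) {
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    sur <- fold_name_tokens(parts[1])
    giv <- fold_name_tokens(paste(parts[-1], collapse = " "))
  } else {
    toks_raw <- strsplit(stringr::str_squish(raw), " +")[[1]]
    folded <- lapply(toks_raw, fold_name_tokens)
    flat <- unlist(folded)
    if (length(flat) <= 1L) {
      sur <- flat
      giv <- character(0)
    } else if (is_initial_token(flat[length(flat)]) && !is_initial_token(flat[1])) {
      # "Sievenpiper J." style: initials trail the surname
      first_init <- which(vapply(flat, is_initial_token, logical(1)))[1]
      sur <- flat[seq_len(first_init - 1L)]
      giv <- flat[first_init:length(flat)]
    } else {
      # "Given Surname": the final raw token (hyphen-split) is the surname
      sur <- folded[[length(folded)]]
      giv <- unlist(folded[-length(folded)])
    }
  }
  list(surname = paste(sort(sur), collapse = " "),
       given = paste(giv, collapse = " "))
}

# Are two folded given-name strings compatible renderings of one person?
# Token-wise: equal, or one a prefix of the other (covers initials "j" vs
# "jurgen" and truncations "stev" vs "steven"). Differing token counts are
# allowed (middle names omitted), but every aligned pair must agree.
given_compatible <- function(g1, g2) {
  t1 <- strsplit(g1, " ", fixed = TRUE)[[1]]
  t2 <- strsplit(g2, " ", fixed = TRUE)[[1]]
  n <- min(length(t1), length(t2))
  if (n == 0L) return(TRUE)
  all(vapply(seq_len(n), function(i) {
    a <- t1[i]; b <- t2[i]
    a == b || startsWith(b, a) || startsWith(a, b)
  }, logical(1)))
}

#' Resolve inconsistent renderings to canonical author identities
#'
#' Publications render the same person differently (full given name vs
#' initials, diacritics, hyphenation, name order), so exact key equality
#' under-merges. Renderings are grouped by exact folded surname and merged
#' within a group whenever their given names are compatible
#' (initial/prefix agreement token by token). Each cluster is labelled by its
#' most informative member (longest folded full name, ties broken
#' lexicographically).
#'
#' @param keys A tibble from [normalize_name()] (columns `surname`, `given`,
#'   `full`, `key`).
#' @return `keys` with two added columns: `person_id` (integer cluster id)
#'   and `person_key` (the representative key of the cluster).
#' @export
resolve_author_identities <- function(keys) {
  stopifnot(all(c("surname", "given", "full", "key") %in% names(keys)))
  n <- nrow(keys)
  parent <- uf_new(n)
  by_sur <- split(seq_len(n), keys$surname)
  for (idx in by_sur) {
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (given_compatible(keys$given[i], keys$given[j])) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  cluster <- uf_labels(parent)
  rep_key <- vapply(split(seq_len(n), cluster), function(idx) {
    full <- keys$full[idx]
    best <- idx[order(-nchar(full), keys$key[idx])][1]
    keys$key[best]
  }, character(1))
  keys$person_id <- cluster
  keys$person_key <- rep_key[as.character(cluster)]
  keys
}

#' Canonical author table for a corpus
#'
#' Normalises every author rendering of every record and resolves identities
#' across the whole record set, honouring per-record principal-investigator
#' restrictions when present.
#'
#' @param records A `biblio_corpus` tibble.
#' @param pi_only If `TRUE`, records carrying principal-investigator
#'   information (`pi_indices`) contribute only those authors.
#' @return Tibble with one row per (record, author) pair: `record_id`,
#'   `author_index`, the normalisation columns, `person_id`, `person_key`.
#' @export
author_table <- function(records, pi_only = FALSE) {
  rows <- purrr::map2_dfr(records$record_id, seq_len(nrow(records)), function(id, i) {
    auth <- records$authors[[i]]
    idx <- seq_len(nrow(auth))
    if (pi_only) {
      pi <- records$pi_indices[[i]]
      if (!is.null(pi) && length(pi) > 0L) idx <- intersect(idx, pi)
    }
    tibble::tibble(record_id = id, author_index = idx, raw = auth$raw[idx])
  })
  keys <- normalize_name(rows$raw)
  res <- resolve_author_identities(keys)
  dplyr::bind_cols(rows[c("record_id", "author_index")], res)
}
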