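#' Match cohort authors to disclosure-list names
#'
#' Whole and approximate string matching between canonical cohort persons and
#' transparency-list names. Exact key equality is taken first. Remaining
#' pairs are scored only when their folded surname token sets agree exactly
#' (the surname gate); the score is a normalised Levenshtein similarity on
#' the full folded names after expanding initial/prefix-compatible given
#' tokens to their longer form, so `"Blair, S."` scores 1 against
#' `"Blair, Steven"` while remaining an approximate (not exact) match.
#' Assignment is one-to-one between canonical persons, highest score first,
#' ties broken lexicographically. Scores at or above `threshold` are
#' auto-accepted; scores in `[review_band, threshold)` are flagged
#' `needs_review` — the hook standing in for manual verification — and count
#' as accepted only under `policy = "promote_review"`.
#'
#' @param cohort_keys Tibble of canonical cohort persons: the `persons`
#'   element of [cohort_authors()] joined back to key columns, or any tibble
#'   with `person_key` (and optionally `surname`, `given`, `full`; re-derived
#'   from the key when absent).
#' @param disclosure_entries Tibble from [read_disclosure_list()].
#' @param threshold Auto-accept similarity threshold in (0, 1].
#' @param review_band Lower edge of the needs-review band.
#' @param policy `"strict"` (default) or `"promote_review"`.
#' @return Tibble of match results: `author_key`, `name_raw`, `source_list`,
#'   `match_type` (`exact`/`approximate`), `score`, `review_status`
#'   (`auto_accepted`, `needs_review`, `rejected`).
#' @export
match_author_lists <- function(cohort_keys, disclosure_entries,
                               threshold = 0.90, review_band = 0.80,
                               policy = c("strict", "promote_review")) {
  policy <- match.arg(policy)
  if (threshold <= 0 || threshold > 1) abort("threshold must lie in (0, 1]")
  authors <- key_parts(unique(cohort_keys$person_key))
  if (nrow(authors) == 0 || nrow(disclosure_entries) == 0) {
    abort("both author and disclosure lists must be non-empty")
  }
  disc <- normalize_name(disclosure_entries$name_raw)
  disc$entry_index <- seq_len(nrow(disc))
  disc <- resolve_author_identities(disc)

  # candidate pairs: exact surname token-set agreement
  cand <- dplyr::inner_join(
    authors, disc,
    by = "surname", suffix = c("_a", "_d"), relationship = "many-to-many"
  )
  if (nrow(cand) == 0) {
    return(empty_matches())
  }
  cand$score <- score_given_pair(cand$surname, cand$given_a, cand$given_d)
  cand$match_type <- ifelse(cand$key_a == cand$key_d, "exact", "approximate")
  cand$score[cand$match_type == "exact"] <- 1
  cand <- cand[cand$score >= review_band, ]
  # one-to-one greedy assignment on canonical persons, highest score first
  ord <- order(-cand$score, cand$match_type != "exact", cand$key_a, cand$raw)
  cand <- cand[ord, ]
  used_a <- character(0)
  used_d <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$key_a[i] %in% used_a || cand$person_id[i] %in% used_d) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$key_a[i])
    used_d <- c(used_d, cand$person_id[i])
  }
  res <- cand[keep, ]
  accepted_cut <- res$score >= threshold | res$match_type == "exact"
  review <- !accepted_cut
  status <- ifelse(accepted_cut, "auto_accepted", "needs_review")
  if (policy == "promote_review") status[status == "needs_review"] <- "auto_accepted"
  tibble::tibble(
    author_key = res$key_a,
    name_raw = disclosure_entries$name_raw[res$entry_index],
    source_list = disclosure_entries$source_list[res$entry_index],
    entry_index = res$entry_index,
    match_type = res$match_type,
    score = res$score,
    review_status = status
  )
}

empty_matches <- function() {
  tibble::tibble(author_key = character(0), name_raw = character(0),
                 source_list = character(0), entry_index = integer(0),
                 match_type = character(0), score = numeric(0),
                 review_status = character(0))
}

key_parts <- function(person_key) {
  parts <- strsplit(person_key, "|", fixed = TRUE)
  tibble::tibble(
    key = person_key,
    surname = vapply(parts, `[`, character(1), 1),
    given = vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1))
  )
}

# similarity after expanding compatible initial/prefix given tokens
score_given_pair <- function(surname, g1, g2) {
  vapply(seq_along(surname), function(i) {
    e <- expand_given(g1[i], g2[i])
    s1 <- stringr::str_squish(paste(surname[i], e[1]))
    s2 <- stringr::str_squish(paste(surname[i], e[2]))
    edit_similarity(s1, s2)
  }, numeric(1))
}

expand_given <- function(g1, g2) {
  t1 <- strsplit(g1, " ", fixed = TRUE)[[1]]
  t2 <- strsplit(g2, " ", fixed = TRUE)[[1]]
  n <- min(length(t1), length(t2))
  if (n > 0) {
    for (i in seq_len(n)) {
      if (t1[i] != t2[i] && (startsWith(t2[i], t1[i]) || startsWith(t1[i], t2[i]))) {
        longer <- if (nchar(t1[i]) >= nchar(t2[i])) t1[i] else t2[i]
        t1[i] <- longer
        t2[i] <- longer
      }
    }
  }
  c(paste(t1, collapse = " "), paste(t2, collapse = " "))
}

accepted_matches <- function(matches) {
  matches[matches$review_status == "auto_accepted", ]
}

#' Disclosure-coverage metrics
#'
#' @param matches Result of [match_author_lists()].
#' @param cohort_keys Canonical cohort persons (tibble with `person_key`).
#' @param disclosure_entries The disclosure list that was matched.
#' @param cohort_records Optionally, the cohort records; when given, the
#'   unmatched remainder (articles without any matched author and their
#'   author union) is reported too.
#' @return A `coverage_report` list: `n_cohort_authors`,
#'   `n_disclosure_names`, `n_matched`, `pct_of_disclosure`, `pct_of_cohort`
#'   (both to one decimal), `unmatched_disclosure_names`, and
#'   `unmatched_author_articles = c(n_authors, n_articles)` when records are
#'   supplied.
#' @export
coverage_metrics <- function(matches, cohort_keys, disclosure_entries,
                             cohort_records = NULL) {
  n_cohort <- dplyr::n_distinct(cohort_keys$person_key)
  if (n_cohort == 0) abort("empty cohort")
  n_disc <- nrow(disclosure_entries)
  acc <- accepted_matches(matches)
  n_matched <- dplyr::n_distinct(acc$author_key)
  unmatched <- disclosure_entries$name_raw[
    !seq_len(n_disc) %in% acc$entry_index]
  out <- list(
    n_cohort_authors = n_cohort,
    n_disclosure_names = n_disc,
    n_matched = n_matched,
    pct_of_disclosure = round(100 * n_matched / n_disc, 1),
    pct_of_cohort = round(100 * n_matched / n_cohort, 1),
    unmatched_disclosure_names = unmatched
  )
  if (!is.null(cohort_records)) {
    rem <- remove_matched_publications(cohort_records, matches)
    out$unmatched_author_articles <- c(
      n_authors = length(rem$remaining_author_keys),
      n_articles = nrow(rem$records)
    )
  }
  structure(out, class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %d matched of %d disclosure names (%.1f%%) and %d cohort authors (%.1f%%)\n",
              x$n_matched, x$n_disclosure_names, x$pct_of_disclosure,
              x$n_cohort_authors, x$pct_of_cohort))
  if (!is.null(x$unmatched_author_articles)) {
    cat(sprintf("Unmatched remainder: %d authors on %d articles\n",
                x$unmatched_author_articles[["n_authors"]],
                x$unmatched_author_articles[["n_articles"]]))
  }
  invisible(x)
}

#' Remove publications involving matched authors
#'
#' A record is removed iff at least one of its (investigator-eligible)
#' authors is an accepted matched person; the remaining author set is the
#' deduplicated union over remaining records.
#'
#' @param cohort_records Cohort `biblio_corpus`.
#' @param matches Result of [match_author_lists()].
#' @param tab Optional precomputed [author_table()] (`pi_only = TRUE`) for
#'   `cohort_records`.
#' @return List: `records` (remaining), `removed_record_ids`,
#'   `remaining_author_keys` (canonical person keys).
#' @export
remove_matched_publications <- function(cohort_records, matches, tab = NULL) {
  tab <- tab %||% author_table(cohort_records, pi_only = TRUE)
  acc <- accepted_matches(matches)
  hit <- unique(tab$record_id[tab$person_key %in% acc$author_key])
  remaining <- cohort_records[!cohort_records$record_id %in% hit, ]
  rem_keys <- unique(tab$person_key[tab$record_id %in% remaining$record_id])
  list(records = remaining, removed_record_ids = hit,
       remaining_author_keys = rem_keys)
}

#' Apply corresponding-author survey adjustments
#'
#' Two adjustment rules over the unmatched remainder: (i) a respondent who
#' *denied* funding is removed from the author set, while any primary
#' recipients they named are retained; (ii) for a respondent who *confirmed*
#' funding, all co-authors on each of the respondent's publications are
#' removed, the confirmer being accounted separately as a funding recipient.
#' Records left with no unaccounted author are dropped from the record set.
#'
#' @param remaining Output of [remove_matched_publications()] (or a list
#'   with `records` and `remaining_author_keys`).
#' @param outcomes Survey outcomes tibble (see [read_survey_outcomes()]);
#'   `author_key` values are canonical person keys of corresponding authors.
#' @param tab Optional precomputed [author_table()] for the remaining records.
#' @return List: `authors` (adjusted author key set), `records` (adjusted
#'   record set), `recipients` (keys accounted as confirmed funding
#'   recipients), `skipped` (outcomes referencing unknown authors).
#' @export
apply_survey_adjustments <- function(remaining, outcomes, tab = NULL) {
  validate_survey_outcomes(outcomes)
  records <- remaining$records
  tab <- tab %||% author_table(records, pi_only = TRUE)
  authors <- unique(remaining$remaining_author_keys)
  known <- outcomes$author_key %in% tab$person_key
  skipped <- outcomes[!known, ]
  if (nrow(skipped) > 0) {
    warn(sprintf("%d survey outcome(s) reference unknown authors; skipped", nrow(skipped)))
  }
  outcomes <- outcomes[known, ]
  removed <- character(0)
  recipients <- character(0)
  protected <- character(0)
  for (i in seq_len(nrow(outcomes))) {
    key <- outcomes$author_key[i]
    if (outcomes$outcome[i] == "denied") {
      removed <- union(removed, key)
      protected <- union(protected, outcomes$named_recipients[[i]])
    } else if (outcomes$outcome[i] == "confirmed") {
      recs <- corresponding_records(records, tab, key)
      co <- tab$person_key[tab$record_id %in% recs & tab$person_key != key]
      removed <- union(removed, co)
      recipients <- union(recipients, key)
      removed <- union(removed, key)
    }
  }
  adjusted_authors <- setdiff(authors, setdiff(removed, protected))
  keep_rec <- vapply(records$record_id, function(id) {
    any(tab$person_key[tab$record_id == id] %in% adjusted_authors)
  }, logical(1))
  list(authors = adjusted_authors, records = records[keep_rec, ],
       recipients = recipients, skipped = skipped)
}

# record ids whose corresponding author resolves to `key`
corresponding_records <- function(records, tab, key) {
  idx <- !is.na(records$corresponding_author_index)
  ids <- records$record_id[idx]
  ca <- records$corresponding_author_index[idx]
  hit <- vapply(seq_along(ids), function(i) {
    row <- tab[tab$record_id == ids[i] & tab$author_index == ca[i], ]
    nrow(row) > 0 && row$person_key[1] == key
  }, logical(1))
  ids[hit]
}

#' Tally survey outcomes
#'
#' @param outcomes Survey outcomes tibble.
#' @return Tibble with one row per outcome category (`confirmed`, `denied`,
#'   `no_reply`, `invalid_address`): count `n` and `pct`, the percentage of
#'   all outcomes rounded to the nearest integer.
#' @export
survey_tally <- function(outcomes) {
  if (nrow(outcomes) == 0) abort("no survey outcomes")
  validate_survey_outcomes(outcomes)
  cats <- c("confirmed", "denied", "no_reply", "invalid_address")
  n <- unname(vapply(cats, function(cat) sum(outcomes$outcome == cat), integer(1)))
  tibble::tibble(outcome = cats, n = n,
                 pct = as.integer(round(100 * n / sum(n))))
}
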