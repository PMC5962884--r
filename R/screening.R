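#' Default cue phrases for the direct-funding screen
#'
#' The screen distinguishes funding statements that report *direct receipt of
#' funding* from an entity (direct cues such as "funded by", "grant from")
#' from statements that only declare a competing interest (consultancy,
#' speaking engagements, honoraria) or indirect support (student grants,
#' institutional donations). Cue lists are plain substrings matched
#' case-insensitively within the sentence containing the funder mention, and
#' are fully configuration-exposed.
#'
#' @return A list with character vectors `direct`, `competing`, `indirect`.
#' @export
default_screening_cues <- function() {
  list(
    direct = c("funded by", "funding from", "funding for", "grant from",
               "grant provided by", "supported by", "financially supported",
               "provided funding", "funding was provided", "funded in part by"),
    competing = c("consult", "speaker", "speaking", "honorari", "advisory",
                  "advisor", "employee", "employment", "personal fees",
                  "lecture fees", "speaking fees", "travel reimbursement"),
    indirect = c("student grant", "student travel award", "studentship",
                 "doctoral scholarship", "donation to")
  )
}

#' Case-insensitive substring pre-filter
#'
#' The corpus-building step: keep every record whose funding-acknowledgement
#' text contains `needle` (default `"cola"`), mimicking a broad funding-text
#' field search. Records with empty funding text simply fail the test.
#'
#' @param records A `biblio_corpus`.
#' @param needle Non-empty substring.
#' @return List with `records` (kept subset) and `decisions` (one row per
#'   input record: `record_id`, `stage = "substring_prefilter"`, `included`,
#'   `reason_code`).
#' @export
prefilter_by_substring <- function(records, needle = "cola") {
  if (!nzchar(needle)) abort("needle must be non-empty")
  hit <- stringr::str_detect(fold_chr(records$funding_text),
                             stringr::fixed(fold_chr(needle)))
  decisions <- tibble::tibble(
    record_id = records$record_id,
    stage = "substring_prefilter",
    included = hit,
    reason_code = ifelse(hit, "included", "no_substring")
  )
  list(records = records[hit, ], decisions = decisions)
}

#' Detect funder-entity mentions in records
#'
#' Scans funding text and database-parsed agency strings for every dictionary
#' variant, case-insensitively, longest-variant-first, reporting
#' non-overlapping occurrences with character spans and their source field.
#'
#' @param records A `biblio_corpus` (one or many rows).
#' @param dict Entity dictionary from [read_entity_dictionary()].
#' @return Tibble: `record_id`, `entity_canonical`, `entity_group`, `start`,
#'   `end` (character offsets in the source text), `source`
#'   (`funding_text` or `agency_strings`), `agency_index`.
#' @export
detect_funder_mentions <- function(records, dict) {
  n_ag <- lengths(records$agency_strings)
  texts <- c(records$funding_text, unlist(records$agency_strings))
  meta <- tibble::tibble(
    record_id = c(records$record_id, rep(records$record_id, n_ag)),
    source = rep(c("funding_text", "agency_strings"),
                 c(nrow(records), sum(n_ag))),
    agency_index = c(rep(NA_integer_, nrow(records)),
                     unlist(lapply(n_ag, seq_len)))
  )
  hits <- scan_texts_mentions(texts, dict)
  if (nrow(hits) == 0) {
    return(tibble::tibble(record_id = character(0),
                          entity_canonical = character(0),
                          entity_group = character(0), start = integer(0),
                          end = integer(0), source = character(0),
                          agency_index = integer(0)))
  }
  out <- dplyr::bind_cols(meta[hits$text_idx, ],
                          hits[c("entity_canonical", "entity_group",
                                 "start", "end")])
  out[order(match(out$record_id, records$record_id), out$start), ]
}

# vectorized variant scan over many texts; dict rows are processed
# longest-variant-first so shorter variants never fire inside a longer one
scan_texts_mentions <- function(texts, dict) {
  folded <- fold_chr(texts)
  cand <- purrr::map_dfr(seq_len(nrow(dict)), function(v) {
    locs <- stringi::stri_locate_all_fixed(folded, dict$variant_folded[v],
                                           omit_no_match = TRUE)
    n <- vapply(locs, nrow, integer(1))
    if (sum(n) == 0) return(tibble::tibble())
    mat <- do.call(rbind, locs)
    tibble::tibble(text_idx = rep(seq_along(folded), n), rank = v,
                   start = mat[, 1], end = mat[, 2])
  })
  if (nrow(cand) == 0) return(tibble::tibble())
  # word-boundary guard
  before <- substr(folded[cand$text_idx], cand$start - 1L, cand$start - 1L)
  after <- substr(folded[cand$text_idx], cand$end + 1L, cand$end + 1L)
  ok <- !grepl("[a-z0-9]", before) & !grepl("[a-z0-9]", after)
  cand <- cand[ok, ]
  # resolve overlaps per text, longest-variant-first
  cand <- cand[order(cand$text_idx, cand$rank, cand$start), ]
  keep <- logical(nrow(cand))
  idx_by_text <- split(seq_len(nrow(cand)), cand$text_idx)
  for (rows in idx_by_text) {
    taken_start <- integer(0)
    taken_end <- integer(0)
    for (r in rows) {
      if (!any(cand$start[r] <= taken_end & cand$end[r] >= taken_start)) {
        keep[r] <- TRUE
        taken_start <- c(taken_start, cand$start[r])
        taken_end <- c(taken_end, cand$end[r])
      }
    }
  }
  cand <- cand[keep, ]
  cand$entity_canonical <- dict$canonical[cand$rank]
  cand$entity_group <- dict$group[cand$rank]
  cand
}

# character spans of sentences (split on '.' and ';')
sentence_spans <- function(text) {
  stringr::str_locate_all(text, "[^.;]+")[[1]]
}

sentence_of <- function(spans, pos) {
  which(spans[, 1] <= pos & spans[, 2] >= pos)[1]
}

#' Classify records as directly funded or excluded with a reason
#'
#' A record passes the screen iff at least one brand-group mention (any group
#' except `other_cola`) occurs in a direct-funding context: its sentence
#' contains a direct cue and no indirect cue. Excluded records receive
#' exactly one reason code, assigned by the first matching rule in the fixed
#' precedence order `ci_only` (a brand-mention sentence carries a
#' competing-interest cue) > `indirect` (an indirect cue) > `other_cola`
#' (the only mentions are other-cola brands) > `indexing_error` (the agency
#' table or funding text names the brand but no direct-funding context
#' exists).
#'
#' @param records A `biblio_corpus`.
#' @param mentions Output of [detect_funder_mentions()] for these records.
#' @param cues Cue lists, see [default_screening_cues()].
#' @return Decisions tibble (`stage = "direct_funding_screen"`).
#' @export
classify_direct_funding <- function(records, mentions,
                                    cues = default_screening_cues()) {
  by_rec <- split(mentions, mentions$record_id)
  decide <- function(i) {
    id <- records$record_id[i]
    m <- by_rec[[id]]
    if (is.null(m) || nrow(m) == 0) {
      return(c(FALSE, "indexing_error"))
    }
    text <- records$funding_text[i]
    folded <- fold_chr(text)
    spans <- sentence_spans(folded)
    txt_m <- m[m$source == "funding_text", ]
    brand_txt <- txt_m[txt_m$entity_group != "other_cola", ]
    sent_has <- function(pos, cue_set) {
      s <- sentence_of(spans, pos)
      if (is.na(s)) return(FALSE)
      sent <- substr(folded, spans[s, 1], spans[s, 2])
      any(stringr::str_detect(sent, stringr::fixed(cue_set)))
    }
    if (nrow(brand_txt) > 0) {
      direct <- vapply(brand_txt$start, function(p) {
        sent_has(p, cues$direct) && !sent_has(p, cues$indirect)
      }, logical(1))
      if (any(direct)) return(c(TRUE, "included"))
      if (any(vapply(brand_txt$start, sent_has, logical(1), cues$competing))) {
        return(c(FALSE, "ci_only"))
      }
      if (any(vapply(brand_txt$start, sent_has, logical(1), cues$indirect))) {
        return(c(FALSE, "indirect"))
      }
    }
    if (all(m$entity_group == "other_cola")) return(c(FALSE, "other_cola"))
    c(FALSE, "indexing_error")
  }
  res <- vapply(seq_len(nrow(records)), decide, character(2))
  tibble::tibble(
    record_id = records$record_id,
    stage = "direct_funding_screen",
    included = res[1, ] == "TRUE",
    reason_code = res[2, ]
  )
}

#' Build Sample 1: all directly brand-funded studies
#'
#' @param records Records entering the screen.
#' @param decisions Decisions from [classify_direct_funding()].
#' @return The included subset of `records`.
#' @export
build_sample1 <- function(records, decisions) {
  keep <- decisions$record_id[decisions$included]
  records[records$record_id %in% keep, ]
}

#' Build Sample 2: restrict to transparency-participating funders
#'
#' A Sample 1 record is retained iff at least one of its funder mentions
#' belongs to a participating group (parent company, foundation, research
#' institute, North America, or a subsidiary that published a transparency
#' list); records funded only by non-participating subsidiaries or bottlers
#' are excluded with reason `subsidiary_nonparticipating`.
#'
#' @param sample1 Sample 1 records.
#' @param mentions Mentions for (at least) these records.
#' @param participating Participating group labels.
#' @return List with `records` and `decisions` (`stage = "brand_eligibility"`).
#' @export
build_sample2 <- function(sample1, mentions,
                          participating = PARTICIPATING_GROUPS) {
  ok <- unname(vapply(sample1$record_id, function(id) {
    g <- mentions$entity_group[mentions$record_id == id]
    any(g %in% participating)
  }, logical(1)))
  decisions <- tibble::tibble(
    record_id = sample1$record_id,
    stage = "brand_eligibility",
    included = ok,
    reason_code = ifelse(ok, "included", "subsidiary_nonparticipating")
  )
  list(records = sample1[ok, ], decisions = decisions)
}

#' Build the transparency-matching cohort
#'
#' Starting from Sample 1, applies the disclosure-list eligibility rules in
#' order: (i) the publication window (default January 2010 - December 2015,
#' inclusive; records lacking a month are judged on year alone), (ii)
#' exclusion of studies funded only by non-participating subsidiaries,
#' (iii) exclusion of consortium-authored studies, (iv) restriction to
#' principal/co-investigators where the record identifies them (when no
#' investigator information is present - the usual case - all authors are
#' retained; this criterion therefore drops authors, not records, and is
#' applied in [cohort_authors()]).
#'
#' @param sample1 Sample 1 records.
#' @param mentions Funder mentions for these records.
#' @param window Length-2 character vector `c("YYYY-MM", "YYYY-MM")`.
#' @param participating Participating group labels.
#' @return List with `records` and `decisions` (`stage = "cohort_eligibility"`,
#'   reasons `pre_window`, `post_window`, `subsidiary_nonparticipating`,
#'   `consortium`).
#' @export
build_transparency_cohort <- function(sample1, mentions,
                                      window = c("2010-01", "2015-12"),
                                      participating = PARTICIPATING_GROUPS) {
  w <- parse_window(window)
  reason <- vapply(seq_len(nrow(sample1)), function(i) {
    ym <- 12L * sample1$year[i] +
      (if (is.na(sample1$month[i])) NA_integer_ else sample1$month[i] - 1L)
    y <- sample1$year[i]
    pre <- if (is.na(sample1$month[i])) y < w$start_year else ym < w$start
    post <- if (is.na(sample1$month[i])) y > w$end_year else ym > w$end
    if (pre) return("pre_window")
    if (post) return("post_window")
    g <- mentions$entity_group[mentions$record_id == sample1$record_id[i]]
    if (!any(g %in% participating)) return("subsidiary_nonparticipating")
    if (sample1$consortium_flag[i]) return("consortium")
    "included"
  }, character(1))
  decisions <- tibble::tibble(
    record_id = sample1$record_id,
    stage = "cohort_eligibility",
    included = reason == "included",
    reason_code = reason
  )
  list(records = sample1[decisions$included, ], decisions = decisions)
}

parse_window <- function(window) {
  p <- do.call(rbind, strsplit(window, "-", fixed = TRUE))
  y <- as.integer(p[, 1]); m <- as.integer(p[, 2])
  list(start = 12L * y[1] + m[1] - 1L, end = 12L * y[2] + m[2] - 1L,
       start_year = y[1], end_year = y[2])
}

#' Unique canonical authors of the cohort
#'
#' Applies the investigator criterion (authors outside `pi_indices` dropped
#' when that information is present), normalises every retained rendering and
#' resolves identities across the cohort.
#'
#' @param cohort_records Cohort `biblio_corpus`.
#' @return List with `table` (per-rendering author table, see
#'   [author_table()]) and `persons` (one row per canonical person:
#'   `person_key`, `n_renderings`, `n_records`).
#' @export
cohort_authors <- function(cohort_records) {
  tab <- author_table(cohort_records, pi_only = TRUE)
  persons <- tab |>
    dplyr::group_by(.data$person_key) |>
    dplyr::summarise(n_renderings = dplyr::n(),
                     n_records = dplyr::n_distinct(.data$record_id),
                     .groups = "drop")
  list(table = tab, persons = persons)
}
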