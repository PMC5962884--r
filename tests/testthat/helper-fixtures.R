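# The packaged flow fixture and everything downstream of it is expensive to
# build, so it is generated once per test run and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

flow_fixture_cached <- function() {
  if (!exists("fx", envir = .fixture_cache)) {
    assign("fx", generate_flow_fixture(), envir = .fixture_cache)
  }
  get("fx", envir = .fixture_cache)
}

screened_fixture_cached <- function() {
  if (!exists("sc", envir = .fixture_cache)) {
    fx <- flow_fixture_cached()
    dict <- default_entity_dictionary()
    pre <- prefilter_by_substring(fx$records)
    mentions <- detect_funder_mentions(pre$records, dict)
    screen <- classify_direct_funding(pre$records, mentions)
    sample1 <- build_sample1(pre$records, screen)
    s2 <- build_sample2(sample1, mentions)
    cohort <- build_transparency_cohort(sample1, mentions)
    ca <- cohort_authors(cohort$records)
    matches <- match_author_lists(ca$persons, fx$disclosure)
    assign("sc", list(fx = fx, pre = pre, mentions = mentions,
                      screen = screen, sample1 = sample1, s2 = s2,
                      cohort = cohort, ca = ca, matches = matches),
           envir = .fixture_cache)
  }
  get("sc", envir = .fixture_cache)
}

# a small but fully consistent flow spec for fast end-to-end tests
small_flow_spec <- function(seed = 99L) {
  flow_spec(list(
    n_total = 40L, seed = seed,
    exclusion_plan = list(ci_only = 6L, indirect = 3L, other_cola = 2L,
                          indexing_error = 2L),
    subsidiary_plan = 4L,
    cohort_plan = list(pre_window = 2L, post_window = 2L, consortium = 1L,
                       non_pi = 0L),
    roster_plan = list(planted_matches = 3L, matched_articles = 6L,
                       matched_extra_authors = 8L, unmatched_articles = 12L,
                       unmatched_authors = 20L, unmatched_corresponding = 10L,
                       disclosure_size = 10L),
    survey_plan = list(confirmed = 1L, denied = 2L, no_reply = 6L,
                       invalid_address = 1L)
  ))
}

# minimal hand-built corpus
tiny_corpus <- function(rows) {
  biblio_corpus(dplyr::bind_rows(rows))
}

tiny_record <- function(id, authors_raw, funding_text = "", year = 2012L,
                        month = NA_integer_, agency = character(0),
                        consortium = FALSE, corr = NA_integer_,
                        abstract = "", pi = NULL) {
  keys <- normalize_name(authors_raw)
  tibble::tibble(
    record_id = id, title = paste("title", id), abstract = abstract,
    journal = "Journal of Dietary Balance", year = year, month = month,
    authors = list(tibble::tibble(raw = authors_raw, surname = keys$surname,
                                  given = keys$given,
                                  canonical_id = NA_character_)),
    corresponding_author_index = corr, funding_text = funding_text,
    agency_strings = list(agency), consortium_flag = consortium,
    pi_indices = list(pi)
  )
}
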