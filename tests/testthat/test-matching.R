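persons_tbl <- function(keys) tibble::tibble(person_key = keys)
entries_tbl <- function(names, source = "USA") {
  tibble::tibble(name_raw = names, source_list = source,
                 person_kind = "researcher")
}

test_that("identical keys give an exact match with score 1", {
  m <- match_author_lists(persons_tbl("blair|steven"),
                          entries_tbl("Blair, Steven"))
  expect_equal(nrow(m), 1)
  expect_equal(m$match_type, "exact")
  expect_equal(m$score, 1)
  expect_equal(m$review_status, "auto_accepted")
})

test_that("compatible initials yield an accepted approximate match", {
  m <- match_author_lists(persons_tbl("blair|s"), entries_tbl("Blair, Steven"))
  expect_equal(m$match_type, "approximate")
  expect_gte(m$score, 0.9)
  expect_equal(m$review_status, "auto_accepted")
})

test_that("surname gate blocks near-miss surnames with different initials", {
  m <- match_author_lists(persons_tbl(c("blairs|t", "hill|james")),
                          entries_tbl(c("Blair, Steven", "Hillman, James")))
  expect_equal(nrow(accepted <- m[m$review_status == "auto_accepted", ]), 0)
})

test_that("assignment is one-to-one on persons and entries", {
  m <- match_author_lists(
    persons_tbl(c("blair|steven", "blair|s", "katz|david")),
    entries_tbl(c("Blair, Steven", "Katz, D.")))
  acc <- m[m$review_status == "auto_accepted", ]
  expect_equal(anyDuplicated(acc$entry_index), 0)
  expect_equal(anyDuplicated(acc$author_key), 0)
  # the exact rendering wins the contested entry
  expect_true("blair|steven" %in% acc$author_key)
})

test_that("raising the threshold never increases accepted matches", {
  sc <- screened_fixture_cached()
  thresholds <- c(0.5, 0.7, 0.8, 0.9, 0.95, 1.0)
  n_acc <- vapply(thresholds, function(th) {
    m <- match_author_lists(sc$ca$persons, sc$fx$disclosure, threshold = th,
                            review_band = min(th, 0.5))
    nrow(m[m$review_status == "auto_accepted", ])
  }, numeric(1))
  expect_true(all(diff(n_acc) <= 0))
})

test_that("review-band matches count only when promoted", {
  # same surname, given names sharing no prefix: similarity below auto-accept
  m_strict <- match_author_lists(persons_tbl("hill|jas"), entries_tbl("Hill, Jan"),
                                 threshold = 0.95, review_band = 0.5)
  expect_equal(m_strict$review_status, "needs_review")
  m_promoted <- match_author_lists(persons_tbl("hill|jas"), entries_tbl("Hill, Jan"),
                                   threshold = 0.95, review_band = 0.5,
                                   policy = "promote_review")
  expect_equal(m_promoted$review_status, "auto_accepted")
})

test_that("coverage metrics compute counts and one-decimal percentages", {
  keys <- persons_tbl(paste0("surname", letters[1:10], "|a"))
  entries <- entries_tbl(c("Surnamea, A.", "Unrelatedname, B."))
  m <- match_author_lists(keys, entries)
  cov <- coverage_metrics(m, keys, entries)
  expect_equal(cov$n_matched, 1)
  expect_equal(cov$pct_of_disclosure, 50)
  expect_equal(cov$pct_of_cohort, 10)
  expect_equal(cov$unmatched_disclosure_names, "Unrelatedname, B.")
  none <- match_author_lists(persons_tbl("zz|q"), entries)
  cov0 <- coverage_metrics(none, persons_tbl("zz|q"), entries)
  expect_equal(cov0$pct_of_cohort, 0)
  expect_equal(cov0$pct_of_disclosure, 0)
  expect_error(coverage_metrics(m, persons_tbl(character(0)), entries),
               "empty cohort")
})

test_that("publication removal drops records with any matched author", {
  corp <- tiny_corpus(list(
    tiny_record("M1", c("Blair, Steven", "Hill, James"), "x"),
    tiny_record("M2", "Hill, James", "x"),
    tiny_record("M3", "Katz, David", "x")
  ))
  m <- match_author_lists(persons_tbl("blair|steven"),
                          entries_tbl("Blair, Steven"))
  rem <- remove_matched_publications(corp, m)
  expect_setequal(rem$records$record_id, c("M2", "M3"))
  expect_setequal(rem$remaining_author_keys, c("hill|james", "katz|david"))
  # conservation: removed + remaining = all
  expect_equal(length(rem$removed_record_ids) + nrow(rem$records), nrow(corp))
  # no matches: identity
  none <- match_author_lists(persons_tbl("nobody|x"), entries_tbl("Blair, S."))
  rem2 <- remove_matched_publications(corp, none)
  expect_equal(nrow(rem2$records), nrow(corp))
  # sole matched author: empty remainder
  solo <- tiny_corpus(list(tiny_record("M4", "Blair, Steven", "x")))
  rem3 <- remove_matched_publications(solo, m)
  expect_equal(nrow(rem3$records), 0)
})

test_that("survey adjustments remove deniers and confirmers' co-authors", {
  corp <- tiny_corpus(list(
    tiny_record("S1", c("Adams, Ann", "Burke, Bob"), "x", corr = 1L),
    tiny_record("S2", c("Cole, Cara", "Dean, Dan"), "x", corr = 1L),
    tiny_record("S3", "Ezra, Eve", "x", corr = 1L)
  ))
  rem <- list(records = corp,
              remaining_author_keys = c("adams|ann", "burke|bob", "cole|cara",
                                        "dean|dan", "ezra|eve"))
  outcomes <- tibble::tibble(
    author_key = c("adams|ann", "cole|cara", "ezra|eve"),
    outcome = c("confirmed", "denied", "no_reply"),
    named_recipients = list(character(0), "dean|dan", character(0))
  )
  adj <- apply_survey_adjustments(rem, outcomes)
  # confirmed corresponding author: co-author removed, confirmer accounted
  expect_false("burke|bob" %in% adj$authors)
  expect_equal(adj$recipients, "adams|ann")
  # denier removed, named recipient kept
  expect_false("cole|cara" %in% adj$authors)
  expect_true("dean|dan" %in% adj$authors)
  expect_true("ezra|eve" %in% adj$authors)
  # S1 has no unaccounted author left
  expect_setequal(adj$records$record_id, c("S2", "S3"))
  # all no_reply leaves everything unchanged
  quiet <- outcomes
  quiet$outcome <- "no_reply"
  quiet$named_recipients <- list(character(0), character(0), character(0))
  adj2 <- apply_survey_adjustments(rem, quiet)
  expect_setequal(adj2$authors, rem$remaining_author_keys)
  # unknown author is reported and skipped
  stray <- tibble::tibble(author_key = "ghost|g", outcome = "denied",
                          named_recipients = list(character(0)))
  expect_warning(adj3 <- apply_survey_adjustments(rem, stray), "unknown")
  expect_equal(nrow(adj3$skipped), 1)
})

test_that("survey tallies use integer-rounded percentages", {
  outcomes <- tibble::tibble(
    author_key = sprintf("a%03d|x", 1:131),
    outcome = rep(c("confirmed", "denied", "no_reply", "invalid_address"),
                  c(14, 29, 68, 20)),
    named_recipients = replicate(131, character(0), simplify = FALSE)
  )
  tal <- survey_tally(outcomes)
  expect_equal(tal$pct[tal$outcome == "confirmed"], 11L)
  expect_equal(tal$pct[tal$outcome == "denied"], 22L)
  expect_equal(sum(tal$n), 131)
  one <- outcomes[outcomes$outcome == "denied", ]
  tal1 <- survey_tally(one)
  expect_equal(tal1$pct[tal1$outcome == "denied"], 100L)
})
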