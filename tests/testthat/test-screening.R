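dict <- default_entity_dictionary()

test_that("substring pre-filter keeps any cola mention, case-insensitively", {
  corp <- tiny_corpus(list(
    tiny_record("R1", "Doe, J.", "Supported by Coca-Cola."),
    tiny_record("R2", "Doe, J.", ""),
    tiny_record("R3", "Doe, J.", "Pepsi-Cola supported this work.")
  ))
  out <- prefilter_by_substring(corp, "cola")
  expect_setequal(out$records$record_id, c("R1", "R3"))
  expect_equal(out$decisions$reason_code[2], "no_substring")
  expect_error(prefilter_by_substring(corp, ""), "non-empty")
})

test_that("funder mentions are detected longest-variant-first with groups", {
  corp <- tiny_corpus(list(
    tiny_record("R1", "Doe, J.",
                "funded by the Beverage Institute of Health and Wellness"),
    tiny_record("R2", "Doe, J.", "", agency = character(0)),
    tiny_record("R3", "Doe, J.", "Pepsi-Cola provided funding."),
    tiny_record("R4", "Doe, J.", "Funded by The Coca-Cola Company.",
                agency = "Coca-Cola Foundation")
  ))
  m <- detect_funder_mentions(corp, dict)
  m1 <- m[m$record_id == "R1", ]
  expect_equal(nrow(m1), 1)
  expect_equal(m1$entity_group, "institute_bihw")
  expect_equal(nrow(m[m$record_id == "R2", ]), 0)
  expect_equal(m$entity_group[m$record_id == "R3"], "other_cola")
  m4 <- m[m$record_id == "R4", ]
  # longest variant wins: one parent-company mention, no nested bare brand
  expect_equal(sum(m4$source == "funding_text"), 1)
  expect_equal(m4$entity_canonical[m4$source == "funding_text"],
               "The Coca-Cola Company")
  expect_equal(m4$entity_group[m4$source == "agency_strings"], "foundation")
})

test_that("direct-funding classification applies the reason precedence", {
  corp <- tiny_corpus(list(
    tiny_record("S1", "Doe, J.",
                "J.S. has received speaking fees from The Coca-Cola Company."),
    tiny_record("S2", "Doe, J.",
                "This work was supported by a student grant from Coca-Cola."),
    tiny_record("S3", "Doe, J.", "This study was funded by Pepsi-Cola.",
                agency = "Pepsi-Cola"),
    tiny_record("S4", "Doe, J.",
                "This study was funded by the Public Science Fund. Coca-Cola had no role in study design.",
                agency = c("Public Science Fund", "Coca-Cola")),
    tiny_record("S5", "Doe, J.", "This study was funded by Coca-Cola.")
  ))
  m <- detect_funder_mentions(corp, dict)
  d <- classify_direct_funding(corp, m)
  expect_equal(d$reason_code, c("ci_only", "indirect", "other_cola",
                                "indexing_error", "included"))
  expect_equal(d$included, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("brand eligibility keeps any participating mention", {
  corp <- tiny_corpus(list(
    tiny_record("B1", "Doe, J.",
                "Funded by The Coca-Cola Company and Coca-Cola Brasil."),
    tiny_record("B2", "Doe, J.", "Funded by Coca-Cola Hellas."),
    tiny_record("B3", "Doe, J.", "Funded by Coca-Cola France.")
  ))
  m <- detect_funder_mentions(corp, dict)
  d <- classify_direct_funding(corp, m)
  s1 <- build_sample1(corp, d)
  expect_equal(nrow(s1), 3)
  s2 <- build_sample2(s1, m)
  expect_setequal(s2$records$record_id, c("B1", "B3"))
  expect_equal(
    unname(s2$decisions$reason_code[s2$decisions$record_id == "B2"]),
    "subsidiary_nonparticipating")
})

test_that("cohort eligibility applies window, subsidiary and consortium rules", {
  ft <- "This study was funded by The Coca-Cola Company."
  corp <- tiny_corpus(list(
    tiny_record("C1", "Doe, J.", ft, year = 2009L),
    tiny_record("C2", "Doe, J.", ft, year = 2016L, month = 2L),
    tiny_record("C3", "Doe, J.", ft, year = 2015L, month = 12L),
    tiny_record("C4", "Doe, J.", ft, year = 2012L, consortium = TRUE),
    tiny_record("C5", "Doe, J.", "Funded by Coca-Cola Japan.", year = 2012L),
    tiny_record("C6", "Doe, J.", ft, year = 2010L, month = 1L),
    tiny_record("C7", "Doe, J.", ft, year = 2015L)  # no month: year decides
  ))
  m <- detect_funder_mentions(corp, dict)
  co <- build_transparency_cohort(corp, m)
  expect_setequal(co$records$record_id, c("C3", "C6", "C7"))
  reasons <- setNames(co$decisions$reason_code, co$decisions$record_id)
  expect_equal(unname(reasons[c("C1", "C2", "C4", "C5")]),
               c("pre_window", "post_window", "consortium",
                 "subsidiary_nonparticipating"))
})

test_that("investigator restriction drops authors, not records", {
  corp <- tiny_corpus(list(
    tiny_record("P1", c("Blair, Steven", "Hill, James"),
                "Funded by Coca-Cola.", pi = 1L),
    tiny_record("P2", c("Katz, David", "Hand, Gregory"), "Funded by Coca-Cola.")
  ))
  ca <- cohort_authors(corp)
  expect_equal(nrow(ca$persons), 3)
  expect_false("hill|james" %in% ca$persons$person_key)
})

test_that("decisions are record-local: permutation never changes them", {
  sc <- screened_fixture_cached()
  perm <- withr::with_seed(11, sample.int(nrow(sc$pre$records)))
  shuffled <- sc$pre$records[perm, ]
  m2 <- detect_funder_mentions(shuffled, dict)
  d2 <- classify_direct_funding(shuffled, m2)
  orig <- setNames(sc$screen$reason_code, sc$screen$record_id)
  expect_equal(unname(orig[d2$record_id]), d2$reason_code)
})

test_that("re-running a stage on its own output excludes nothing", {
  sc <- screened_fixture_cached()
  m1 <- sc$mentions[sc$mentions$record_id %in% sc$sample1$record_id, ]
  again <- classify_direct_funding(sc$sample1, m1)
  expect_true(all(again$included))
  cohort2 <- build_transparency_cohort(sc$cohort$records, sc$mentions)
  expect_true(all(cohort2$decisions$included))
})

test_that("PRISMA summary enforces conservation and reason tallies", {
  sc <- screened_fixture_cached()
  ledger <- prisma_summary(list(sc$pre$decisions, sc$screen,
                                sc$s2$decisions, sc$cohort$decisions))
  expect_equal(ledger$n_in, ledger$n_included + ledger$n_excluded)
  bad <- sc$screen
  bad$reason_code[!bad$included][1] <- "included"
  expect_error(prisma_summary(list(bad)), "conservation")
  empty <- prisma_summary(list(sc$screen[0, ]))
  expect_equal(empty$n_in, 0)
})
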