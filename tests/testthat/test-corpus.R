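roster <- c("Müller, Jürgen", "García-López, María", "Sievenpiper, J.")

make_full_corpus <- function() {
  r1 <- tiny_record("R1", roster[1:2],
                    funding_text = "This study was funded by The Coca-Cola Company.",
                    year = 2011L, month = 3L,
                    agency = c("Coca-Cola", "National Fund"),
                    corr = 1L)
  r1$authors[[1]]$canonical_id <- c("A1", "A2")
  r2 <- tiny_record("R2", roster[3], year = 2014L, abstract = "energy balance",
                    pi = 1L)
  r3 <- tiny_record("R3", roster[1], funding_text = "", consortium = TRUE)
  tiny_corpus(list(r1, r2, r3))
}

expect_corpus_equal <- function(a, b) {
  expect_equal(a$record_id, b$record_id)
  for (col in c("title", "abstract", "journal", "year", "month",
                "corresponding_author_index", "funding_text",
                "consortium_flag")) {
    expect_equal(a[[col]], b[[col]], label = col)
  }
  expect_equal(a$agency_strings, b$agency_strings)
  for (i in seq_len(nrow(a))) {
    expect_equal(as.data.frame(a$authors[[i]]), as.data.frame(b$authors[[i]]))
    expect_equal(a$pi_indices[[i]], b$pi_indices[[i]])
  }
}

test_that("jsonl round-trip is the identity, diacritics preserved", {
  corp <- make_full_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records(corp, path, "jsonl")
  back <- read_records(path, "jsonl")
  expect_corpus_equal(back, corp)
  expect_true(any(grepl("Müller", back$authors[[1]]$raw)))
  expect_equal(back$funding_text[3], "")
})

test_that("tab_export round-trip returns an equal record list", {
  corp <- make_full_corpus()
  path <- withr::local_tempfile(fileext = ".txt")
  write_records(corp, path, "tab_export")
  back <- read_records(path, "tab_export")
  expect_corpus_equal(back, corp)
  expect_equal(back$authors[[1]]$canonical_id, c("A1", "A2"))
})

test_that("csv dialect keeps documented fields and applies defaults", {
  corp <- make_full_corpus()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(corp, path, "csv")
  back <- read_records(path, "csv")
  expect_equal(back$record_id, corp$record_id)
  expect_equal(back$funding_text, corp$funding_text)
  expect_equal(back$year, corp$year)
  expect_equal(back$authors[[1]]$raw, corp$authors[[1]]$raw)
  # documented lossy fields
  expect_true(all(is.na(back$authors[[1]]$canonical_id)))
  expect_null(back$pi_indices[[2]])
})

test_that("empty record list writes a valid empty file", {
  corp <- make_full_corpus()[0, ]
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records(corp, path, "jsonl")
  back <- read_records(path, "jsonl")
  expect_equal(nrow(back), 0)
})

test_that("malformed rows are rejected with row numbers, not dropped silently", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"record_id":"R1","year":2012,"authors":[{"raw":"Doe, Jane"}]}'
  bad <- '{"year":2012,"authors":[{"raw":"No Id"}]}'
  writeLines(c(good, bad, good2 <- sub("R1", "R2", good)), path)
  expect_warning(back <- read_records(path, "jsonl"), "malformed")
  expect_equal(nrow(back), 2)
  errs <- attr(back, "errors")
  expect_equal(errs$row, 2L)
  expect_match(errs$message, "record_id")
})

test_that("unreadable file is fatal", {
  expect_error(read_records(file.path(tempdir(), "nope.jsonl"), "jsonl"),
               "no such file")
})

test_that("disclosure lists read one entry per row, duplicates retained", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(name_raw = c("Blair, S.", "Hill, J.", "Blair, S.",
                                "Hand, G.", "Katz, D."),
                   source_list = c("USA", "USA", "UK", "USA", "France"))
  write.csv(df, path, row.names = FALSE)
  entries <- read_disclosure_list(path)
  expect_equal(nrow(entries), 5)
  expect_equal(sum(entries$name_raw == "Blair, S."), 2)
  expect_setequal(entries$source_list[entries$name_raw == "Blair, S."],
                  c("USA", "UK"))
})

test_that("disclosure list without a name column is fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(who = "x"), path, row.names = FALSE)
  expect_error(read_disclosure_list(path), "name column")
})

test_that("survey outcomes round-trip and are validated", {
  out <- tibble::tibble(
    author_key = c("a|b", "c|d"),
    outcome = c("denied", "confirmed"),
    named_recipients = list(c("e|f"), character(0))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_outcomes(out, path)
  back <- read_survey_outcomes(path)
  expect_equal(back$author_key, out$author_key)
  expect_equal(back$named_recipients, out$named_recipients)
  bad <- out
  bad$outcome[1] <- "maybe"
  expect_error(fundaudit:::validate_survey_outcomes(bad), "outcome")
  bad2 <- out
  bad2$outcome[1] <- "no_reply"
  expect_error(fundaudit:::validate_survey_outcomes(bad2), "named_recipients")
})
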