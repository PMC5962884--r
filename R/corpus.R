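#' Construct and validate a bibliographic corpus
#'
#' The corpus is a tibble with one row per publication record and the class
#' `biblio_corpus`. Author lists are nested tibbles so that the exact
#' rendering of every name on every publication is preserved; no I/O routine
#' ever trims or re-cases text.
#'
#' Columns: `record_id` (unique key), `title`, `abstract` (may be empty),
#' `journal`, `year` (integer), `month` (integer 1-12 or `NA`), `authors`
#' (list of tibbles with `raw`, `surname`, `given`, `canonical_id`),
#' `corresponding_author_index` (or `NA`), `funding_text` (may be empty),
#' `agency_strings` (list of character), `consortium_flag` (logical),
#' `pi_indices` (list of integer indices of principal investigators, `NULL`
#' when the funding statement does not identify them — the usual case).
#'
#' @param df A data frame with the columns above (missing optional columns
#'   are filled with documented defaults).
#' @param year_window Plausibility window for `year`.
#' @return A validated `biblio_corpus` tibble.
#' @export
biblio_corpus <- function(df, year_window = c(1900L, 2100L)) {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  defaults <- list(
    title = character(n), abstract = character(n), journal = character(n),
    month = rep(NA_integer_, n),
    corresponding_author_index = rep(NA_integer_, n),
    funding_text = character(n),
    agency_strings = replicate(n, character(0), simplify = FALSE),
    consortium_flag = logical(n),
    pi_indices = replicate(n, NULL, simplify = FALSE)
  )
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  req <- c("record_id", "authors")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(paste0("corpus lacks required column(s): ", paste(missing, collapse = ", ")))
  }
  df$record_id <- as.character(df$record_id)
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  df$corresponding_author_index <- as.integer(df$corresponding_author_index)
  if (anyDuplicated(df$record_id)) abort("record_id values are not unique")
  if (any(!is.na(df$year) & (df$year < year_window[1] | df$year > year_window[2]))) {
    abort("year outside the plausible window")
  }
  for (i in seq_len(n)) {
    auth <- df$authors[[i]]
    if (is.null(auth) || nrow(auth) == 0) abort(sprintf("record %s has no authors", df$record_id[i]))
    if (!"canonical_id" %in% names(auth)) auth$canonical_id <- NA_character_
    if (any(!nzchar(auth$raw))) abort(sprintf("record %s has an empty author rendering", df$record_id[i]))
    df$authors[[i]] <- tibble::as_tibble(auth)
    cai <- df$corresponding_author_index[i]
    if (!is.na(cai) && (cai < 1L || cai > nrow(auth))) {
      abort(sprintf("record %s: corresponding_author_index out of range", df$record_id[i]))
    }
  }
  class(df) <- c("biblio_corpus", class(tibble::tibble()))
  df
}

record_to_list <- function(records, i) {
  auth <- records$authors[[i]]
  list(
    record_id = records$record_id[i],
    title = records$title[i],
    abstract = records$abstract[i],
    journal = records$journal[i],
    year = records$year[i],
    month = if (is.na(records$month[i])) NULL else records$month[i],
    authors = lapply(seq_len(nrow(auth)), function(j) {
      a <- list(raw = auth$raw[j], surname = auth$surname[j], given = auth$given[j])
      if (!is.na(auth$canonical_id[j])) a$canonical_id <- auth$canonical_id[j]
      a
    }),
    corresponding_author_index =
      if (is.na(records$corresponding_author_index[i])) NULL
      else records$corresponding_author_index[i],
    funding_text = records$funding_text[i],
    agency_strings = as.list(records$agency_strings[[i]]),
    consortium_flag = records$consortium_flag[i],
    pi_indices = if (is.null(records$pi_indices[[i]])) NULL
      else as.list(records$pi_indices[[i]])
  )
}

list_to_record_row <- function(obj) {
  if (is.null(obj$record_id) || is.null(obj$authors) || length(obj$authors) == 0) {
    abort("record missing record_id or authors")
  }
  authors <- tibble::tibble(
    raw = vapply(obj$authors, function(a) as.character(a$raw %||% ""), character(1)),
    surname = vapply(obj$authors, function(a) as.character(a$surname %||% ""), character(1)),
    given = vapply(obj$authors, function(a) as.character(a$given %||% ""), character(1)),
    canonical_id = vapply(obj$authors, function(a)
      as.character(a$canonical_id %||% NA_character_), character(1))
  )
  tibble::tibble(
    record_id = as.character(obj$record_id),
    title = as.character(obj$title %||% ""),
    abstract = as.character(obj$abstract %||% ""),
    journal = as.character(obj$journal %||% ""),
    year = as.integer(obj$year %||% NA_integer_),
    month = as.integer(obj$month %||% NA_integer_),
    authors = list(authors),
    corresponding_author_index = as.integer(obj$corresponding_author_index %||% NA_integer_),
    funding_text = as.character(obj$funding_text %||% ""),
    agency_strings = list(vapply(obj$agency_strings %||% list(), as.character, character(1))),
    consortium_flag = isTRUE(obj$consortium_flag),
    pi_indices = list(if (is.null(obj$pi_indices)) NULL
      else vapply(obj$pi_indices, as.integer, integer(1)))
  )
}

SEP_MULTI <- "; "

#' Read bibliographic records
#'
#' Three dialects are supported. `jsonl` (one JSON object per line) is
#' lossless. `csv` is lossy by documentation: author renderings are stored as
#' a `"; "`-joined list of `raw` strings (surname/given re-derived by parsing)
#' and `canonical_id`/`pi_indices` are dropped. `tab_export` models a
#' two-line-header, tab-separated bibliographic export with fixed column tags
#' (`UT` id, `AU` authors, `TI` title, `AB` abstract, `SO` journal, `PY`
#' year, `PD` month, `FX` funding text, `FU` agency strings, `RP`
#' corresponding-author index, `CT` consortium flag, `CI` canonical ids,
#' `PI` investigator indices); it round-trips everything [write_records()]
#' emits. Malformed rows are collected in the `errors` attribute (row number
#' and message), never silently dropped.
#'
#' @param path File to read.
#' @param dialect One of `"jsonl"`, `"csv"`, `"tab_export"`.
#' @return A `biblio_corpus`; rejected rows described in `attr(, "errors")`.
#' @export
read_records <- function(path, dialect = c("jsonl", "csv", "tab_export")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("cannot read records: no such file ", path))
  switch(dialect,
    jsonl = read_records_jsonl(path),
    csv = read_records_csv(path),
    tab_export = read_records_tab(path)
  )
}

collect_rows <- function(objs) {
  errors <- tibble::tibble(row = integer(0), message = character(0))
  rows <- list()
  for (i in seq_along(objs)) {
    parsed <- tryCatch(list_to_record_row(objs[[i]]), error = function(e) e)
    if (inherits(parsed, "error")) {
      msg <- conditionMessage(parsed)
      errors <- dplyr::bind_rows(errors, tibble::tibble(row = i, message = msg))
    } else {
      rows[[length(rows) + 1L]] <- parsed
    }
  }
  if (length(rows) == 0) {
    out <- empty_corpus()
  } else {
    out <- biblio_corpus(dplyr::bind_rows(rows))
  }
  attr(out, "errors") <- errors
  if (nrow(errors) > 0) {
    warn(sprintf("%d malformed row(s) rejected; see attr(x, 'errors')", nrow(errors)))
  }
  out
}

empty_corpus <- function() {
  df <- tibble::tibble(
    record_id = character(0), title = character(0), abstract = character(0),
    journal = character(0), year = integer(0), month = integer(0),
    authors = list(), corresponding_author_index = integer(0),
    funding_text = character(0), agency_strings = list(),
    consortium_flag = logical(0), pi_indices = list()
  )
  class(df) <- c("biblio_corpus", class(tibble::tibble()))
  df
}

read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_corpus())
  objs <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
             error = function(e) list())
  })
  collect_rows(objs)
}

authors_to_field <- function(auth) paste(auth$raw, collapse = SEP_MULTI)

field_to_authors <- function(field) {
  raws <- strsplit(field, SEP_MULTI, fixed = TRUE)[[1]]
  lapply(raws, function(r) {
    key <- normalize_name(r)
    list(raw = r, surname = key$surname[1], given = key$given[1])
  })
}

read_records_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  objs <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    list(
      record_id = if (nzchar(r$record_id %||% "")) r$record_id else NULL,
      title = r$title %||% "", abstract = r$abstract %||% "",
      journal = r$journal %||% "",
      year = if (nzchar(r$year %||% "")) as.integer(r$year) else NULL,
      month = if (nzchar(r$month %||% "")) as.integer(r$month) else NULL,
      authors = field_to_authors(r$authors %||% ""),
      corresponding_author_index =
        if (nzchar(r$corresponding_author_index %||% ""))
          as.integer(r$corresponding_author_index) else NULL,
      funding_text = r$funding_text %||% "",
      agency_strings = as.list(split_multi(r$agency_strings %||% "")),
      consortium_flag = identical(r$consortium_flag, "TRUE")
    )
  })
  collect_rows(objs)
}

split_multi <- function(x) {
  if (!nzchar(x)) return(character(0))
  strsplit(x, SEP_MULTI, fixed = TRUE)[[1]]
}

TAB_TAGS <- c("UT", "AU", "TI", "AB", "SO", "PY", "PD", "FX", "FU", "RP",
              "CT", "CI", "PI")

read_records_tab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2 || !startsWith(lines[1], "FN ")) {
    abort("not a tab_export file: missing FN header line")
  }
  tags <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  objs <- lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    length(f) <- length(tags)
    f[is.na(f)] <- ""
    r <- as.list(setNames(f, tags))
    auths <- field_to_authors(r$AU %||% "")
    cids <- split_multi(r$CI %||% "")
    if (length(cids) == length(auths)) {
      for (j in seq_along(auths)) {
        if (nzchar(cids[j]) && cids[j] != ".") auths[[j]]$canonical_id <- cids[j]
      }
    }
    list(
      record_id = if (nzchar(r$UT %||% "")) r$UT else NULL,
      title = r$TI %||% "", abstract = r$AB %||% "", journal = r$SO %||% "",
      year = if (nzchar(r$PY %||% "")) as.integer(r$PY) else NULL,
      month = if (nzchar(r$PD %||% "")) as.integer(r$PD) else NULL,
      authors = auths,
      corresponding_author_index =
        if (nzchar(r$RP %||% "")) as.integer(r$RP) else NULL,
      funding_text = r$FX %||% "",
      agency_strings = as.list(split_multi(r$FU %||% "")),
      consortium_flag = identical(r$CT, "TRUE"),
      pi_indices = if (nzchar(r$PI %||% ""))
        as.list(as.integer(split_multi(r$PI))) else NULL
    )
  })
  collect_rows(objs)
}

#' Write bibliographic records
#'
#' Inverse of [read_records()]; `jsonl` and `tab_export` are lossless,
#' `csv` drops `canonical_id` and `pi_indices` and flattens author renderings
#' to their `raw` strings (documented in [read_records()]).
#'
#' @param records A `biblio_corpus`.
#' @param path Output file.
#' @param dialect One of `"jsonl"`, `"csv"`, `"tab_export"`.
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path, dialect = c("jsonl", "csv", "tab_export")) {
  dialect <- match.arg(dialect)
  n <- nrow(records)
  if (dialect == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    lines <- vapply(seq_len(n), function(i) {
      as.character(jsonlite::toJSON(record_to_list(records, i),
                                    auto_unbox = TRUE, null = "null", digits = NA))
    }, character(1))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  } else if (dialect == "csv") {
    df <- data.frame(
      record_id = records$record_id, title = records$title,
      abstract = records$abstract, journal = records$journal,
      year = records$year, month = records$month,
      authors = vapply(records$authors, authors_to_field, character(1)),
      corresponding_author_index = records$corresponding_author_index,
      funding_text = records$funding_text,
      agency_strings = vapply(records$agency_strings, paste, character(1),
                              collapse = SEP_MULTI),
      consortium_flag = records$consortium_flag,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    header <- c("FN fundaudit tab export 1.0", paste(TAB_TAGS, collapse = "\t"))
    rows <- vapply(seq_len(n), function(i) {
      auth <- records$authors[[i]]
      cids <- ifelse(is.na(auth$canonical_id), ".", auth$canonical_id)
      pi <- records$pi_indices[[i]]
      vals <- c(
        UT = records$record_id[i],
        AU = authors_to_field(auth),
        TI = records$title[i], AB = records$abstract[i],
        SO = records$journal[i],
        PY = ifelse(is.na(records$year[i]), "", as.character(records$year[i])),
        PD = ifelse(is.na(records$month[i]), "", as.character(records$month[i])),
        FX = records$funding_text[i],
        FU = paste(records$agency_strings[[i]], collapse = SEP_MULTI),
        RP = ifelse(is.na(records$corresponding_author_index[i]), "",
                    as.character(records$corresponding_author_index[i])),
        CT = ifelse(records$consortium_flag[i], "TRUE", "FALSE"),
        CI = paste(cids, collapse = SEP_MULTI),
        PI = if (is.null(pi)) "" else paste(pi, collapse = SEP_MULTI)
      )
      paste(vals[TAB_TAGS], collapse = "\t")
    }, character(1))
    writeLines(enc2utf8(c(header, rows)), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a transparency (disclosure) list
#'
#' A disclosure list is a CSV with at least a name column (`name_raw` or
#' `name`); optional columns `source_list` (e.g. a country label) and
#' `person_kind` (`researcher`, `non-academic expert`, `unknown`). Identical
#' names appearing on several source lists are retained as separate entries;
#' deduplication happens in matching, not at I/O.
#'
#' @param path CSV file.
#' @return Tibble with columns `name_raw`, `source_list`, `person_kind`.
#' @export
read_disclosure_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  name_col <- intersect(c("name_raw", "name"), names(df))[1]
  if (is.na(name_col)) abort("disclosure list lacks a name column")
  out <- tibble::tibble(
    name_raw = df[[name_col]],
    source_list = df[["source_list"]] %||% rep("unknown", nrow(df)),
    person_kind = df[["person_kind"]] %||% rep("unknown", nrow(df))
  )
  if (any(!nzchar(out$name_raw))) abort("disclosure list contains empty names")
  out
}

#' Write a disclosure list (CSV)
#' @param entries Tibble as returned by [read_disclosure_list()].
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_disclosure_list <- function(entries, path) {
  utils::write.csv(entries, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write corresponding-author survey outcomes
#'
#' Outcomes CSV columns: `author_key` (normalised name key of a corresponding
#' author), `outcome` (one of `confirmed`, `denied`, `no_reply`,
#' `invalid_address`) and `named_recipients` (`"; "`-joined normalised keys,
#' only ever non-empty for `denied`).
#'
#' @param path CSV file.
#' @return Tibble with those columns (`named_recipients` a list column).
#' @export
read_survey_outcomes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  out <- tibble::tibble(
    author_key = df$author_key,
    outcome = df$outcome,
    named_recipients = lapply(df$named_recipients %||% rep("", nrow(df)), split_multi)
  )
  validate_survey_outcomes(out)
  out
}

validate_survey_outcomes <- function(outcomes) {
  allowed <- c("confirmed", "denied", "no_reply", "invalid_address")
  if (!all(outcomes$outcome %in% allowed)) {
    abort("survey outcome outside {confirmed, denied, no_reply, invalid_address}")
  }
  bad <- lengths(outcomes$named_recipients) > 0 & outcomes$outcome != "denied"
  if (any(bad)) abort("named_recipients only allowed for denied outcomes")
  invisible(outcomes)
}

#' @rdname read_survey_outcomes
#' @param outcomes Tibble of outcomes.
#' @export
write_survey_outcomes <- function(outcomes, path) {
  df <- data.frame(
    author_key = outcomes$author_key,
    outcome = outcomes$outcome,
    named_recipients = vapply(outcomes$named_recipients, paste, character(1),
                              collapse = SEP_MULTI),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
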