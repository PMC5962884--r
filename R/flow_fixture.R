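#' Read and validate a flow specification
#'
#' A flow spec fixes every count the synthetic corpus must realize: total
#' records, the screen exclusion breakdown, the subsidiary and cohort
#' exclusion plans, the author roster structure (matched authors, article
#' split, disclosure-list size, corresponding-author overlap) and the survey
#' outcome plan, plus the generation seed. All cross-constraints are checked
#' before any generation; an inconsistent spec fails with the violated
#' constraint named.
#'
#' @param x Path to a YAML spec or an equivalent list.
#' @return A validated `flow_spec` list.
#' @export
flow_spec <- function(x) {
  spec <- if (is.character(x)) yaml::read_yaml(x) else x
  validate_flow_spec(spec)
}

#' @rdname flow_spec
#' @export
default_flow_spec <- function() {
  flow_spec(system.file("extdata", "prisma2018.yaml", package = "fundaudit",
                        mustWork = TRUE))
}

validate_flow_spec <- function(spec) {
  need <- c("n_total", "seed", "exclusion_plan", "subsidiary_plan",
            "cohort_plan", "roster_plan", "survey_plan")
  missing <- setdiff(need, names(spec))
  if (length(missing) > 0) {
    abort(paste0("flow spec lacks field(s): ", paste(missing, collapse = ", ")))
  }
  ep <- spec$exclusion_plan; cp <- spec$cohort_plan
  rp <- spec$roster_plan; sp <- spec$survey_plan
  counts <- c(unlist(ep), unlist(cp), unlist(rp), unlist(sp),
              spec$subsidiary_plan, spec$n_total)
  if (any(counts < 0)) abort("flow spec constraint violated: negative count")
  n_screen_excl <- sum(unlist(ep[c("ci_only", "indirect", "other_cola",
                                   "indexing_error")]))
  n_sample1 <- spec$subsidiary_plan + cp$pre_window + cp$post_window +
    cp$consortium + rp$matched_articles + rp$unmatched_articles
  if (spec$n_total != n_screen_excl + n_sample1) {
    abort(sprintf("flow spec constraint violated: n_total (%d) != screen exclusions (%d) + Sample 1 (%d)",
                  spec$n_total, n_screen_excl, n_sample1))
  }
  if (rp$unmatched_corresponding > rp$unmatched_articles) {
    abort("flow spec constraint violated: more corresponding authors than unmatched articles")
  }
  if (rp$unmatched_authors < rp$unmatched_corresponding) {
    abort("flow spec constraint violated: unmatched_authors < unmatched_corresponding")
  }
  n_others <- rp$unmatched_authors - rp$unmatched_corresponding
  if (rp$unmatched_articles > 0 && n_others > 3 * rp$unmatched_articles) {
    abort("flow spec constraint violated: too many unmatched authors for the article count")
  }
  if (rp$matched_articles > 0 && rp$matched_extra_authors > 3 * rp$matched_articles) {
    abort("flow spec constraint violated: too many matched-group extra authors")
  }
  if (rp$planted_matches > 0 && rp$matched_articles < rp$planted_matches) {
    abort("flow spec constraint violated: fewer matched-group articles than planted matches")
  }
  if (rp$disclosure_size < rp$planted_matches) {
    abort("flow spec constraint violated: disclosure list smaller than planted matches")
  }
  if (sum(unlist(sp)) != rp$unmatched_corresponding) {
    abort("flow spec constraint violated: survey outcomes do not sum to the corresponding-author count")
  }
  structure(spec, class = "flow_spec")
}

# ---- name pools ------------------------------------------------------------

GIVEN_POOL <- c(
  "Alan", "Beatriz", "Carlos", "Diane", "Erik", "Fiona", "Gareth", "Helena",
  "Ivan", "Joana", "Kevin", "Laura", "Miguel", "Nadia", "Oliver", "Paula",
  "Quentin", "Rachel", "Simon", "Teresa", "Ulrich", "Veronica", "Walter",
  "Ximena", "Yolanda", "Zachary", "Amelia", "Bernard", "Clara", "Dominic",
  "Estela", "Frederik", "Gloria", "Hector", "Irene", "Jorge", "Katrin",
  "Leonard", "Marina", "Nicolas", "Ophelia", "Patric", "Rodrigo", "Sandra",
  "Tobias", "Ursula", "Vicente", "Wilhelm",
  "José", "Jürgen", "María", "François", "Renée",
  "Björn", "Agnès", "Søren", "Zoë", "André",
  "Inés", "Günter"
)

surname_pool <- function(prefixes, suffixes, n) {
  pool <- as.vector(outer(prefixes, suffixes, paste0))
  if (n > length(pool)) abort("surname pool exhausted")
  pool[seq_len(n)]
}

COHORT_PRE <- c("Bar", "Den", "Fel", "Gor", "Hal", "Jin", "Kor", "Lam",
                "Mir", "Nor", "Pel", "Ras", "Sol", "Tur", "Vas", "Wen",
                "Yor", "Zan", "Bren", "Cal", "Dor", "Fen", "Gris", "Hon",
                "Kel", "Lor", "Mon", "Nes", "Pol", "Ril", "Sten")
COHORT_SUF <- c("son", "field", "wick", "ham", "dale", "berg", "ton", "more",
                "ley", "worth", "stein", "mann", "ford", "shaw", "gate",
                "hurst", "combe", "bridge", "wood", "stone", "croft", "mere",
                "by", "thwaite", "ington", "well", "bourne", "chester",
                "don", "mount", "ridge")
BG_PRE <- c("Ard", "Bly", "Crom", "Dray", "Elm", "Frost", "Gild", "Hax",
            "Ingle", "Jasp", "Knott", "Lund", "Marsh", "Nib", "Ost", "Pry",
            "Quill", "Rook", "Sarn", "Tate")
BG_SUF <- c("acre", "bee", "cott", "dew", "fall", "garth", "holt", "ing",
            "kin", "land", "moor", "nock", "over", "pike", "row", "sett",
            "tree", "under", "vale", "wold")
DIST_PRE <- c("Ald", "Bruk", "Czer", "Dvor", "Ekk", "Fyl", "Gnad", "Hrub",
              "Ilk", "Jurk", "Kral", "Lysz", "Mrak", "Novk", "Olsz", "Pilk",
              "Rzep", "Skal", "Tvar", "Ulk")
DIST_SUF <- c("quist", "czak", "opoulos", "ashvili", "awa", "eanu", "ijn",
              "onen", "ovic", "sky", "uuri", "zynski")

canonical_key <- function(surname, given) {
  normalize_name(paste0(surname, ", ", given))$key
}

make_author_registry <- function(n_matched, n_extra_a, n_corr, n_other_b,
                                 n_background) {
  n_cohort <- n_matched + n_extra_a + n_corr + n_other_b
  sur <- surname_pool(COHORT_PRE, COHORT_SUF, n_cohort)
  # every ninth cohort surname is hyphenated; uniqueness of token sets holds
  # because the base surname is unique
  hyph <- seq_len(n_cohort) %% 9L == 0L
  second <- c("Vega", "Ruiz", "Prado", "Mela", "Arta")
  sur[hyph] <- paste0(sur[hyph], "-", second[(which(hyph) %% 5L) + 1L])
  given <- GIVEN_POOL[(seq_len(n_cohort) - 1L) %% length(GIVEN_POOL) + 1L]
  role <- rep(c("matched", "extra_a", "corresponding", "other_b"),
              c(n_matched, n_extra_a, n_corr, n_other_b))
  reg <- tibble::tibble(
    canonical_id = sprintf("A%04d", seq_len(n_cohort)),
    surname = sur, given = given, role = role
  )
  if (n_background > 0) {
    bg <- tibble::tibble(
      canonical_id = sprintf("B%04d", seq_len(n_background)),
      surname = surname_pool(BG_PRE, BG_SUF, n_background),
      given = GIVEN_POOL[(seq_len(n_background) + 7L) %% length(GIVEN_POOL) + 1L],
      role = "background"
    )
    reg <- dplyr::bind_rows(reg, bg)
  }
  reg$key <- canonical_key(reg$surname, reg$given)
  reg
}

applicable_kinds <- function(surname, given) {
  kinds <- c("order_swap")
  if (nchar(strsplit(given, " ")[[1]][1]) > 1) kinds <- c(kinds, "initials")
  if (stringi::stri_trans_general(paste(surname, given), "Latin-ASCII") !=
      paste(surname, given)) kinds <- c(kinds, "diacritic_fold")
  if (grepl("-", surname, fixed = TRUE)) kinds <- c(kinds, "hyphen_split")
  if (nchar(strsplit(given, " ")[[1]][1]) > 4) kinds <- c(kinds, "truncate_given")
  kinds
}

# one rendering of registry row `a`: canonical on first appearance,
# perturbed afterwards (uses the current RNG stream)
render_appearance <- function(a, first) {
  if (first) {
    return(list(raw = paste0(a$surname, ", ", a$given), surname = a$surname,
                given = a$given, canonical_id = a$canonical_id))
  }
  kinds <- applicable_kinds(a$surname, a$given)
  kinds <- sample(kinds, sample(1:2, 1))
  perturb_name(list(raw = paste0(a$surname, ", ", a$given),
                    surname = a$surname, given = a$given,
                    canonical_id = a$canonical_id), kinds)
}

distribute_extras <- function(n_items, n_bins) {
  if (n_bins == 0) return(integer(0))
  base <- n_items %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n_items - base * n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

JOURNAL_POOL <- paste("Journal of", c(
  "Dietary Balance", "Beverage Science", "Active Living", "Metabolic Health",
  "Population Nutrition", "Exercise Medicine", "Sugar Research",
  "Hydration Studies", "Energy Physiology", "Preventive Dietetics",
  "Caloric Epidemiology", "Sports Nutrition", "Public Diet Policy",
  "Weight Dynamics", "Nutrient Metabolism"))

TITLE_WORDS <- c("hydration", "energy balance", "physical activity",
                 "sweetened beverages", "caloric intake", "exercise habits",
                 "weight change", "glucose response", "dietary patterns",
                 "sedentary time")

#' Generate the synthetic flow fixture
#'
#' Builds a full synthetic corpus realizing the given flow specification
#' exactly: screen-failing records use competing-interest-only, indirect,
#' other-cola or indexing-error phrasings from the packaged templates;
#' eligible records are funded by participating or non-participating brand
#' entities as planned; cohort authors are rendered inconsistently across
#' publications (initials, diacritic folds, hyphen splits, order swaps,
#' truncations) so naive string equality under-merges; exactly the planned
#' number of cohort authors also appear, perturbed, on the generated
#' disclosure list, alongside near-miss and unrelated distractor names.
#' Output is deterministic given the spec's seed.
#'
#' @param spec A `flow_spec` (default: the packaged specification).
#' @return List: `records` (a `biblio_corpus`), `disclosure` (tibble),
#'   `survey` (outcome tibble), `truth` (per-record, per-author,
#'   per-disclosure ground-truth labels; see Details in the vignette).
#' @export
generate_flow_fixture <- function(spec = default_flow_spec()) {
  spec <- validate_flow_spec(unclass(spec))
  with_seed(spec$seed, build_flow_fixture(spec))
}

build_flow_fixture <- function(spec) {
  rp <- spec$roster_plan; cp <- spec$cohort_plan; ep <- spec$exclusion_plan
  n_others_b <- rp$unmatched_authors - rp$unmatched_corresponding
  n_noncohort <- spec$n_total - rp$matched_articles - rp$unmatched_articles
  n_background <- min(300L, max(20L, n_noncohort))
  reg <- make_author_registry(rp$planted_matches, rp$matched_extra_authors,
                              rp$unmatched_corresponding, n_others_b,
                              n_background)
  seen <- new.env(parent = emptyenv())
  appear <- function(id) {
    first <- !exists(id, envir = seen)
    assign(id, TRUE, envir = seen)
    first
  }
  render_ids <- function(ids) {
    rows <- lapply(ids, function(id) {
      a <- reg[reg$canonical_id == id, ]
      render_appearance(a, appear(id))
    })
    tibble::tibble(
      raw = vapply(rows, `[[`, character(1), "raw"),
      surname = vapply(rows, `[[`, character(1), "surname"),
      given = vapply(rows, `[[`, character(1), "given"),
      canonical_id = ids
    )
  }

  tmpl <- yaml::read_yaml(system.file("extdata", "funding_templates.yaml",
                                      package = "fundaudit", mustWork = TRUE))
  participating <- c("The Coca-Cola Company", "The Coca-Cola Foundation",
                     "Coca-Cola North America", "Coca-Cola France",
                     "Coca-Cola Germany", "Coca-Cola Australia",
                     "Beverage Institute for Health and Wellness")
  nonparticipating <- c("Coca-Cola Brasil", "Coca-Cola Hellas",
                        "Coca-Cola Japan", "Coca-Cola India",
                        "Coca-Cola China")
  other_colas <- c("Pepsi-Cola", "RC Cola")
  brand_ci <- c("The Coca-Cola Company", "Coca-Cola North America")

  fill <- function(template, entity, extra = list()) {
    out <- gsub("{entity}", entity, template, fixed = TRUE)
    for (nm in names(extra)) {
      out <- gsub(paste0("{", nm, "}"), extra[[nm]], out, fixed = TRUE)
    }
    out
  }
  direct_text <- function(entity) {
    text <- fill(sample(tmpl$direct, 1), entity)
    if (!grepl("cola", fold_chr(entity), fixed = TRUE)) {
      text <- paste(text, "This research programme is part of the Coca-Cola system.")
    }
    text
  }
  in_window_year <- function() sample(2010:2015, 1)
  any_month <- function() sample(1:12, 1)

  rows <- list()
  truth_rows <- list()
  push <- function(row, stratum, reason, funder_group, cohort_group = NA_character_) {
    rows[[length(rows) + 1L]] <<- row
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      ord = length(rows), stratum = stratum, true_reason = reason,
      funder_group = funder_group, cohort_group = cohort_group)
  }
  base_row <- function(authors, year, month, funding_text, agency,
                       consortium = FALSE, corr = 1L, abstract = "") {
    tibble::tibble(
      title = paste("A study of", sample(TITLE_WORDS, 1), "and",
                    sample(TITLE_WORDS, 1)),
      abstract = abstract, journal = sample(JOURNAL_POOL, 1),
      year = as.integer(year), month = as.integer(month),
      authors = list(authors), corresponding_author_index = as.integer(corr),
      funding_text = funding_text, agency_strings = list(agency),
      consortium_flag = consortium, pi_indices = list(NULL)
    )
  }
  dict <- default_entity_dictionary()
  entity_group_of <- function(entity) dict$group[match(entity, dict$canonical)][1]

  # ---- cohort stratum A: articles carrying a planted-match author ----------
  matched_ids <- reg$canonical_id[reg$role == "matched"]
  extra_ids <- reg$canonical_id[reg$role == "extra_a"]
  sizes_a <- distribute_extras(rp$matched_extra_authors, rp$matched_articles)
  taken <- 0L
  for (j in seq_len(rp$matched_articles)) {
    m_id <- matched_ids[(j - 1L) %% max(1L, length(matched_ids)) + 1L]
    n_extra <- sizes_a[j]
    ids <- m_id
    if (n_extra > 0) {
      ids <- c(ids, extra_ids[taken + seq_len(n_extra)])
      taken <- taken + n_extra
    }
    entity <- sample(participating, 1)
    push(base_row(render_ids(ids), in_window_year(), any_month(),
                  direct_text(entity), entity),
         "cohort_matched", "included", entity_group_of(entity), "A")
  }

  # ---- cohort stratum B: the unmatched remainder ---------------------------
  corr_ids <- reg$canonical_id[reg$role == "corresponding"]
  other_ids <- reg$canonical_id[reg$role == "other_b"]
  sizes_b <- distribute_extras(n_others_b, rp$unmatched_articles)
  taken <- 0L
  for (j in seq_len(rp$unmatched_articles)) {
    c_id <- corr_ids[(j - 1L) %% max(1L, length(corr_ids)) + 1L]
    ids <- c_id
    if (sizes_b[j] > 0) {
      ids <- c(ids, other_ids[taken + seq_len(sizes_b[j])])
      taken <- taken + sizes_b[j]
    }
    entity <- sample(participating, 1)
    push(base_row(render_ids(ids), in_window_year(), any_month(),
                  direct_text(entity), entity),
         "cohort_unmatched", "included", entity_group_of(entity), "B")
  }

  # ---- remaining Sample-1 strata -------------------------------------------
  bg_ids <- reg$canonical_id[reg$role == "background"]
  next_bg <- 0L
  bg_authors <- function(n) {
    idx <- (next_bg + seq_len(n) - 1L) %% length(bg_ids) + 1L
    next_bg <<- next_bg + n
    render_ids(bg_ids[idx])
  }
  for (j in seq_len(spec$subsidiary_plan)) {
    entity <- nonparticipating[(j - 1L) %% length(nonparticipating) + 1L]
    push(base_row(bg_authors(sample(1:3, 1)), in_window_year(), any_month(),
                  direct_text(entity), entity),
         "subsidiary", "subsidiary_nonparticipating", entity_group_of(entity))
  }
  for (j in seq_len(cp$pre_window)) {
    entity <- sample(participating, 1)
    push(base_row(bg_authors(sample(1:3, 1)), sample(2008:2009, 1), any_month(),
                  direct_text(entity), entity),
         "pre_window", "pre_window", entity_group_of(entity))
  }
  for (j in seq_len(cp$post_window)) {
    entity <- sample(participating, 1)
    push(base_row(bg_authors(sample(1:3, 1)), 2016L, sample(1:6, 1),
                  direct_text(entity), entity),
         "post_window", "post_window", entity_group_of(entity))
  }
  for (j in seq_len(cp$consortium)) {
    entity <- sample(participating, 1)
    push(base_row(bg_authors(sample(2:4, 1)), in_window_year(), any_month(),
                  direct_text(entity), entity, consortium = TRUE),
         "consortium", "consortium", entity_group_of(entity))
  }

  # ---- screen-excluded strata ----------------------------------------------
  rand_initials <- function() {
    paste0(sample(LETTERS, 1), ".", sample(LETTERS, 1), ".")
  }
  for (j in seq_len(ep$ci_only)) {
    entity <- sample(brand_ci, 1)
    text <- fill(sample(tmpl$ci_only, 1), entity,
                 list(initials = rand_initials()))
    push(base_row(bg_authors(sample(1:3, 1)), sample(2008:2016, 1), any_month(),
                  text, character(0)),
         "screen_ci", "ci_only", entity_group_of(entity))
  }
  for (j in seq_len(ep$indirect)) {
    entity <- sample(brand_ci, 1)
    text <- fill(sample(tmpl$indirect, 1), entity)
    push(base_row(bg_authors(sample(1:3, 1)), sample(2008:2016, 1), any_month(),
                  text, character(0)),
         "screen_indirect", "indirect", entity_group_of(entity))
  }
  for (j in seq_len(ep$other_cola)) {
    entity <- other_colas[(j - 1L) %% length(other_colas) + 1L]
    text <- fill(sample(tmpl$direct, 1), entity)
    push(base_row(bg_authors(sample(1:3, 1)), sample(2008:2016, 1), any_month(),
                  text, entity),
         "screen_other_cola", "other_cola", "other_cola")
  }
  for (j in seq_len(ep$indexing_error)) {
    entity <- "Coca-Cola"
    text <- fill(sample(tmpl$indexing_error, 1), entity,
                 list(other = sample(tmpl$other_funders, 1)))
    push(base_row(bg_authors(sample(1:3, 1)), sample(2008:2016, 1), any_month(),
                  text, c(sample(tmpl$other_funders, 1), "Coca-Cola")),
         "screen_indexing", "indexing_error", "parent_company")
  }

  records <- dplyr::bind_rows(rows)
  truth_records <- dplyr::bind_rows(truth_rows)

  # shuffle record order; ids assigned in shuffled order so order carries no
  # information about the stratum
  perm <- sample.int(nrow(records))
  records <- records[perm, ]
  truth_records <- truth_records[perm, ]
  records$record_id <- sprintf("WOS%06d", seq_len(nrow(records)))
  truth_records$record_id <- records$record_id
  truth_records$ord <- NULL
  records <- biblio_corpus(records[, c("record_id", setdiff(names(records), "record_id"))])

  # abstracts from a small mixture-of-topics process
  abs_corpus <- generate_topic_corpus(nrow(records), k_true = 4,
                                      vocab_size = 120, doc_length = 60,
                                      concentration = 0.15,
                                      seed = spec$seed %% 1000000L + 11L)
  records$abstract <- abs_corpus$abstracts

  # ---- disclosure list ------------------------------------------------------
  disclosure <- build_disclosure(reg, rp, spec)

  # ---- survey outcomes ------------------------------------------------------
  survey <- build_survey(reg, spec, truth_records, records)

  truth <- list(
    records = truth_records,
    authors = reg,
    disclosure = disclosure$truth,
    survey_keys = survey$keys,
    n_cohort_components = cohort_component_count(records, truth_records),
    planted_matches = rp$planted_matches,
    n_disclosure = nrow(disclosure$entries)
  )
  list(records = records, disclosure = disclosure$entries,
       survey = survey$outcomes, truth = truth)
}

mutate_surname <- function(s, forbidden) {
  body <- substr(s, 1, max(1, nchar(s) - 2))
  out <- paste0(body, "vx")
  while (fold_chr(out) %in% forbidden) out <- paste0(out, "x")
  out
}

build_disclosure <- function(reg, rp, spec) {
  n_plant <- rp$planted_matches
  n_dist <- rp$disclosure_size - n_plant
  source_pool <- c("USA", "UK", "Australia", "France", "Germany")
  rows <- list()
  truth <- list()
  matched <- reg[reg$role == "matched", ]
  for (i in seq_len(n_plant)) {
    a <- matched[i, ]
    kinds <- intersect(applicable_kinds(a$surname, a$given),
                       c("initials", "diacritic_fold", "hyphen_split",
                         "truncate_given"))
    kinds <- if (length(kinds) > 0) sample(kinds, 1) else character(0)
    r <- perturb_name(list(raw = paste0(a$surname, ", ", a$given),
                           surname = a$surname, given = a$given,
                           canonical_id = a$canonical_id), kinds)
    name_raw <- if (stats::runif(1) < 0.5 && !grepl(" ", r$surname, fixed = TRUE)) {
      paste(r$given, r$surname)
    } else {
      paste0(r$surname, ", ", r$given)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name_raw = name_raw,
      source_list = source_pool[(i - 1L) %% length(source_pool) + 1L],
      person_kind = "researcher")
    truth[[length(truth) + 1L]] <- tibble::tibble(
      name_raw = name_raw, canonical_id = a$canonical_id)
  }
  # distractors: near-miss surnames (>= 2 edits from a real cohort surname,
  # incompatible initials) plus unrelated names from a disjoint pool
  cohort_sur_folded <- fold_chr(reg$surname[reg$role != "background"])
  n_near <- min(60L, n_dist)
  unmatched_cohort <- reg[reg$role %in% c("extra_a", "other_b"), ]
  for (i in seq_len(n_near) ) {
    a <- unmatched_cohort[(i - 1L) %% max(1L, nrow(unmatched_cohort)) + 1L, ]
    sur <- mutate_surname(a$surname, cohort_sur_folded)
    giv <- GIVEN_POOL[which(substr(GIVEN_POOL, 1, 1) != substr(a$given, 1, 1))[1]]
    name_raw <- paste0(sur, ", ", giv)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name_raw = name_raw,
      source_list = sample(source_pool, 1),
      person_kind = "researcher")
    truth[[length(truth) + 1L]] <- tibble::tibble(
      name_raw = name_raw, canonical_id = NA_character_)
  }
  n_far <- n_dist - n_near
  if (n_far > 0) {
    sur <- surname_pool(DIST_PRE, DIST_SUF, n_far)
    for (i in seq_len(n_far)) {
      giv <- GIVEN_POOL[(i + 3L) %% length(GIVEN_POOL) + 1L]
      name_raw <- paste0(sur[i], ", ", giv)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name_raw = name_raw,
        source_list = sample(source_pool, 1),
        person_kind = sample(c("researcher", "non-academic expert"), 1,
                             prob = c(0.7, 0.3)))
      truth[[length(truth) + 1L]] <- tibble::tibble(
        name_raw = name_raw, canonical_id = NA_character_)
    }
  }
  entries <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truth)
  if (nrow(entries) > 0) {
    perm <- sample.int(nrow(entries))
    entries <- entries[perm, ]
    truth <- truth[perm, ]
  }
  list(entries = entries, truth = truth)
}

build_survey <- function(reg, spec, truth_records, records) {
  sp <- spec$survey_plan
  corr <- reg[reg$role == "corresponding", ]
  n <- nrow(corr)
  outcome <- rep(c("confirmed", "denied", "no_reply", "invalid_address"),
                 c(sp$confirmed, sp$denied, sp$no_reply, sp$invalid_address))
  keys <- corr$key
  named <- replicate(n, character(0), simplify = FALSE)
  # a handful of deniers name the true grant recipient: a co-author on one of
  # their articles
  denier_idx <- which(outcome == "denied")
  b_ids <- truth_records$record_id[truth_records$cohort_group %in% "B"]
  for (d in utils::head(denier_idx, 5)) {
    rec <- find_first_record(records, b_ids, corr$canonical_id[d])
    if (!is.na(rec)) {
      auth <- records$authors[[match(rec, records$record_id)]]
      co <- auth$canonical_id[auth$canonical_id != corr$canonical_id[d]]
      if (length(co) > 0) {
        named[[d]] <- reg$key[match(co[1], reg$canonical_id)]
      }
    }
  }
  outcomes <- tibble::tibble(author_key = keys, outcome = outcome,
                             named_recipients = named)
  perm <- sample.int(n)
  outcomes <- outcomes[perm, ]
  list(outcomes = outcomes, keys = setNames(corr$key, corr$canonical_id))
}

find_first_record <- function(records, candidate_ids, canonical_id) {
  for (id in candidate_ids) {
    auth <- records$authors[[match(id, records$record_id)]]
    if (canonical_id %in% auth$canonical_id) return(id)
  }
  NA_character_
}

# true number of connected components of the cohort co-authorship graph,
# computed by union-find over canonical ids (independently of igraph)
cohort_component_count <- function(records, truth_records) {
  cohort_ids <- truth_records$record_id[!is.na(truth_records$cohort_group)]
  ids <- unique(unlist(lapply(cohort_ids, function(id) {
    records$authors[[match(id, records$record_id)]]$canonical_id
  })))
  if (length(ids) == 0) return(0L)
  parent <- uf_new(length(ids))
  for (id in cohort_ids) {
    a <- records$authors[[match(id, records$record_id)]]$canonical_id
    idx <- match(a, ids)
    for (i in seq_along(idx)[-1]) parent <- uf_union(parent, idx[1], idx[i])
  }
  max(uf_labels(parent))
}
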