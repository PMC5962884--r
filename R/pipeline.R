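#' Validate a pipeline configuration
#'
#' The configuration drives [run_pipeline()]: input paths, stage toggles,
#' thresholds, the cohort window, topic-model settings, the seed, and the
#' output directory. Referenced files must exist at validation time.
#'
#' @param x Path to a YAML configuration or an equivalent list.
#' @return A validated `pipeline_config` list (defaults filled in).
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    dialect = "jsonl",
    needle = "cola",
    window = c("2010-01", "2015-12"),
    match_threshold = 0.90,
    review_band = 0.80,
    match_policy = "strict",
    topics_k = 20L,
    topics_iterations = 400L,
    topics_burn_in = 150L,
    seed = 1L,
    stages = list(screen = TRUE, match = TRUE, network = TRUE, topics = TRUE)
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$stages)) {
    if (is.null(cfg$stages[[nm]])) cfg$stages[[nm]] <- defaults$stages[[nm]]
  }
  if (is.null(cfg$corpus)) abort("config lacks 'corpus' input path")
  if (is.null(cfg$output_dir)) abort("config lacks 'output_dir'")
  needed <- c(cfg$corpus,
              if (isTRUE(cfg$stages$match)) cfg$disclosure,
              if (isTRUE(cfg$stages$match) && !is.null(cfg$survey)) cfg$survey,
              if (!is.null(cfg$entity_dictionary)) cfg$entity_dictionary)
  if (isTRUE(cfg$stages$match) && is.null(cfg$disclosure)) {
    abort("matching enabled but no 'disclosure' path configured")
  }
  for (p in needed) {
    if (!file.exists(p)) abort(paste0("configured input does not exist: ", p))
  }
  structure(cfg, class = "pipeline_config")
}

# hash of the analytic parameters only: where outputs land does not change
# what was computed
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  rlang::hash(cfg[setdiff(names(cfg), "output_dir")])
}

provenance_header <- function(cfg) {
  sprintf("# fundaudit run: config %s, seed %d", config_hash(cfg), cfg$seed)
}

write_with_provenance <- function(lines, path, cfg) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(provenance_header(cfg), lines)), con, useBytes = TRUE)
  invisible(path)
}

#' Run the full audit pipeline
#'
#' Chains prefilter, direct-funding screen, Sample 1/2 construction, cohort
#' construction, disclosure matching, survey adjustment, co-authorship
#' network analysis and topic modelling, honouring the stage toggles, and
#' writes every stage's artifacts (CSV/JSON/GraphML) into the configured
#' output directory. Every output embeds the configuration hash and seed.
#'
#' @param config A `pipeline_config` (or a path/list coercible to one).
#' @return Invisibly, a list of in-memory stage results (also the artifact
#'   directory path in `$output_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    inform(msg)
  }
  out <- list(output_dir = cfg$output_dir, config = cfg)
  logf("reading corpus %s (%s)", cfg$corpus, cfg$dialect)
  records <- read_records(cfg$corpus, cfg$dialect)
  dict <- if (is.null(cfg$entity_dictionary)) default_entity_dictionary()
          else read_entity_dictionary(cfg$entity_dictionary)

  if (!isTRUE(cfg$stages$screen)) return(invisible(out))
  logf("screening %d records", nrow(records))
  pre <- prefilter_by_substring(records, cfg$needle)
  mentions <- detect_funder_mentions(pre$records, dict)
  screen <- classify_direct_funding(pre$records, mentions)
  sample1 <- build_sample1(pre$records, screen)
  s2 <- build_sample2(sample1, mentions)
  cohort <- build_transparency_cohort(sample1, mentions, window = cfg$window)
  ledger <- prisma_summary(list(pre$decisions, screen, s2$decisions,
                                cohort$decisions))
  export_prisma(ledger, file.path(cfg$output_dir, "prisma.csv"), "csv")
  export_prisma(ledger, file.path(cfg$output_dir, "prisma.json"), "json")
  write_with_provenance(utils::capture.output(print(ledger)),
                        file.path(cfg$output_dir, "prisma.txt"), cfg)
  out$ledger <- ledger
  out$sample1 <- sample1
  out$sample2 <- s2$records
  out$cohort <- cohort$records

  matches <- NULL
  coh <- NULL
  if (isTRUE(cfg$stages$match)) {
    logf("matching cohort authors against %s", cfg$disclosure)
    disclosure <- read_disclosure_list(cfg$disclosure)
    coh <- cohort_authors(cohort$records)
    matches <- match_author_lists(coh$persons, disclosure,
                                  threshold = cfg$match_threshold,
                                  review_band = cfg$review_band,
                                  policy = cfg$match_policy)
    utils::write.csv(as.data.frame(matches),
                     file.path(cfg$output_dir, "matches.csv"), row.names = FALSE)
    coverage <- coverage_metrics(matches, coh$persons, disclosure,
                                 cohort_records = cohort$records)
    jsonlite::write_json(
      c(unclass(coverage)[c("n_cohort_authors", "n_disclosure_names",
                            "n_matched", "pct_of_disclosure", "pct_of_cohort")],
        list(unmatched_author_articles = coverage$unmatched_author_articles,
             config = config_hash(cfg), seed = cfg$seed)),
      file.path(cfg$output_dir, "coverage.json"), auto_unbox = TRUE, digits = NA)
    out$matches <- matches
    out$coverage <- coverage
    if (!is.null(cfg$survey)) {
      outcomes <- read_survey_outcomes(cfg$survey)
      rem <- remove_matched_publications(cohort$records, matches, tab = coh$table)
      adj <- apply_survey_adjustments(rem, outcomes)
      tal <- survey_tally(outcomes)
      utils::write.csv(as.data.frame(tal),
                       file.path(cfg$output_dir, "survey_tally.csv"),
                       row.names = FALSE)
      out$remainder <- rem
      out$adjusted <- adj
      out$survey_tally <- tal
    }
  }

  if (isTRUE(cfg$stages$network)) {
    logf("building co-authorship network on Sample 1")
    status <- NULL
    if (!is.null(matches)) {
      acc <- matches[matches$review_status == "auto_accepted", ]
      s2_tab <- author_table(s2$records)
      status <- setNames(rep("unlisted_subsidiary",
                             length(unique(author_table(sample1)$person_key))),
                         unique(author_table(sample1)$person_key))
      status[unique(s2_tab$person_key)] <- "unlisted_participating"
      status[acc$author_key] <- "on_list"
    }
    graph <- build_coauthor_graph(sample1, node_status = status)
    partition <- girvan_newman_partition(graph)
    export_graph(graph, file.path(cfg$output_dir, "coauthors.graphml"),
                 partition = partition, format = "graphml")
    part_df <- data.frame(
      node = names(partition$assignment),
      community = unname(partition$assignment),
      degree = unname(degree_centrality(graph)[names(partition$assignment)]),
      betweenness = unname(betweenness_centrality(graph)[names(partition$assignment)])
    )
    utils::write.csv(part_df, file.path(cfg$output_dir, "communities.csv"),
                     row.names = FALSE)
    out$graph <- graph
    out$partition <- partition
    net_stats <- list(
      nodes = igraph::vcount(graph), edges = igraph::ecount(graph),
      total_tie_weight = sum(igraph::E(graph)$weight),
      components = max(c(0L, graph_components(graph))),
      communities = max(partition$assignment),
      modularity = partition$quality,
      config = config_hash(cfg), seed = cfg$seed)
    jsonlite::write_json(net_stats, file.path(cfg$output_dir, "network.json"),
                         auto_unbox = TRUE, digits = NA)
    out$network_stats <- net_stats
  }

  if (isTRUE(cfg$stages$topics)) {
    basis <- if (!is.null(out$sample2)) out$sample2 else records
    logf("topic modelling %d abstracts (k = %d)", nrow(basis), cfg$topics_k)
    prep <- preprocess_abstracts(basis)
    model <- fit_topic_model(prep, k = cfg$topics_k,
                             iterations = cfg$topics_iterations,
                             burn_in = cfg$topics_burn_in, seed = cfg$seed)
    assignments <- dominant_topic_assignment(model)
    summary <- topic_summary(model, assignments)
    summary_df <- data.frame(
      topic = summary$topic, n_docs = summary$n_docs,
      share_pct = summary$share_pct, mean_ratio = summary$mean_ratio,
      top_terms = vapply(summary$top_terms,
                         function(t) paste(names(t), collapse = " "),
                         character(1)))
    utils::write.csv(summary_df, file.path(cfg$output_dir, "topics.csv"),
                     row.names = FALSE)
    export_topic_model(model, file.path(cfg$output_dir, "topic_model"))
    out$topic_model <- model
    out$topic_summary <- summary
  }
  logf("pipeline complete; artifacts in %s", cfg$output_dir)
  invisible(out)
}

#' Render a human-readable summary of pipeline artifacts
#'
#' Collates the PRISMA table, coverage report, network headline statistics
#' and topic table from an artifact directory into one text summary. Missing
#' artifacts cause their section to be skipped with a warning, not an error.
#'
#' @param dir Artifact directory written by [run_pipeline()].
#' @param path Optional file to write the summary to.
#' @return The summary, invisibly, as a character vector of lines.
#' @export
render_reports <- function(dir, path = NULL) {
  lines <- c("== fundaudit report ==", "")
  section <- function(file, title, render) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      warn(paste0("artifact missing, section skipped: ", file))
      return(character(0))
    }
    c(paste0("-- ", title, " --"), render(p), "")
  }
  lines <- c(lines, section("prisma.csv", "Screening flow", function(p) {
    df <- utils::read.csv(p)
    sprintf("%-24s %5d -> %5d (excluded %d)", df$stage, df$n_in,
            df$n_included, df$n_excluded)
  }))
  lines <- c(lines, section("coverage.json", "Disclosure coverage", function(p) {
    cov <- jsonlite::read_json(p)
    out <- sprintf("matched %d of %d disclosure names (%.1f%%); %.1f%% of %d cohort authors",
                   cov$n_matched, cov$n_disclosure_names, cov$pct_of_disclosure,
                   cov$pct_of_cohort, cov$n_cohort_authors)
    if (!is.null(cov$unmatched_author_articles)) {
      out <- c(out, sprintf("unmatched remainder: %d authors on %d articles",
                            cov$unmatched_author_articles$n_authors,
                            cov$unmatched_author_articles$n_articles))
    }
    out
  }))
  lines <- c(lines, section("survey_tally.csv", "Survey outcomes", function(p) {
    df <- utils::read.csv(p)
    sprintf("%-16s %4d (%d%%)", df$outcome, df$n, df$pct)
  }))
  lines <- c(lines, section("network.json", "Co-authorship network", function(p) {
    net <- jsonlite::read_json(p)
    sprintf("nodes %d, edges %d, components %d, communities %d, modularity %.4f",
            net$nodes, net$edges, net$components, net$communities,
            net$modularity)
  }))
  lines <- c(lines, section("topics.csv", "Topics", function(p) {
    df <- utils::read.csv(p)
    sprintf("topic %2d: %5.1f%% of docs, mean dominance %.2f | %s",
            df$topic, df$share_pct, df$mean_ratio, df$top_terms)
  }))
  if (!is.null(path)) {
    con <- file(path, "wb")
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
    close(con)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
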