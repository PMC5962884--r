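#' Tokenise and stem abstracts for topic modelling
#'
#' Lower-cases, strips punctuation and numbers, removes stopwords, applies
#' the Porter stemmer, and prunes the vocabulary by document-frequency
#' bounds. Records with empty abstracts (or abstracts reduced to nothing by
#' preprocessing) are dropped with a log entry in the `dropped` attribute.
#'
#' @param x A `biblio_corpus` (abstracts taken from the `abstract` column)
#'   or a character vector of documents.
#' @param stopwords Stopword list; default [stop_words_en()].
#' @param stem Apply the Porter stemmer.
#' @param min_df Minimum number of documents a term must occur in.
#' @param max_df_prop Maximum fraction of documents a term may occur in.
#' @return List: `tokens` (list of character vectors of stems), `vocabulary`
#'   (sorted), `doc_ids`; dropped document ids in `attr(, "dropped")`.
#' @export
preprocess_abstracts <- function(x, stopwords = stop_words_en(), stem = TRUE,
                                 min_df = 1L, max_df_prop = 1.0) {
  if (inherits(x, "biblio_corpus") || is.data.frame(x)) {
    docs <- x$abstract
    ids <- x$record_id
  } else {
    docs <- as.character(x)
    ids <- as.character(seq_along(docs))
  }
  tokens <- lapply(docs, function(d) {
    d <- fold_chr(d)
    d <- stringr::str_replace_all(d, "[^a-z]+", " ")
    toks <- strsplit(stringr::str_squish(d), " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks) & !(toks %in% stopwords) & nchar(toks) > 1]
    if (stem) toks <- porter_stem(toks)
    toks
  })
  keep <- lengths(tokens) > 0
  dropped <- ids[!keep]
  if (length(dropped) > 0) {
    inform(sprintf("dropped %d document(s) with empty abstracts after preprocessing",
                   length(dropped)))
  }
  tokens <- tokens[keep]
  ids <- ids[keep]
  if (length(tokens) == 0) abort("all abstracts empty after preprocessing")
  df_count <- table(unlist(lapply(tokens, unique)))
  n_docs <- length(tokens)
  vocab <- names(df_count)[df_count >= min_df & df_count <= max_df_prop * n_docs]
  vocab <- sort(vocab)
  tokens <- lapply(tokens, function(t) t[t %in% vocab])
  out <- list(tokens = tokens, vocabulary = vocab, doc_ids = ids)
  attr(out, "dropped") <- dropped
  out
}

#' Fit a latent topic model by collapsed Gibbs sampling
#'
#' The standard mixture-of-topics model: each document draws topic weights
#' from a symmetric Dirichlet (concentration `alpha`), each topic a word
#' distribution from a symmetric Dirichlet (concentration `beta`); words are
#' drawn topic-wise. Estimation is collapsed Gibbs sampling; the returned
#' probability tables are posterior means averaged over the post-burn-in
#' sweeps. Runs are deterministic given `seed`.
#'
#' @param corpus Output of [preprocess_abstracts()] (or any list with
#'   `tokens` and `vocabulary`).
#' @param k Number of topics (at least 2).
#' @param alpha Document-topic concentration; default `50 / k`, the common
#'   exploratory choice. For recovery studies on synthetic corpora use a
#'   value matched to the generating concentration.
#' @param beta Topic-word concentration.
#' @param iterations,burn_in Gibbs sweeps and burn-in sweeps.
#' @param seed Integer seed.
#' @return A `topic_model`: `k`, `word_topic` (k x V, rows sum to 1),
#'   `doc_topic` (D x k, rows sum to 1), `vocabulary`, `doc_ids`, `seed`,
#'   `sampler_state` (iterations, burn-in, hyperparameters, samples kept).
#' @export
fit_topic_model <- function(corpus, k, alpha = 50 / k, beta = 0.01,
                            iterations = 2000L, burn_in = 500L, seed = 1L) {
  if (k < 2) abort("k must be at least 2")
  vocab <- corpus$vocabulary
  if (length(vocab) < 2) abort("vocabulary smaller than 2")
  if (length(corpus$tokens) < k) abort("need at least k documents")
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  docs <- lapply(corpus$tokens, function(t) match(t, vocab) - 1L)
  fit <- with_seed(seed, gibbs_lda_cpp(docs, as.integer(k), length(vocab),
                                       alpha, beta, as.integer(iterations),
                                       as.integer(burn_in)))
  dimnames(fit$phi) <- list(paste0("topic", seq_len(k)), vocab)
  dimnames(fit$theta) <- list(corpus$doc_ids %||% seq_along(docs),
                              paste0("topic", seq_len(k)))
  structure(list(
    k = as.integer(k), word_topic = fit$phi, doc_topic = fit$theta,
    vocabulary = vocab, doc_ids = rownames(fit$theta), seed = seed,
    sampler_state = list(iterations = iterations, burn_in = burn_in,
                         alpha = alpha, beta = beta,
                         n_samples = fit$n_samples)
  ), class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic model: k = %d, %d documents, vocabulary %d, %d Gibbs samples\n",
              x$k, nrow(x$doc_topic), length(x$vocabulary),
              x$sampler_state$n_samples))
  invisible(x)
}

#' Dominant topic per document, with dominance ratio
#'
#' The dominant topic is the argmax of a document's topic weights; the
#' dominance ratio is the top weight divided by the second weight (at least
#' 1 by construction). Ties go to the lowest topic id with ratio 1.
#'
#' @param model A `topic_model`.
#' @return Tibble: `doc_id`, `topic` (integer), `ratio`.
#' @export
dominant_topic_assignment <- function(model) {
  theta <- model$doc_topic
  if (ncol(theta) < 2) abort("need at least 2 topics")
  top <- apply(theta, 1, which.max)
  ratio <- vapply(seq_len(nrow(theta)), function(i) {
    w <- sort(theta[i, ], decreasing = TRUE)
    w[1] / w[2]
  }, numeric(1))
  tibble::tibble(doc_id = rownames(theta), topic = as.integer(top),
                 ratio = ratio)
}

#' Per-topic summary: document shares, mean dominance, top stems
#'
#' For each topic: the share of documents whose dominant topic it is (in
#' percent; shares sum to 100 up to rounding), the mean dominance ratio over
#' those documents, and the `n_top` most probable word stems.
#'
#' @param model A `topic_model`.
#' @param assignments Output of [dominant_topic_assignment()].
#' @param n_top Number of top stems to report (7 for a figure-style table,
#'   20 for a supplementary-style table).
#' @return Tibble: `topic`, `n_docs`, `share_pct`, `mean_ratio`,
#'   `top_terms` (list column of named probability vectors).
#' @export
topic_summary <- function(model, assignments = dominant_topic_assignment(model),
                          n_top = 7L) {
  n_docs_total <- nrow(model$doc_topic)
  purrr::map_dfr(seq_len(model$k), function(t) {
    docs <- assignments[assignments$topic == t, ]
    phi <- model$word_topic[t, ]
    top <- sort(phi, decreasing = TRUE)[seq_len(min(n_top, length(phi)))]
    tibble::tibble(
      topic = t,
      n_docs = nrow(docs),
      share_pct = round(100 * nrow(docs) / n_docs_total, 1),
      mean_ratio = if (nrow(docs) > 0) mean(docs$ratio) else NA_real_,
      top_terms = list(top)
    )
  })
}

#' Export topic-model tables as CSV
#'
#' @param model A `topic_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_topic_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- file.path(dir, "word_topic.csv")
  dt <- file.path(dir, "doc_topic.csv")
  utils::write.csv(as.data.frame(model$word_topic), wt)
  utils::write.csv(as.data.frame(model$doc_topic), dt)
  invisible(c(wt, dt))
}
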