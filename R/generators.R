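#' Perturb an author rendering
#'
#' Produces an alternative printed rendering of the same canonical person,
#' of the kinds publications actually exhibit: given names reduced to
#' initials, diacritics folded, hyphenated surnames split, name order
#' swapped, given names truncated. The canonical identity never changes.
#' If the requested kinds leave the rendering unchanged (e.g. folding an
#' ASCII-only name), a fallback kind is applied so a non-empty request
#' always yields a different rendering.
#'
#' @param name A one-row author rendering (list or tibble row with `raw`,
#'   `surname`, `given`, `canonical_id`).
#' @param kinds Subset of `c("initials", "diacritic_fold", "hyphen_split",
#'   "order_swap", "truncate_given")`.
#' @param seed Integer; perturbation is deterministic given `seed` (kept for
#'   interface symmetry - the kinds fully determine the result).
#' @return A rendering of the same shape with the same `canonical_id`.
#' @export
perturb_name <- function(name, kinds = character(0), seed = 1L) {
  allowed <- c("initials", "diacritic_fold", "hyphen_split", "order_swap",
               "truncate_given")
  bad <- setdiff(kinds, allowed)
  if (length(bad) > 0) abort(paste0("unknown perturbation kind: ", paste(bad, collapse = ", ")))
  out <- apply_perturbations(name$surname, name$given, kinds)
  if (length(kinds) > 0 && out$raw == name$raw) {
    fallback <- if (!"initials" %in% kinds && nchar(name$given) > 2) "initials"
                else "order_swap"
    out <- apply_perturbations(name$surname, name$given, union(kinds, fallback))
  }
  list(raw = out$raw, surname = out$surname, given = out$given,
       canonical_id = name$canonical_id %||% NA_character_)
}

apply_perturbations <- function(surname, given, kinds) {
  if ("diacritic_fold" %in% kinds) {
    surname <- stringi::stri_trans_general(surname, "Latin-ASCII")
    given <- stringi::stri_trans_general(given, "Latin-ASCII")
  }
  if ("hyphen_split" %in% kinds) surname <- gsub("-", " ", surname, fixed = TRUE)
  if ("truncate_given" %in% kinds) {
    toks <- strsplit(given, " ", fixed = TRUE)[[1]]
    if (length(toks) > 0 && nchar(toks[1]) > 4) toks[1] <- substr(toks[1], 1, 4)
    given <- paste(toks, collapse = " ")
  }
  if ("initials" %in% kinds) {
    toks <- strsplit(given, " ", fixed = TRUE)[[1]]
    given <- paste(paste0(substr(toks, 1, 1), "."), collapse = " ")
  }
  # the swapped "Given Surname" form is only unambiguous for single-token
  # surnames; a split hyphenated surname keeps the comma form
  raw <- if ("order_swap" %in% kinds && !grepl(" ", surname, fixed = TRUE)) {
    paste(given, surname)
  } else {
    paste0(surname, ", ", given)
  }
  list(raw = raw, surname = surname, given = given)
}

#' Generate a synthetic topic-mixture corpus
#'
#' Documents drawn from the standard mixture-of-topics generative process:
#' per-document topic weights from a symmetric Dirichlet with the given
#' concentration, words drawn topic-wise from per-topic word distributions.
#' The vocabulary is partitioned into `k_true` blocks; each topic places
#' mass `1 - leak` uniformly on its own block and `leak` uniformly on the
#' whole vocabulary, so `leak = 0` gives fully separable topics.
#'
#' @param n_docs,k_true,vocab_size,doc_length Corpus dimensions.
#' @param concentration Symmetric Dirichlet concentration for document
#'   weights.
#' @param leak Off-block probability mass per topic.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List: `abstracts` (documents as space-joined words), `tokens`
#'   (list of word vectors), `vocabulary`, `truth` (list with `doc_topic`
#'   weights used, `word_topic` distributions, `k_true`).
#' @export
generate_topic_corpus <- function(n_docs, k_true, vocab_size, doc_length,
                                  concentration = 0.1, leak = 0, seed = 1L) {
  if (k_true < 2) abort("k_true must be at least 2")
  if (doc_length < 1) abort("doc_length must be positive")
  if (vocab_size < k_true) abort("vocab_size must be at least k_true")
  vocab <- synthetic_vocab(vocab_size)
  block <- sort(rep(seq_len(k_true), length.out = vocab_size))
  phi <- matrix(0, k_true, vocab_size, dimnames = list(NULL, vocab))
  for (t in seq_len(k_true)) {
    own <- block == t
    phi[t, own] <- (1 - leak) / sum(own)
    phi[t, ] <- phi[t, ] + leak / vocab_size
  }
  with_seed(seed, {
    theta <- matrix(stats::rgamma(n_docs * k_true, shape = concentration),
                    n_docs, k_true)
    theta <- theta / rowSums(theta)
    tokens <- lapply(seq_len(n_docs), function(d) {
      z <- sample.int(k_true, doc_length, replace = TRUE, prob = theta[d, ])
      words <- character(doc_length)
      for (t in unique(z)) {
        sel <- z == t
        words[sel] <- sample(vocab, sum(sel), replace = TRUE, prob = phi[t, ])
      }
      words
    })
    list(
      abstracts = vapply(tokens, paste, character(1), collapse = " "),
      tokens = tokens,
      vocabulary = vocab,
      truth = list(doc_topic = theta, word_topic = phi, k_true = k_true)
    )
  })
}

# letters-only pseudo-words, stable under stemming-free preprocessing
synthetic_vocab <- function(n) {
  syl <- c("ba", "ce", "di", "fo", "gu", "ha", "je", "ki", "lo", "mu",
           "na", "pe", "ri", "so", "tu", "va", "we", "xi", "yo", "zu")
  words <- as.vector(outer(syl, syl, function(a, b) paste0(a, b, "x")))
  words <- as.vector(outer(words, c("on", "ar", "el", "im", "ul"), paste0))
  if (n > length(words)) abort("vocab_size too large for the synthetic word pool")
  words[seq_len(n)]
}

#' Generate a planted-partition co-authorship graph
#'
#' A stochastic-block-style weighted graph: within-block edges appear with
#' probability `p_in`, between-block edges with probability `p_out`, and
#' `bridge_edges` guaranteed bridges are added between consecutive blocks
#' (first-to-first nodes and so on). Edge weights are 1. Truth labels are
#' the planted block memberships.
#'
#' @param blocks Integer vector of block sizes (all positive).
#' @param p_in,p_out Edge probabilities in `[0, 1]`.
#' @param bridge_edges Number of deterministic bridges between each pair of
#'   consecutive blocks.
#' @param seed Integer seed.
#' @return List: `graph` (a `coauthor_graph`), `truth` (named integer block
#'   labels).
#' @export
generate_planted_graph <- function(blocks, p_in, p_out, bridge_edges = 0L,
                                   seed = 1L) {
  if (any(blocks < 1)) abort("block of size 0")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  n <- sum(blocks)
  label <- rep(seq_along(blocks), blocks)
  nodes <- sprintf("v%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  same <- label[pairs[1, ]] == label[pairs[2, ]]
  edges <- with_seed(seed, {
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < p
    pairs[, keep, drop = FALSE]
  })
  el <- t(edges)
  if (bridge_edges > 0 && length(blocks) > 1) {
    starts <- cumsum(c(0, blocks[-length(blocks)]))
    for (b in seq_len(length(blocks) - 1)) {
      for (e in seq_len(bridge_edges)) {
        i <- starts[b] + ((e - 1L) %% blocks[b]) + 1L
        j <- starts[b + 1] + ((e - 1L) %% blocks[b + 1]) + 1L
        el <- rbind(el, c(i, j))
      }
    }
    el <- unique(el)
  }
  df <- data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                   weight = 1)
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  class(g) <- c("coauthor_graph", class(g))
  list(graph = g, truth = setNames(label, nodes))
}
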