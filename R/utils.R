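#' @importFrom rlang %||% abort warn inform
#' @importFrom stats setNames
#' @import tibble
NULL

# Strip diacritics to ASCII; lower-case.
fold_chr <- function(x) {
  stringr::str_to_lower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

# Normalised Levenshtein similarity in [0,1]; both vectors recycled pairwise.
edit_similarity <- function(a, b) {
  d <- diag_adist(a, b)
  denom <- pmax(nchar(a), nchar(b))
  ifelse(denom == 0, 1, 1 - d / denom)
}

diag_adist <- function(a, b) {
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) utils::adist(a[i], b[i])[1, 1], numeric(1))
}

# Deterministic RNG scope: run `expr` under `seed` without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Minimal union-find used by identity resolution and the fixture generator.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_labels <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, sort(unique(roots)))
}
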