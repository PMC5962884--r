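#' Build the weighted co-authorship graph
#'
#' Authors are nodes; an edge's weight is the number of publications the two
#' authors share. Every record with `k` authors contributes +1 to each of
#' its `choose(k, 2)` author pairs; single-author records contribute an
#' isolated node. Nodes are canonical persons (renderings resolved across
#' the record set), so a researcher printed as both "Blair, Steven" and
#' "Blair, S." is one node.
#'
#' @param records A `biblio_corpus`.
#' @param node_status Optional named character vector mapping person keys to
#'   a match-status label (`on_list`, `unlisted_participating`,
#'   `unlisted_subsidiary`); unknown keys get `"unlisted_participating"`.
#' @param tab Optional precomputed [author_table()] for `records`.
#' @return An `igraph` object (undirected, edge attribute `weight`, vertex
#'   attributes `name` and `status`), classed `coauthor_graph`.
#' @export
build_coauthor_graph <- function(records, node_status = NULL, tab = NULL) {
  tab <- tab %||% author_table(records)
  pairs <- purrr::map_dfr(split(tab$person_key, tab$record_id), function(keys) {
    keys <- sort(unique(keys))
    if (length(keys) < 2) return(tibble::tibble())
    cmb <- utils::combn(keys, 2)
    tibble::tibble(from = cmb[1, ], to = cmb[2, ])
  })
  nodes <- sort(unique(tab$person_key))
  if (nrow(pairs) > 0) {
    edges <- dplyr::count(pairs, .data$from, .data$to, name = "weight")
  } else {
    edges <- tibble::tibble(from = character(0), to = character(0),
                            weight = integer(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  status <- rep("unlisted_participating", length(nodes))
  if (!is.null(node_status)) {
    hit <- nodes %in% names(node_status)
    status[hit] <- unname(node_status[nodes[hit]])
  }
  igraph::V(g)$status <- status
  class(g) <- c("coauthor_graph", class(g))
  g
}

#' Weighted degree centrality
#'
#' The sum of the weights of a node's ties; isolated nodes score 0.
#'
#' @param graph A co-authorship graph.
#' @return Named numeric vector.
#' @export
degree_centrality <- function(graph) {
  igraph::strength(graph, weights = igraph::E(graph)$weight)
}

#' Node or edge betweenness centrality
#'
#' The (fractionally attributed) number of shortest paths between all node
#' pairs passing through each node (endpoints excluded) or edge. Shortest
#' paths are computed on the unweighted topology by default; in weighted
#' mode an edge of weight w has length 1/w, so stronger collaborations are
#' shorter.
#'
#' @param graph A co-authorship graph.
#' @param target `"nodes"` or `"edges"`.
#' @param weighted Use inverse-weight distances instead of hop counts.
#' @return Named numeric vector (edges named `"a|b"` with sorted endpoints).
#' @export
betweenness_centrality <- function(graph, target = c("nodes", "edges"),
                                   weighted = FALSE) {
  target <- match.arg(target)
  w <- if (weighted) 1 / igraph::E(graph)$weight else NA
  if (target == "nodes") {
    igraph::betweenness(graph, weights = w, directed = FALSE)
  } else {
    b <- igraph::edge_betweenness(graph, weights = w, directed = FALSE)
    setNames(b, edge_names(graph))
  }
}

edge_names <- function(graph) {
  if (igraph::ecount(graph) == 0) return(character(0))
  ends <- igraph::as_edgelist(graph)
  vapply(seq_len(nrow(ends)), function(i) {
    paste(sort(ends[i, ]), collapse = "|")
  }, character(1))
}

#' Girvan-Newman edge-betweenness community detection
#'
#' Divisive community detection: repeatedly recompute edge betweenness and
#' remove the highest-scoring tie (ties broken deterministically by the
#' lexicographically smallest sorted endpoint pair), recording the full
#' removal sequence. Under the `max_modularity` stopping rule the returned
#' partition is the component structure of maximal weighted modularity
#' encountered along the sequence (modularity evaluated on the *original*
#' weighted graph); under `k_components` removal stops as soon as the graph
#' has at least `k` components.
#'
#' @param graph A co-authorship graph with at least one edge (an edgeless
#'   graph yields singleton communities with quality 0).
#' @param stop `"max_modularity"` or `"k_components"`.
#' @param k Component target for `stop = "k_components"`.
#' @param weighted Use inverse-weight distances for the betweenness ranking.
#' @return A `community_partition` list: `assignment` (named integer,
#'   community ids ordered by smallest member key), `quality` (modularity of
#'   the returned partition), `removal_sequence` (tibble `from`, `to`, in
#'   removal order).
#' @export
girvan_newman_partition <- function(graph, stop = c("max_modularity", "k_components"),
                                    k = 2L, weighted = FALSE) {
  stop <- match.arg(stop)
  wts <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  igraph::E(graph)$weight <- wts
  if (igraph::ecount(graph) == 0) {
    assignment <- canonical_components(graph)
    return(new_partition(assignment, 0, tibble::tibble(from = character(0),
                                                       to = character(0))))
  }
  work <- graph
  removed <- list()
  best_assign <- canonical_components(graph)
  best_q <- partition_modularity(graph, best_assign)
  n_comp_prev <- max(best_assign)
  while (igraph::ecount(work) > 0) {
    if (stop == "k_components" && n_comp_prev >= k) break
    w <- if (weighted) 1 / igraph::E(work)$weight else NA
    eb <- igraph::edge_betweenness(work, weights = w, directed = FALSE)
    ends <- igraph::as_edgelist(work)
    tie_key <- paste(pmin(ends[, 1], ends[, 2]),
                     pmax(ends[, 1], ends[, 2]), sep = "\r")
    mx <- max(eb)
    tied <- which(eb >= mx - 1e-10)
    pick <- tied[order(tie_key[tied])][1]
    removed[[length(removed) + 1L]] <- sort(ends[pick, ])
    work <- igraph::delete_edges(work, pick)
    assign_now <- canonical_components(work)
    n_comp <- max(assign_now)
    if (n_comp > n_comp_prev) {
      q <- partition_modularity(graph, assign_now)
      if (stop == "max_modularity" && q > best_q) {
        best_q <- q
        best_assign <- assign_now
      } else if (stop == "k_components") {
        best_q <- q
        best_assign <- assign_now
      }
      n_comp_prev <- n_comp
    }
  }
  seq_tbl <- tibble::tibble(
    from = vapply(removed, `[`, character(1), 1),
    to = vapply(removed, `[`, character(1), 2)
  )
  new_partition(best_assign, best_q, seq_tbl)
}

new_partition <- function(assignment, quality, removal_sequence) {
  structure(list(assignment = assignment, quality = quality,
                 removal_sequence = removal_sequence),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities over %d nodes, modularity %.4f\n",
              max(x$assignment), length(x$assignment), x$quality))
  invisible(x)
}

partition_modularity <- function(graph, assignment) {
  igraph::modularity(graph, assignment[igraph::V(graph)$name],
                     weights = igraph::E(graph)$weight)
}

# connected components with deterministic ids: communities numbered by their
# lexicographically smallest member key
canonical_components <- function(graph) {
  comp <- igraph::components(graph)$membership
  mins <- tapply(names(comp), comp, min)
  relabel <- match(mins, sort(mins))
  out <- relabel[comp]
  names(out) <- names(comp)
  out[order(names(out))]
}

#' Connected components
#'
#' @param graph A co-authorship graph.
#' @return Named integer vector mapping each node to a component id;
#'   components numbered by smallest member key. Empty graph gives an empty
#'   map.
#' @export
graph_components <- function(graph) {
  if (igraph::vcount(graph) == 0) return(setNames(integer(0), character(0)))
  canonical_components(graph)
}

#' Export / import an attributed co-authorship graph
#'
#' GraphML preserves node attributes (match-status class, weighted degree,
#' community id when a partition is supplied) and edge weights and is
#' re-importable with [import_graph()]; `edgelist` writes a plain
#' tab-separated `from`, `to`, `weight` table (node attributes dropped,
#' isolated nodes listed in a `#` comment header).
#'
#' @param graph A co-authorship graph.
#' @param path Output file.
#' @param partition Optional `community_partition`.
#' @param format `"graphml"` or `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, partition = NULL,
                         format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  igraph::V(graph)$degree <- degree_centrality(graph)
  if (!is.null(partition)) {
    igraph::V(graph)$community <- unname(partition$assignment[igraph::V(graph)$name])
  }
  if (format == "graphml") {
    cl <- class(graph)
    class(graph) <- setdiff(cl, "coauthor_graph")
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ends <- igraph::as_edgelist(graph)
    df <- data.frame(from = ends[, 1], to = ends[, 2],
                     weight = igraph::E(graph)$weight)
    iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(enc2utf8(c(
      paste0("# isolated: ", paste(iso, collapse = ";")),
      "from\tto\tweight",
      sprintf("%s\t%s\t%s", df$from, df$to, df$weight)
    )), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    iso <- sub("^# isolated: ", "", lines[1])
    iso <- strsplit(iso, ";", fixed = TRUE)[[1]]
    iso <- iso[nzchar(iso)]
    df <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE)
    nodes <- sort(unique(c(df$from, df$to, iso)))
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = data.frame(name = nodes))
  }
  class(g) <- c("coauthor_graph", class(g))
  g
}
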