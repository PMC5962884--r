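# Independent betweenness oracle: exhaustive enumeration of all simple paths
# between every node pair, keeping only shortest ones, with fractional
# attribution. Deliberately brute force; only usable for tiny graphs.
oracle_betweenness <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  node_score <- setNames(numeric(length(nodes)), nodes)
  edge_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  edge_score <- setNames(numeric(nrow(edges)),
                         mapply(edge_key, edges$from, edges$to))
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        paths[[length(paths) + 1L]] <<- path
        return()
      }
      for (nxt in adj[[last]]) {
        if (!(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(from)
    paths
  }
  pairs <- utils::combn(nodes, 2)
  for (p in seq_len(ncol(pairs))) {
    paths <- all_paths(pairs[1, p], pairs[2, p])
    if (length(paths) == 0) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    w <- 1 / length(shortest)
    for (sp in shortest) {
      inner <- sp[-c(1, length(sp))]
      node_score[inner] <- node_score[inner] + w
      for (i in seq_len(length(sp) - 1)) {
        k <- edge_key(sp[i], sp[i + 1])
        edge_score[k] <- edge_score[k] + w
      }
    }
  }
  list(nodes = node_score, edges = edge_score)
}

# random connected graph on <= max_nodes nodes (uniform edge sampling plus a
# random spanning tree to guarantee connectivity)
random_connected_graph <- function(max_nodes = 8) {
  n <- sample(3:max_nodes, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  perm <- sample(nodes)
  tree <- data.frame(
    from = perm[2:n],
    to = vapply(2:n, function(i) sample(perm[1:(i - 1)], 1), character(1))
  )
  extra_pairs <- utils::combn(nodes, 2)
  pick <- stats::runif(ncol(extra_pairs)) < 0.3
  extra <- data.frame(from = extra_pairs[1, pick], to = extra_pairs[2, pick])
  edges <- rbind(tree, extra)
  key <- apply(edges, 1, function(r) paste(sort(r), collapse = "|"))
  edges <- edges[!duplicated(key), ]
  df <- data.frame(from = edges$from, to = edges$to, weight = 1)
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  class(g) <- c("coauthor_graph", class(g))
  list(graph = g, edges = edges, nodes = nodes)
}

# two cliques of size k joined by a single bridge edge
two_clique_bridge <- function(k) {
  nodes <- c(sprintf("a%02d", seq_len(k)), sprintf("b%02d", seq_len(k)))
  cl <- function(v) {
    cmb <- utils::combn(v, 2)
    data.frame(from = cmb[1, ], to = cmb[2, ])
  }
  edges <- rbind(cl(nodes[1:k]), cl(nodes[(k + 1):(2 * k)]),
                 data.frame(from = "a01", to = "b01"))
  df <- data.frame(edges, weight = 1)
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  class(g) <- c("coauthor_graph", class(g))
  g
}
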