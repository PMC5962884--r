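test_that("co-authorship graph accumulates pair weights per publication", {
  corp <- tiny_corpus(list(
    tiny_record("G1", c("Adams, Ann", "Burke, Bob", "Cole, Cara"), "x"),
    tiny_record("G2", c("Adams, Ann", "Burke, Bob"), "x"),
    tiny_record("G3", "Dean, Dan", "x")
  ))
  g <- build_coauthor_graph(corp)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  w <- igraph::E(g)$weight
  names(w) <- fundaudit:::edge_names(g)
  expect_equal(unname(w[["adams|ann|burke|bob"]]), 2)
  deg <- degree_centrality(g)
  expect_equal(unname(deg[["dean|dan"]]), 0)
  # handshake identity
  expect_equal(sum(deg), 2 * sum(w))
})

test_that("degree is the sum of incident tie weights", {
  df <- data.frame(from = c("A", "B"), to = c("B", "C"), weight = c(3, 1))
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  expect_equal(unname(degree_centrality(g)["B"]), 4)
})

test_that("betweenness matches hand-enumerated values on a path", {
  df <- data.frame(from = c("A", "B"), to = c("B", "C"), weight = 1)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  nb <- betweenness_centrality(g)
  expect_equal(unname(nb[c("A", "B", "C")]), c(0, 1, 0))
  eb <- betweenness_centrality(g, "edges")
  expect_equal(unname(eb[c("A|B", "B|C")]), c(2, 2))
  # complete graph: no intermediate vertices
  k3 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"), weight = 1),
    directed = FALSE)
  expect_equal(max(betweenness_centrality(k3)), 0)
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  withr::with_seed(42, {
    for (i in 1:30) {
      rg <- random_connected_graph(8)
      oracle <- oracle_betweenness(rg$edges, rg$nodes)
      nb <- betweenness_centrality(rg$graph)
      eb <- betweenness_centrality(rg$graph, "edges")
      expect_equal(nb[names(oracle$nodes)], oracle$nodes, tolerance = 1e-10)
      expect_equal(eb[names(oracle$edges)], oracle$edges, tolerance = 1e-10)
    }
  })
})

test_that("edge-betweenness partitioning removes the bridge first", {
  g <- two_clique_bridge(3)
  p <- girvan_newman_partition(g)
  expect_equal(sort(unname(unlist(p$removal_sequence[1, ]))), c("a01", "b01"))
  expect_equal(max(p$assignment), 2)
  expect_equal(unname(p$assignment[c("a01", "a02", "a03")]), rep(1L, 3))
  expect_equal(unname(p$assignment[c("b01", "b02", "b03")]), rep(2L, 3))
  expect_gte(p$quality, 0)
})

test_that("a disconnected graph partitions immediately into its components", {
  df <- data.frame(from = c("A", "A", "C", "C"), to = c("B", "B2", "D", "D2"),
                   weight = 1)
  df <- data.frame(from = c("A", "B", "C", "X", "Y", "Z"),
                   to = c("B", "C", "A", "Y", "Z", "X"), weight = 1)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  p <- girvan_newman_partition(g)
  comp <- graph_components(g)
  expect_equal(p$assignment, comp)
  expect_equal(max(comp), 2)
})

test_that("edgeless graphs give singleton communities with quality zero", {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("A", "B"))
  p <- girvan_newman_partition(g)
  expect_equal(max(p$assignment), 2)
  expect_equal(p$quality, 0)
})

test_that("metrics are invariant under node relabelling", {
  withr::with_seed(7, {
    rg <- random_connected_graph(7)
    nb <- betweenness_centrality(rg$graph)
    relabel <- setNames(sprintf("z%02d", seq_along(rg$nodes)), rg$nodes)
    df <- data.frame(from = unname(relabel[rg$edges$from]),
                     to = unname(relabel[rg$edges$to]), weight = 1)
    g2 <- igraph::graph_from_data_frame(
      df, directed = FALSE, vertices = data.frame(name = unname(relabel)))
    nb2 <- betweenness_centrality(g2)
    expect_equal(unname(nb2[unname(relabel[names(nb)])]), unname(nb))
  })
})

test_that("component ids are deterministic and empty graphs give empty maps", {
  df <- data.frame(from = c("C", "A"), to = c("D", "B"), weight = 1)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  comp <- graph_components(g)
  expect_equal(unname(comp[c("A", "B", "C", "D")]), c(1L, 1L, 2L, 2L))
  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_length(graph_components(empty), 0)
})

test_that("graph export round-trips attributes in both formats", {
  corp <- tiny_corpus(list(
    tiny_record("G1", c("Adams, Ann", "Burke, Bob", "Cole, Cara"), "x"),
    tiny_record("G2", "Dean, Dan", "x")
  ))
  g <- build_coauthor_graph(corp, node_status = c("adams|ann" = "on_list"))
  p <- girvan_newman_partition(g)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, partition = p, format = "graphml")
  back <- import_graph(gml, "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  st <- setNames(igraph::V(back)$status, igraph::V(back)$name)
  expect_equal(unname(st["adams|ann"]), "on_list")
  expect_true(!is.null(igraph::V(back)$community))
  el <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, el, format = "edgelist")
  back2 <- import_graph(el, "edgelist")
  expect_setequal(igraph::V(back2)$name, igraph::V(g)$name)
  expect_equal(sum(igraph::E(back2)$weight), sum(igraph::E(g)$weight))
})

test_that("fixture cohort graph component count equals the generator truth", {
  sc <- screened_fixture_cached()
  g <- build_coauthor_graph(sc$cohort$records, tab = sc$ca$table)
  expect_equal(max(graph_components(g)),
               sc$fx$truth$n_cohort_components)
})
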