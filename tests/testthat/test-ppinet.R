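string_df <- function(...) {
  rows <- list(...)
  data.frame(protein1 = vapply(rows, `[[`, "", 1),
             protein2 = vapply(rows, `[[`, "", 2),
             combined_score = as.numeric(vapply(rows, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

test_that("STRING loading thresholds, dedups and detects the score scale", {
  df <- string_df(c("A", "B", "950"), c("B", "A", "950"),
                  c("A", "A", "999"))
  g <- load_string_edges(df)
  expect_identical(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::E(g)$combined_score, 0.95)

  # fractional-scale file gives the identical graph
  df_frac <- df; df_frac$combined_score <- df$combined_score / 1000
  g2 <- load_string_edges(df_frac)
  expect_equal(igraph::as_data_frame(g2), igraph::as_data_frame(g))

  expect_warning(empty <- load_string_edges(
    string_df(c("A", "B", "900"), c("B", "C", "850"))), "no edge")
  expect_identical(igraph::ecount(empty), 0)
  expect_error(load_string_edges(data.frame(a = 1)), "missing columns")

  # duplicate pair keeps the max score; whitelist induces a subgraph
  df3 <- string_df(c("A", "B", "950"), c("B", "A", "990"),
                   c("B", "C", "920"), c("C", "D", "980"))
  g3 <- load_string_edges(df3)
  ab <- igraph::E(g3)[igraph::V(g3)["A"] %--% igraph::V(g3)["B"]]
  expect_equal(ab$combined_score, 0.99)
  g4 <- load_string_edges(df3, node_whitelist = c("A", "B", "C"))
  expect_setequal(igraph::V(g4)$name, c("A", "B", "C"))
  expect_identical(igraph::ecount(g4), 2)

  # round-trip through a TSV file
  f <- tempfile(fileext = ".tsv")
  write_string_tsv(df3, f)
  expect_equal(igraph::as_data_frame(load_string_edges(f)),
               igraph::as_data_frame(g3))
})

test_that("centralities agree with hand cases and a brute-force oracle", {
  tri <- load_string_edges(string_df(c("A", "B", "950"),
                                     c("B", "C", "950"),
                                     c("A", "C", "950")))
  ct <- centralities(tri)
  expect_true(all(ct$degree == 2))
  expect_true(all(ct$betweenness == 0))

  path <- load_string_edges(string_df(c("A", "B", "950"),
                                      c("B", "C", "950")))
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "B"], 1.0)
  expect_true(all(cp$betweenness[cp$node != "B"] == 0))

  # random graph vs path-enumeration oracle
  set.seed(13)
  n <- 8
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < 0.4) adj[i, j] <- adj[j, i] <- 1
  }
  ids <- sprintf("N%02d", 1:n)
  rows <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  df <- data.frame(protein1 = ids[rows[, 1]], protein2 = ids[rows[, 2]],
                   combined_score = 950)
  g <- load_string_edges(df)
  ct2 <- centralities(g)
  oracle <- brute_betweenness(adj)
  present <- match(ct2$node, ids)
  expect_equal(ct2$betweenness_raw, oracle[present], tolerance = 1e-10)
  expect_equal(sum(ct2$degree), 2 * igraph::ecount(g))
})

test_that("hub selection ranks by degree, betweenness, then id", {
  star <- load_string_edges(string_df(c("C", "A", "950"), c("C", "B", "950"),
                                      c("C", "D", "950"), c("C", "E", "950")))
  hubs <- select_hubs(centralities(star), top_k = 1)
  expect_identical(hubs$node, "C")

  # degree ties resolved by betweenness: the path middle beats the
  # triangle nodes (all degree 2, only P2 carries shortest paths)
  g <- load_string_edges(string_df(c("P1", "P2", "950"),
                                   c("P2", "P3", "950"),
                                   c("Q1", "Q2", "950"),
                                   c("Q2", "Q3", "950"),
                                   c("Q1", "Q3", "950")))
  ct <- centralities(g)
  two <- select_hubs(ct, top_k = 2)
  expect_identical(two$node[1:2], c("P2", "Q1"))
  expect_warning(all_nodes <- select_hubs(ct, top_k = 99), "all nodes")
  expect_identical(nrow(all_nodes), nrow(ct))
})

test_that("greedy modularity matches exact values and near-optimal partitions", {
  two_tri <- load_string_edges(string_df(
    c("A", "B", "950"), c("B", "C", "950"), c("A", "C", "950"),
    c("D", "E", "950"), c("E", "F", "950"), c("D", "F", "950")))
  comm <- detect_communities(two_tri)
  expect_identical(length(unique(comm$membership)), 2L)
  expect_equal(comm$modularity, 0.5)

  k5 <- t(utils::combn(paste0("K", 1:5), 2))
  complete <- load_string_edges(
    data.frame(protein1 = k5[, 1], protein2 = k5[, 2],
               combined_score = 950))
  expect_identical(length(unique(detect_communities(complete)$membership)),
                   1L)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y", "z")
  ec <- detect_communities(edgeless)
  expect_identical(length(unique(ec$membership)), 3L)
  expect_equal(ec$modularity, 0)

  # greedy Q within 0.05 of the exhaustive optimum on small random graphs
  gaps <- vapply(1:20, function(s) {
    set.seed(s + 40)
    n <- 7
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.45) adj[i, j] <- adj[j, i] <- 1
    if (sum(adj) == 0) return(0)
    ids <- sprintf("V%02d", 1:n)
    rows <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    g <- load_string_edges(data.frame(protein1 = ids[rows[, 1]],
                                      protein2 = ids[rows[, 2]],
                                      combined_score = 950))
    got <- detect_communities(g)$modularity
    best <- brute_max_modularity(adj[unique(as.vector(rows)),
                                     unique(as.vector(rows)),
                                     drop = FALSE])
    best - got
  }, numeric(1))
  expect_true(all(gaps <= 0.05 + 1e-10))
})
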