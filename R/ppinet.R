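#' Load a STRING-format interaction table as a thresholded graph
#'
#' Reads a TSV (or takes a data.frame) with columns `protein1`,
#' `protein2`, `combined_score`. Scores on the 0-1000 integer scale are
#' auto-detected (any value > 1) and divided by 1000. Edges with score
#' strictly greater than `score_min` are kept; self-loops are dropped;
#' duplicate undirected pairs are collapsed keeping the maximal score.
#'
#' @param x path to a TSV file, or a data.frame with the three columns.
#' @param score_min combined-score threshold on the 0-1 scale (default
#'   0.9, the conventional "highest confidence" STRING cut).
#' @param node_whitelist optional gene set; the induced subgraph on
#'   these nodes is returned.
#' @return an undirected simple [igraph::igraph] graph with edge
#'   attribute `combined_score`.
#' @export
load_string_edges <- function(x, score_min = 0.9, node_whitelist = NULL) {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("load_string_edges: missing columns: ",
         paste(miss, collapse = ", "))
  score <- as.numeric(df$combined_score)
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  df <- data.frame(protein1 = as.character(df$protein1),
                   protein2 = as.character(df$protein2),
                   combined_score = score, stringsAsFactors = FALSE)
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  df <- df[!is.na(df$combined_score) & df$combined_score > score_min, ,
           drop = FALSE]
  if (!nrow(df)) {
    warning("load_string_edges: no edge passes score > ", score_min)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  # undirected dedup keeping the maximal score
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  best <- vapply(split(seq_len(nrow(df)), key), function(i) {
    i[which.max(df$combined_score[i])]
  }, integer(1))
  best <- sort(best)
  edges <- data.frame(from = a[best], to = b[best],
                      combined_score = df$combined_score[best],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(node_whitelist)) {
    keep <- intersect(igraph::V(g)$name, node_whitelist)
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}

#' Node centralities
#'
#' Unweighted degree and shortest-path betweenness (normalized by
#' (n-1)(n-2)/2, the number of node pairs a vertex could lie between);
#' scores carried by the edges are used only for thresholding upstream,
#' never for the centralities themselves.
#'
#' @param graph an undirected igraph graph.
#' @return data.frame: node, degree, betweenness (normalized),
#'   betweenness_raw.
#' @export
centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("centralities: empty graph")
  deg <- igraph::degree(graph)
  btw_raw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  data.frame(node = igraph::V(graph)$name,
             degree = unname(deg),
             betweenness = unname(btw_raw / norm),
             betweenness_raw = unname(btw_raw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select hub nodes
#'
#' Ranks by degree (descending), then betweenness (descending), then
#' node id (lexicographic), and returns the first `top_k`.
#'
#' @param centrality_table output of [centralities()].
#' @param top_k number of hubs (default 10).
#' @return the top rows of the centrality table, rank order.
#' @export
select_hubs <- function(centrality_table, top_k = 10) {
  stopifnot(nrow(centrality_table) > 0)
  ord <- order(-centrality_table$degree, -centrality_table$betweenness,
               centrality_table$node)
  if (top_k > nrow(centrality_table)) {
    warning("select_hubs: top_k exceeds node count; returning all nodes")
    top_k <- nrow(centrality_table)
  }
  out <- centrality_table[ord[seq_len(top_k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Community detection by greedy modularity optimization
#'
#' Clauset-Newman-Moore greedy agglomeration maximizing modularity
#' `Q = sum_c (e_c/m - (d_c/2m)^2)`: the merge level with the highest Q
#' is selected (ties resolved toward fewer communities), followed by a
#' deterministic single-node refinement pass -- each node, in vertex
#' order, is moved to the adjacent community that most increases Q until
#' no strictly improving move remains. An edgeless graph yields
#' singleton communities with Q = 0 by convention.
#'
#' @param graph an undirected simple igraph graph.
#' @return list with `membership` (named integer vector, labels 1..K)
#'   and `modularity` (Q of the returned partition).
#' @export
detect_communities <- function(graph) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) == 0L) {
    memb <- setNames(seq_len(n), igraph::V(graph)$name)
    return(list(membership = memb, modularity = 0))
  }
  cl <- igraph::cluster_fast_greedy(graph, weights = NULL)
  n_comp <- igraph::count_components(graph)
  qs <- rep(-Inf, n)
  for (k in seq(n_comp, n)) {
    m_k <- igraph::cut_at(cl, no = k)
    qs[k] <- igraph::modularity(graph, m_k)
  }
  memb <- igraph::cut_at(cl, no = which.max(qs))
  memb <- .refine_membership(graph, memb)
  q <- igraph::modularity(graph, memb)
  # relabel 1..K in order of first appearance
  memb <- match(memb, unique(memb))
  list(membership = setNames(as.integer(memb), igraph::V(graph)$name),
       modularity = q)
}

# Deterministic local refinement: move single nodes to neighboring
# communities while modularity strictly improves.
.refine_membership <- function(graph, memb) {
  adj <- igraph::as_adj_list(graph)
  for (pass in 1:50) {
    improved <- FALSE
    q_cur <- igraph::modularity(graph, memb)
    for (v in seq_along(memb)) {
      cand <- unique(memb[as.integer(adj[[v]])])
      cand <- setdiff(cand, memb[v])
      if (!length(cand)) next
      best_q <- q_cur
      best_c <- memb[v]
      for (cc in sort(cand)) {
        trial <- memb
        trial[v] <- cc
        q_t <- igraph::modularity(graph, trial)
        if (q_t > best_q + 1e-12) {
          best_q <- q_t
          best_c <- cc
        }
      }
      if (best_c != memb[v]) {
        memb[v] <- best_c
        q_cur <- best_q
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}
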