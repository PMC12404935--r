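.LAYERS <- c("deg", "module", "rewired", "tf_t2dm", "tf_htn")

#' Assemble the five-layer integrative network
#'
#' One node per (gene, layer) membership across the five layers --
#' shared DEGs (score: log2 fold change), the disease-linked
#' co-expression module (score: module membership correlation), rewired
#' genes (score: rewiring score), and the two conditions' significant
#' TFs (score: NES difference). Inter-layer edges connect every pair of
#' layers containing the same gene, so a gene present in L layers
#' contributes choose(L, 2) edges.
#'
#' @param deg,module,rewired,tf_t2dm,tf_htn named numeric vectors
#'   (names = gene/TF ids, values = layer scores); any of them may be
#'   empty, but not all.
#' @return object of class `multilayer_network`: an undirected igraph
#'   graph with node attributes `gene`, `layer`, `score`, nodes ordered
#'   by (layer, gene).
#' @export
build_multilayer <- function(deg = numeric(0), module = numeric(0),
                             rewired = numeric(0),
                             tf_t2dm = numeric(0), tf_htn = numeric(0)) {
  layers <- list(deg = deg, module = module, rewired = rewired,
                 tf_t2dm = tf_t2dm, tf_htn = tf_htn)
  sizes <- lengths(layers)
  if (sum(sizes) == 0L)
    stop("build_multilayer: all layers are empty")
  nodes <- do.call(rbind, lapply(.LAYERS, function(ly) {
    v <- layers[[ly]]
    if (!length(v)) return(NULL)
    if (is.null(names(v)))
      stop("build_multilayer: layer '", ly, "' must be a named vector")
    data.frame(gene = names(v), layer = ly, score = unname(v),
               stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(match(nodes$layer, .LAYERS), nodes$gene), ]
  nodes$key <- paste(nodes$layer, nodes$gene, sep = "::")
  edges <- do.call(rbind, lapply(split(nodes$key, nodes$gene), function(k) {
    if (length(k) < 2L) return(NULL)
    t(utils::combn(sort(k), 2L))
  }))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$key,
                            gene = nodes$gene, layer = nodes$layer,
                            score = nodes$score)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, nodes$key),
                                       ncol = 2L)))
  }
  class(g) <- c("multilayer_network", class(g))
  g
}

#' Export a multilayer network as GraphML
#'
#' Writes well-formed GraphML with node attributes `gene`, `layer` and
#' `score` in a deterministic node/edge order, so two exports of the
#' same network are byte-identical and the file round-trips through any
#' generic GraphML reader.
#'
#' @param network a `multilayer_network` (see [build_multilayer()]) or
#'   any igraph graph.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_graphml <- function(network, path) {
  g <- network
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Tissue-specificity Z-scores from a TPM matrix
#'
#' Optionally log2(TPM + 1)-transforms, then standardizes each gene
#' across tissues (`Z = (x - mean) / sd`; constant genes yield an
#' all-zero row). Average-linkage hierarchical clustering orders are
#' returned for genes (correlation distance) and tissues (Euclidean
#' distance), ready for heatmap display.
#'
#' @param tpm gene x tissue matrix of TPM values (>= 0), >= 2 tissues.
#' @param log_transform apply log2(TPM + 1) first (default TRUE).
#' @return list: `z` (gene x tissue Z matrix), `gene_order`,
#'   `tissue_order` (integer orderings).
#' @export
tissue_zscores <- function(tpm, log_transform = TRUE) {
  stopifnot(is.matrix(tpm))
  if (any(tpm < 0)) stop("tissue_zscores: TPM values must be >= 0")
  if (ncol(tpm) < 2L)
    stop("tissue_zscores: need at least 2 tissues")
  x <- if (log_transform) log2(tpm + 1) else tpm
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  gene_order <- seq_len(nrow(z))
  if (nrow(z) > 2L) {
    cc <- suppressWarnings(cor(t(x)))
    cc[is.na(cc)] <- 0
    gene_order <- hclust(stats::as.dist(1 - cc), method = "average")$order
  }
  tissue_order <- seq_len(ncol(z))
  if (ncol(z) > 2L) {
    tissue_order <- hclust(dist(t(z)), method = "average")$order
  }
  list(z = z, gene_order = gene_order, tissue_order = tissue_order)
}
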