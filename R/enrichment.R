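#' Hypergeometric over-representation of gene sets
#'
#' Tests each gene set for over-representation in a gene list against a
#' gene universe using the upper-tail hypergeometric probability
#' `P(X >= k)` with `N` universe genes, `K` set genes and `n` list
#' genes, followed by Benjamini-Hochberg adjustment across tested sets.
#' Sets are intersected with the universe before the size filter.
#'
#' @param gene_list character vector of genes of interest (a subset of
#'   `universe`; genes outside it are dropped with a warning).
#' @param universe character vector, the background gene universe
#'   (typically all genes present after QC).
#' @param collection named list of gene sets (see [read_gmt()] or
#'   [simulate_genesets()]).
#' @param min_size,max_size set-size bounds after universe intersection
#'   (defaults 5 and 500).
#' @return data.frame sorted by p: set, overlap_k, list_n, set_k,
#'   universe_n, p, fdr, genes (comma-separated overlap).
#' @export
hypergeom_enrich <- function(gene_list, universe, collection,
                             min_size = 5, max_size = 500) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!length(gene_list) || !length(universe))
    stop("hypergeom_enrich: empty gene list or universe")
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning("hypergeom_enrich: ", length(outside),
            " list gene(s) outside the universe were dropped")
    gene_list <- intersect(gene_list, universe)
    if (!length(gene_list))
      stop("hypergeom_enrich: no list gene lies in the universe")
  }
  sets <- lapply(collection, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (!length(sets))
    stop("hypergeom_enrich: no set within the size bounds")
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- intersect(gene_list, s)
    k <- length(ov)
    K <- length(s)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap_k = k, list_n = n, set_k = K,
               universe_n = N, p = p,
               genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$set),
             c("set", "overlap_k", "list_n", "set_k", "universe_n",
               "p", "fdr", "genes")]
  rownames(out) <- NULL
  out
}
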