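#' Condition-specific correlation network
#'
#' Pearson correlation matrix over the supplied genes for one
#' condition's samples, carrying the sample count needed by the Fisher
#' r-to-z differential-edge test.
#'
#' @param expr gene x sample matrix (one condition's samples).
#' @param genes optional subset of genes (default all rows).
#' @return object of class `correlation_network`: list with `cor`
#'   (symmetric matrix, unit diagonal) and `n` (sample count).
#' @export
correlation_network <- function(expr, genes = NULL) {
  stopifnot(is.matrix(expr))
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("correlation_network: genes absent from matrix: ",
           paste(head(missing, 5), collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  structure(list(cor = cor(t(expr)), n = ncol(expr)),
            class = "correlation_network")
}

.net_cor <- function(net) {
  if (inherits(net, "correlation_network")) net$cor else net
}

#' Select the genes with the largest between-condition mean differences
#'
#' Ranks the shared genes by absolute difference of per-condition mean
#' expression (descending; ties broken lexicographically by gene id) and
#' returns the first `n` — the gene universe on which the rewiring
#' analysis operates.
#'
#' @param expr_a,expr_b gene x sample matrices for the two conditions.
#' @param n number of genes to keep (default 100).
#' @return character vector of gene ids.
#' @export
select_top_diff_genes <- function(expr_a, expr_b, n = 100) {
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  if (!length(shared))
    stop("select_top_diff_genes: no shared genes between matrices")
  delta <- abs(rowMeans(expr_a[shared, , drop = FALSE]) -
                 rowMeans(expr_b[shared, , drop = FALSE]))
  ord <- order(-delta, shared)
  if (n > length(shared)) {
    warning("select_top_diff_genes: n exceeds shared gene count; ",
            "returning all ", length(shared), " genes")
    n <- length(shared)
  }
  shared[ord][seq_len(n)]
}

#' Per-gene connectivity in a correlation network
#'
#' The signed sum of a gene's correlation coefficients with every other
#' analyzed gene (self excluded): `k_i = sum_{j != i} r_ij`.
#'
#' @param network a `correlation_network` or a correlation matrix.
#' @return named numeric vector of connectivities.
#' @export
connectivity <- function(network) {
  r <- .net_cor(network)
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  rowSums(r) - diag(r)
}

# Zero out correlations whose per-pair Pearson test is not significant,
# mirroring a network whose edges are significant correlations only.
.significant_cor <- function(net, alpha) {
  stopifnot(inherits(net, "correlation_network"))
  r <- net$cor
  n <- net$n
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-tstat, df = n - 2)
  r[p >= alpha] <- 0
  diag(r) <- 1
  r
}

#' Rewiring scores and gain/loss classification
#'
#' The rewiring score of a gene is its connectivity in condition A minus
#' its connectivity in condition B (e.g., T2DM minus HTN). With the
#' default `edges = "significant"` the condition networks retain only
#' statistically significant correlations (per-pair Pearson test,
#' two-sided p < `alpha`; all other entries set to 0) before
#' connectivities are summed, matching a network whose edges are
#' significant co-expression relationships; `edges = "all"` sums the
#' raw signed correlations over all pairs. Genes above the `pct_hi`
#' percentile of the score distribution are classified as connectivity
#' `gain`, below the `pct_lo` percentile as `loss`, and `stable`
#' otherwise (percentiles over the analyzed gene set, linear
#' interpolation). A degenerate all-equal score distribution yields all
#' `stable`.
#'
#' @param net_a,net_b `correlation_network`s over the identical gene
#'   set (plain correlation matrices are accepted with
#'   `edges = "all"`).
#' @param pct_hi,pct_lo percentile thresholds (defaults 95 and 5).
#' @param edges `"significant"` (default) or `"all"`; see above.
#' @param alpha per-pair significance level for `edges = "significant"`
#'   (default 0.05).
#' @return data.frame: gene_id, connectivity_a, connectivity_b,
#'   rewiring_score, class (factor gain/loss/stable).
#' @export
rewiring_scores <- function(net_a, net_b, pct_hi = 95, pct_lo = 5,
                            edges = c("significant", "all"),
                            alpha = 0.05) {
  edges <- match.arg(edges)
  if (edges == "significant") {
    if (!inherits(net_a, "correlation_network") ||
        !inherits(net_b, "correlation_network"))
      stop("rewiring_scores: edges = \"significant\" needs ",
           "correlation_network inputs (sample sizes required); ",
           "use edges = \"all\" for plain matrices")
    ra <- .significant_cor(net_a, alpha)
    rb <- .significant_cor(net_b, alpha)
  } else {
    ra <- .net_cor(net_a)
    rb <- .net_cor(net_b)
  }
  if (!identical(rownames(ra), rownames(rb)))
    stop("rewiring_scores: the two networks must cover the same genes ",
         "in the same order")
  ka <- connectivity(ra)
  kb <- connectivity(rb)
  score <- ka - kb
  cls <- rep("stable", length(score))
  if (length(unique(score)) > 1L) {
    hi <- quantile(score, pct_hi / 100, type = 7, names = FALSE)
    lo <- quantile(score, pct_lo / 100, type = 7, names = FALSE)
    cls[score > hi] <- "gain"
    cls[score < lo] <- "loss"
  }
  data.frame(gene_id = rownames(ra),
             connectivity_a = unname(ka),
             connectivity_b = unname(kb),
             rewiring_score = unname(score),
             class = factor(cls, levels = c("gain", "loss", "stable")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential edges between two correlation networks
#'
#' For every gene pair, compares the two conditions' correlations with
#' the Fisher r-to-z statistic
#' `z = (atanh r_A - atanh r_B) / sqrt(1/(n_A-3) + 1/(n_B-3))`,
#' two-sided normal p-values, and Benjamini-Hochberg adjustment across
#' all pairs. Correlations at |r| = 1 are clamped to 1 - 1e-7 with a
#' warning before the transform.
#'
#' @param net_a,net_b `correlation_network`s over the same gene set with
#'   sample counts >= 4.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame: gene_i, gene_j, r_a, r_b, z, p, fdr, significant.
#' @export
differential_edges <- function(net_a, net_b, alpha = 0.05) {
  stopifnot(inherits(net_a, "correlation_network"),
            inherits(net_b, "correlation_network"))
  if (net_a$n < 4L || net_b$n < 4L)
    stop("differential_edges: both conditions need at least 4 samples")
  ra <- net_a$cor; rb <- net_b$cor
  if (!identical(rownames(ra), rownames(rb)))
    stop("differential_edges: gene sets differ between networks")
  idx <- which(upper.tri(ra), arr.ind = TRUE)
  va <- ra[idx]; vb <- rb[idx]
  if (any(abs(c(va, vb)) >= 1)) {
    warning("differential_edges: |r| = 1 clamped to 1 - 1e-7")
    clamp <- function(r) sign(r) * pmin(abs(r), 1 - 1e-7)
    va <- clamp(va); vb <- clamp(vb)
  }
  se <- sqrt(1 / (net_a$n - 3) + 1 / (net_b$n - 3))
  z <- (atanh(va) - atanh(vb)) / se
  p <- 2 * pnorm(-abs(z))
  fdr <- bh_adjust(p)
  data.frame(gene_i = rownames(ra)[idx[, 1L]],
             gene_j = rownames(ra)[idx[, 2L]],
             r_a = va, r_b = vb, z = z, p = p, fdr = fdr,
             significant = fdr < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
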