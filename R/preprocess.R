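#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the row means of the column-sorted matrix: after
#' normalization each column holds the identical sorted value vector.
#' Idempotent; gene and sample ids are preserved.
#'
#' @param expr gene x sample numeric matrix without missing values.
#' @return normalized matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(is.matrix(expr))
  if (anyNA(expr))
    stop("quantile_normalize: matrix contains missing values; run qc_filter first")
  if (ncol(expr) < 2L) return(expr)
  ord <- apply(expr, 2L, order)
  sorted <- matrix(0, nrow(expr), ncol(expr))
  for (j in seq_len(ncol(expr))) sorted[, j] <- expr[ord[, j], j]
  ref <- rowMeans(sorted)
  out <- expr
  for (j in seq_len(ncol(expr))) out[ord[, j], j] <- ref
  out
}

#' Collapse probe-level rows to gene level
#'
#' Many-to-one probe-to-gene maps are resolved by keeping, for each gene,
#' the probe with the maximal mean expression across samples. Unmapped
#' probes are dropped.
#'
#' @param expr probe x sample matrix (rownames = probe ids).
#' @param map data.frame with columns `probe_id`, `gene_id`.
#' @return gene x sample matrix (rownames = gene ids), gene order given
#'   by first appearance of each gene among the kept probes.
#' @export
collapse_probes <- function(expr, map) {
  stopifnot(is.matrix(expr), all(c("probe_id", "gene_id") %in% names(map)))
  map <- map[map$probe_id %in% rownames(expr) & !is.na(map$gene_id) &
               nzchar(map$gene_id), , drop = FALSE]
  if (!nrow(map))
    stop("collapse_probes: no probe in the map matches the matrix")
  means <- rowMeans(expr[map$probe_id, , drop = FALSE], na.rm = TRUE)
  keep <- vapply(split(seq_len(nrow(map)), map$gene_id), function(i) {
    i[which.max(means[i])]
  }, integer(1))
  keep <- keep[order(keep)]  # deterministic: first-appearance gene order
  out <- expr[map$probe_id[keep], , drop = FALSE]
  rownames(out) <- map$gene_id[keep]
  out
}

#' Batch correction preserving condition contrasts
#'
#' Per gene, design-cell means (condition x context when a `context`
#' column is present, otherwise condition) are computed; each batch's
#' mean residual is subtracted and the cell means added back. Batch
#' residual means become zero to machine tolerance while case-minus-
#' control differences are preserved exactly. Intended for designs where
#' batches are nested within disease context, so naive per-batch
#' standardization would erase the biology.
#'
#' @param expr gene x sample matrix.
#' @param samples sample table with `sample_id`, `condition` and
#'   optionally `context` and `batch` columns.
#' @return corrected matrix.
#' @export
correct_batch <- function(expr, samples) {
  stopifnot(is.matrix(expr),
            all(colnames(expr) %in% samples$sample_id))
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  if (!"batch" %in% names(samples) ||
      length(unique(samples$batch)) < 2L) {
    return(expr)
  }
  cell <- if ("context" %in% names(samples))
    interaction(samples$condition, samples$context, drop = TRUE)
  else factor(samples$condition)
  cell_means <- vapply(levels(cell), function(lv) {
    rowMeans(expr[, cell == lv, drop = FALSE])
  }, numeric(nrow(expr)))
  resid <- expr - cell_means[, as.integer(cell), drop = FALSE]
  for (b in unique(samples$batch)) {
    cols <- which(samples$batch == b)
    if (length(cols) < 2L) {
      warning("correct_batch: batch '", b,
              "' has a single sample; left uncorrected")
      next
    }
    resid[, cols] <- resid[, cols] - rowMeans(resid[, cols, drop = FALSE])
  }
  resid + cell_means[, as.integer(cell), drop = FALSE]
}

#' Quality-control filtering of genes and samples
#'
#' Removes genes then samples whose fraction of missing values exceeds
#' `max_missing_frac`, then removes zero-variance genes. Returns the
#' filtered matrix and a removal report.
#'
#' @param expr gene x sample matrix.
#' @param max_missing_frac maximal tolerated missing fraction (default
#'   0.5).
#' @return list with `expr` (clean matrix) and `report` (data.frame: id,
#'   type, reason).
#' @export
qc_filter <- function(expr, max_missing_frac = 0.5) {
  stopifnot(is.matrix(expr))
  report <- data.frame(id = character(0), type = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  gene_miss <- rowMeans(is.na(expr))
  drop_g <- gene_miss > max_missing_frac
  if (any(drop_g)) {
    report <- rbind(report, data.frame(
      id = rownames(expr)[drop_g], type = "gene",
      reason = sprintf("missing fraction %.2f > %.2f",
                       gene_miss[drop_g], max_missing_frac),
      stringsAsFactors = FALSE))
    expr <- expr[!drop_g, , drop = FALSE]
  }
  samp_miss <- colMeans(is.na(expr))
  drop_s <- samp_miss > max_missing_frac
  if (any(drop_s)) {
    report <- rbind(report, data.frame(
      id = colnames(expr)[drop_s], type = "sample",
      reason = sprintf("missing fraction %.2f > %.2f",
                       samp_miss[drop_s], max_missing_frac),
      stringsAsFactors = FALSE))
    expr <- expr[, !drop_s, drop = FALSE]
  }
  v <- apply(expr, 1L, var, na.rm = TRUE)
  zero_v <- !is.na(v) & v == 0
  if (any(zero_v)) {
    report <- rbind(report, data.frame(
      id = rownames(expr)[zero_v], type = "gene",
      reason = "zero variance", stringsAsFactors = FALSE))
    expr <- expr[!zero_v, , drop = FALSE]
  }
  if (!nrow(expr) || !ncol(expr))
    stop("qc_filter: all genes or samples were removed")
  list(expr = expr, report = report)
}

#' Variance filtering
#'
#' Keeps genes whose variance is strictly greater than the requested
#' percentile (linear-interpolation / type-7 convention) of the per-gene
#' variance vector.
#'
#' @param expr gene x sample matrix with >= 2 samples.
#' @param percentile percentile in 0-100 (default 70, a common choice
#'   for retaining the most informative third of genes).
#' @return filtered matrix, gene order preserved.
#' @export
filter_variance <- function(expr, percentile = 70) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L,
            percentile >= 0, percentile <= 100)
  v <- apply(expr, 1L, var)
  thr <- quantile(v, percentile / 100, type = 7, names = FALSE)
  keep <- v > thr
  if (!any(keep))
    warning("filter_variance: no gene exceeds the ",
            percentile, "th percentile threshold")
  expr[keep, , drop = FALSE]
}

#' Detect outlier samples by hierarchical clustering
#'
#' Average-linkage clustering on Euclidean distances between sample
#' profiles; a sample is flagged when its first merge into the tree
#' occurs above the cut height. The automatic cut is
#' mean(merge heights) + 2.5 * sd(merge heights).
#'
#' @param expr gene x sample matrix with >= 3 samples.
#' @param cut_height numeric cut height, or `"auto"`.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(expr, cut_height = "auto") {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3L)
    stop("detect_outlier_samples: need at least 3 samples")
  hc <- hclust(dist(t(expr)), method = "average")
  h <- hc$height
  cut <- if (identical(cut_height, "auto")) {
    mean(h) + 2.5 * sd(h)
  } else {
    as.numeric(cut_height)
  }
  # height at which each leaf first joins the tree
  first_merge <- rep(NA_real_, ncol(expr))
  for (k in seq_len(nrow(hc$merge))) {
    for (side in 1:2) {
      m <- hc$merge[k, side]
      if (m < 0) first_merge[-m] <- h[k]
    }
  }
  colnames(expr)[first_merge > cut]
}
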