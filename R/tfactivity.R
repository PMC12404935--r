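#' Load a regulon table
#'
#' Reads a DoRothEA-style TSV (or takes a data.frame) with columns
#' `tf`, `confidence`, `target`, `mor`. Rows outside the requested
#' confidence levels are dropped, rows with malformed mode-of-regulation
#' (non-numeric or zero) are rejected with a warning, and duplicate
#' (tf, target) pairs are collapsed keeping the first occurrence.
#'
#' @param x path or data.frame.
#' @param confidence_keep confidence levels retained (default
#'   `c("A", "B")`, the high-confidence tiers).
#' @return data.frame (tf, confidence, target, mor).
#' @export
load_regulons <- function(x, confidence_keep = c("A", "B")) {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  need <- c("tf", "confidence", "target", "mor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("load_regulons: missing columns: ", paste(miss, collapse = ", "))
  mor <- suppressWarnings(as.numeric(df$mor))
  bad <- is.na(mor) | mor == 0
  if (any(bad)) {
    warning("load_regulons: rejected ", sum(bad),
            " row(s) with malformed mode-of-regulation")
    df <- df[!bad, , drop = FALSE]
    mor <- mor[!bad]
  }
  df$mor <- mor
  df <- df[df$confidence %in% confidence_keep, , drop = FALSE]
  if (!nrow(df))
    stop("load_regulons: no regulon rows left after confidence filter; ",
         "consider widening confidence_keep")
  dup <- duplicated(df[, c("tf", "target")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df[, need]
}

#' Regulon activity as normalized enrichment scores
#'
#' Expression is gene-wise standardized across samples
#' (`sig_gs = (x_gs - mean_g) / sd_g`); the activity of a TF in a sample
#' is the mor-weighted sum of its targets' signatures normalized by the
#' weight norm: `NES_ts = sum_targets mor * sig_ts / sqrt(sum mor^2)`.
#' Under pure noise each TF's NES has mean ~0 and variance ~1. TFs with
#' fewer than `min_targets` targets present in the matrix are excluded
#' and listed in the `"excluded"` attribute.
#'
#' @param expr gene x sample matrix (QC'd, no missing values).
#' @param regulons regulon data.frame (see [load_regulons()]).
#' @param min_targets minimal number of present targets (default 5).
#' @return TF x sample NES matrix with attributes `"regulon_size"`
#'   (named integer) and `"excluded"` (character).
#' @export
activity_nes <- function(expr, regulons, min_targets = 5) {
  stopifnot(is.matrix(expr),
            all(c("tf", "target", "mor") %in% names(regulons)))
  sig <- t(scale(t(expr)))
  sig[is.na(sig)] <- 0
  regulons <- regulons[regulons$target %in% rownames(expr), , drop = FALSE]
  sizes <- table(regulons$tf)
  keep_tfs <- names(sizes)[sizes >= min_targets]
  excluded <- setdiff(names(sizes), keep_tfs)
  if (!length(keep_tfs))
    stop("activity_nes: no TF has >= ", min_targets, " present targets")
  nes <- t(vapply(keep_tfs, function(tf) {
    rows <- regulons[regulons$tf == tf, ]
    w <- rows$mor
    colSums(w * sig[rows$target, , drop = FALSE]) / sqrt(sum(w^2))
  }, numeric(ncol(expr))))
  dimnames(nes) <- list(keep_tfs, colnames(expr))
  attr(nes, "regulon_size") <-
    setNames(as.integer(sizes[keep_tfs]), keep_tfs)
  attr(nes, "excluded") <- excluded
  nes
}

#' Differential TF activity between case and control
#'
#' Pooled-variance (Student's) two-sample t-test per TF on the NES
#' values, two-sided; significance at p < 0.05.
#'
#' @param nes TF x sample NES matrix (see [activity_nes()]).
#' @param samples sample table with `sample_id` and `condition`.
#' @return data.frame: tf, mean_diff (case minus control), t, p,
#'   significant.
#' @export
differential_activity <- function(nes, samples) {
  stopifnot(is.matrix(nes))
  samples <- samples[match(colnames(nes), samples$sample_id), ]
  case <- samples$condition == "case"
  if (sum(case) < 2L || sum(!case) < 2L)
    stop("differential_activity: each group needs at least 2 samples")
  rows <- lapply(rownames(nes), function(tf) {
    x <- nes[tf, case]; y <- nes[tf, !case]
    tt <- t.test(x, y, var.equal = TRUE)
    data.frame(tf = tf, mean_diff = mean(x) - mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}
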