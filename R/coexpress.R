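#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power beta, the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` yields connectivities
#' `k_i = sum_j a_ij`; k is discretized into `n_bins` equal-width bins
#' and log10(bin frequency) is regressed on log10(bin-mean k). The
#' signed fit index is `-sign(slope) * R^2`. The chosen power is the
#' smallest candidate whose signed R^2 reaches `r2_target`; if none
#' does, the argmax is chosen with a warning.
#'
#' @param expr gene x sample matrix (no zero-variance genes).
#' @param powers candidate powers (default 1:10 then 12, 14, 16; with a
#'   few dozen samples, powers beyond ~16 amplify correlation sampling
#'   noise -- the relative error of r^beta grows with beta -- faster
#'   than they sharpen the network).
#' @param r2_target target signed scale-free R^2 (default 0.80).
#' @param n_bins histogram bins for the degree distribution (default 10).
#' @return list with `power` (chosen beta) and `report` (data.frame:
#'   power, r_squared, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16),
                                r2_target = 0.80, n_bins = 10) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 8L)
    warning("pick_soft_threshold: fewer than 8 samples; ",
            "scale-free fit estimates will be unstable")
  v <- apply(expr, 1L, var)
  if (any(v == 0))
    stop("pick_soft_threshold: constant genes present; run qc_filter first")
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    fit <- .scale_free_fit(k, n_bins)
    data.frame(power = b, r_squared = fit$r_squared, slope = fit$slope,
               mean_k = mean(k))
  })
  report <- do.call(rbind, rows)
  hit <- which(report$r_squared >= r2_target)
  if (length(hit)) {
    power <- report$power[hit[1L]]
  } else {
    power <- report$power[which.max(report$r_squared)]
    warning("pick_soft_threshold: no candidate reached R^2 >= ",
            r2_target, "; using argmax (power = ", power, ")")
  }
  list(power = power, report = report)
}

# Signed scale-free model fit on a connectivity vector: connectivities
# are discretized into equal-width bins on the k scale (the convention
# of the established co-expression tooling), and log10(bin frequency)
# is regressed on log10(bin-mean k).
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = n_bins)
  freq <- tabulate(bin, nbins = n_bins)
  dk <- vapply(split(k, bin),
               function(x) if (length(x)) mean(x) else NA_real_,
               numeric(1))
  keep <- freq > 0 & !is.na(dk) & dk > 0
  if (sum(keep) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_))
  x <- log10(dk[keep])
  y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope)
}

#' Topological overlap from an unsigned adjacency
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' with unit diagonal. High overlap means two genes share neighbors in
#' addition to any direct connection.
#'
#' @param adjacency symmetric matrix with values in \[0, 1\] (diagonal
#'   ignored).
#' @return symmetric TOM matrix with values in \[0, 1\] and diagonal 1.
#' @export
tom_from_adjacency <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Build the topological overlap matrix from expression
#'
#' Unsigned adjacency `|cor|^beta` followed by [tom_from_adjacency()].
#'
#' @param expr gene x sample matrix.
#' @param beta soft-threshold power (>= 1).
#' @return gene x gene TOM matrix.
#' @export
build_tom <- function(expr, beta) {
  stopifnot(is.matrix(expr), beta >= 1)
  a <- abs(cor(t(expr)))^beta
  tom_from_adjacency(a)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut statically at `static_cut`; clusters smaller than
#' `min_module_size` are set aside as unassigned (label 0). Modules
#' whose eigengenes correlate above `1 - merge_cut_height` are then
#' merged iteratively (highest-correlation pair first, ties by smallest
#' label pair) and labels are reassigned 1..K by decreasing size.
#'
#' @param tom TOM matrix (see [build_tom()]).
#' @param expr the expression matrix the TOM was built from (needed for
#'   eigengene-based merging).
#' @param min_module_size minimum module size (default 200, the
#'   conventional choice for genome-scale arrays; synthetic analyses use
#'   smaller values).
#' @param merge_cut_height eigengene dissimilarity below which modules
#'   merge (default 0.20, i.e. correlation > 0.80 merges).
#' @param static_cut tree cut height on 1 - TOM (default 0.99).
#' @return named integer vector (gene -> module label; 0 = unassigned),
#'   labels 1..K ordered by decreasing module size.
#' @export
detect_modules <- function(tom, expr, min_module_size = 200,
                           merge_cut_height = 0.20, static_cut = 0.99) {
  stopifnot(is.matrix(tom), nrow(tom) == nrow(expr))
  genes <- rownames(tom)
  if (is.null(genes)) genes <- rownames(expr)
  d <- 1 - tom
  hc <- hclust(stats::as.dist(d), method = "average")
  if (max(hc$height) <= static_cut) {
    labels <- rep(1L, nrow(tom))
  } else {
    labels <- cutree(hc, h = static_cut)
  }
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  labels[labels %in% small] <- 0L
  if (all(labels == 0L)) {
    warning("detect_modules: no cluster reaches min_module_size = ",
            min_module_size, "; all genes unassigned")
    return(setNames(labels, genes))
  }
  labels <- setNames(labels, genes)

  # eigengene merge: correlation > 1 - merge_cut_height collapses modules
  merge_thr <- 1 - merge_cut_height
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, labels)$eigengenes
    me <- me[paste0("ME", mods), , drop = FALSE]
    cc <- cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    if (cc[best[1L], best[2L]] <= merge_thr) break
    pair <- sort(mods[best])
    labels[labels == pair[2L]] <- pair[1L]
  }

  # relabel by decreasing size; unassigned stays 0
  mods <- sort(unique(labels[labels > 0L]))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new_ids <- integer(max(mods))
  new_ids[mods[order(-sizes, mods)]] <- seq_along(mods)
  out <- ifelse(labels > 0L, new_ids[labels], 0L)
  setNames(as.integer(out), genes)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component across
#' samples of the module's gene-standardized expression, scaled to unit
#' variance and sign-aligned so that its correlation with the module's
#' mean standardized profile is non-negative. The fraction of variance
#' it explains is reported per module.
#'
#' @param expr gene x sample matrix.
#' @param partition named integer vector gene -> module label (as from
#'   [detect_modules()]); eigengenes are computed for every label
#'   present, including 0 if any gene is unassigned.
#' @return list with `eigengenes` (module x sample matrix, rownames
#'   "ME<label>") and `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, partition) {
  stopifnot(is.matrix(expr), !is.null(names(partition)))
  partition <- partition[names(partition) %in% rownames(expr)]
  mods <- sort(unique(partition))
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    g <- names(partition)[partition == mods[i]]
    x <- expr[g, , drop = FALSE]
    xs <- t(scale(t(x)))          # gene-standardized
    xs[is.na(xs)] <- 0            # constant genes contribute nothing
    if (nrow(xs) == 1L) {
      e <- as.numeric(xs)
      ve[i] <- 1
    } else {
      sv <- svd(xs)
      e <- sv$v[, 1L]
      ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    if (sd(e) > 0) e <- e / sd(e)
    if (cor(e, colMeans(xs)) < 0) e <- -e
    me[i, ] <- e
  }
  list(eigengenes = me, var_explained = ve)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each numerically
#' encoded trait, with two-sided p-values from the t distribution with
#' n - 2 degrees of freedom. The default encoding follows the
#' case/control and sex conventions: disease (case = 1, control = 0)
#' and sex (female = 1, male = 0).
#'
#' @param eigengenes module x sample matrix (see [module_eigengenes()]).
#' @param samples sample table aligned to the eigengene columns.
#' @param traits optional sample x trait numeric data.frame; if `NULL`,
#'   built from `samples` (`disease`, and `sex` when present).
#' @return data.frame (module, trait, r, p); constant traits yield NA
#'   with a warning.
#' @export
module_trait_correlation <- function(eigengenes, samples, traits = NULL) {
  stopifnot(is.matrix(eigengenes))
  samples <- samples[match(colnames(eigengenes), samples$sample_id), ]
  if (is.null(traits)) {
    traits <- data.frame(disease = as.numeric(samples$condition == "case"))
    if ("sex" %in% names(samples) && any(samples$sex %in% c("female", "male")))
      traits$sex <- as.numeric(samples$sex == "female")
  }
  n <- ncol(eigengenes)
  out <- expand.grid(module = rownames(eigengenes), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    tv <- traits[[out$trait[i]]]
    if (sd(tv) == 0) {
      warning("module_trait_correlation: trait '", out$trait[i],
              "' is constant; correlation undefined")
      next
    }
    r <- cor(eigengenes[out$module[i], ], tv)
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    out$r[i] <- r
    out$p[i] <- 2 * pt(-abs(tt), df = n - 2)
  }
  out
}
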