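#' Simulation configuration for two-condition expression data
#'
#' Builds and validates the configuration used by [simulate_expression()]
#' and [simulate_regulons()]. The generator emulates a two-disease-context
#' (T2DM vs HTN) case/control microarray compendium: several batches
#' (one per original series) nested within disease context, log2-scale
#' expression with gene-wise baselines around 8, planted differentially
#' expressed genes, planted correlated gene modules, planted
#' condition-specific correlation hubs (rewiring), and planted
#' transcription-factor regulon activity shifts.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_group samples per context x case/control cell
#'   (four cells in total).
#' @param n_batches number of batches, split between the two disease
#'   contexts (batches are nested within context, as when each original
#'   dataset is one batch of one disease).
#' @param n_modules,module_size number and size of planted co-expression
#'   modules.
#' @param module_cor within-module Pearson correlation (latent-factor
#'   loading chosen so the pairwise correlation equals this value).
#' @param n_degs,deg_effect number of planted differentially expressed
#'   genes and their absolute log2 case-minus-control shift (signs
#'   alternate across the planted genes).
#' @param n_rewired,rewired_partners,rewired_cor planted rewired hubs:
#'   each hub correlates with `rewired_partners` partner genes at
#'   `rewired_cor` in the T2DM context only.
#' @param n_tfs,targets_per_tf,tf_effect planted regulons: number of TFs,
#'   targets per TF, and the activity shift (in units of `noise_sd`)
#'   applied to targets of active TFs in T2DM case samples.
#' @param noise_sd residual log2-scale noise standard deviation.
#' @param batch_sd standard deviation of per-gene, per-batch offsets.
#' @param seed integer seed; component-level child seeds are derived from
#'   it by fixed offsets so each generator is independently reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 400, n_samples_per_group = 10,
#'                   n_modules = 2, module_size = 30, n_tfs = 4)
#' sim <- simulate_expression(cfg)
#' dim(sim$expr)
sim_config <- function(n_genes = 1000,
                       n_samples_per_group = 15,
                       n_batches = 5,
                       n_modules = 4,
                       module_size = 50,
                       module_cor = 0.8,
                       n_degs = 20,
                       deg_effect = 2,
                       n_rewired = 2,
                       rewired_partners = 20,
                       rewired_cor = 0.8,
                       n_tfs = 10,
                       targets_per_tf = 10,
                       tf_effect = 1,
                       noise_sd = 1,
                       batch_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_batches = as.integer(n_batches),
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    module_cor = module_cor,
    n_degs = as.integer(n_degs),
    deg_effect = deg_effect,
    n_rewired = as.integer(n_rewired),
    rewired_partners = as.integer(rewired_partners),
    rewired_cor = rewired_cor,
    n_tfs = as.integer(n_tfs),
    targets_per_tf = as.integer(targets_per_tf),
    tf_effect = tf_effect,
    noise_sd = noise_sd,
    batch_sd = batch_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_samples_per_group", "n_batches", "n_modules",
              "module_size", "n_degs", "n_rewired", "rewired_partners",
              "n_tfs", "targets_per_tf")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("sim_config: '", f, "' must be a non-negative count")
  }
  if (cfg$n_genes < 1L || cfg$n_samples_per_group < 1L || cfg$n_batches < 1L)
    stop("sim_config: n_genes, n_samples_per_group and n_batches must be >= 1")
  for (f in c("module_cor", "rewired_cor")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: '", f, "' must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("sim_config: noise_sd must be positive")
  if (cfg$batch_sd < 0) stop("sim_config: batch_sd must be non-negative")
  n_planted <- with(cfg, n_modules * module_size + n_degs +
                      n_rewired * (1L + rewired_partners) +
                      n_tfs * targets_per_tf)
  if (n_planted > cfg$n_genes)
    stop("sim_config: planted genes (", n_planted,
         ") exceed n_genes (", cfg$n_genes, ")")
  structure(cfg, class = "sim_config")
}

# Fixed child-seed offsets: one global seed expands into per-component
# seeds so e.g. the regulon table is reproducible without regenerating
# the expression matrix.
.child_seed <- function(seed, component) {
  offs <- c(expression = 0L, regulons = 101L, ppi = 202L,
            genesets = 303L, tpm = 404L)
  (as.integer(seed) + offs[[component]]) %% .Machine$integer.max
}

# Deterministic layout of planted gene blocks within 1..n_genes:
# modules first, then DEGs, rewired hubs, their partners, TF targets.
.plant_layout <- function(cfg) {
  ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  pos <- 0L
  take <- function(k) {
    out <- if (k > 0L) ids[pos + seq_len(k)] else character(0)
    pos <<- pos + k
    out
  }
  modules <- lapply(seq_len(cfg$n_modules),
                    function(m) take(cfg$module_size))
  names(modules) <- if (cfg$n_modules > 0L)
    paste0("M", seq_len(cfg$n_modules)) else character(0)
  degs <- take(cfg$n_degs)
  hubs <- take(cfg$n_rewired)
  partners <- lapply(seq_len(cfg$n_rewired),
                     function(i) take(cfg$rewired_partners))
  names(partners) <- hubs
  targets <- lapply(seq_len(cfg$n_tfs),
                    function(i) take(cfg$targets_per_tf))
  names(targets) <- if (cfg$n_tfs > 0L)
    sprintf("TF%03d", seq_len(cfg$n_tfs)) else character(0)
  list(gene_ids = ids, modules = modules, degs = degs, hubs = hubs,
       partners = partners, tf_targets = targets)
}

# Sample sheet: two contexts x case/control x n per cell, batches nested
# within context (cyclic assignment), sex drawn at random.
.sample_sheet <- function(cfg) {
  n <- cfg$n_samples_per_group
  ctx <- rep(c("T2DM", "HTN"), each = 2L * n)
  cond <- rep(rep(c("case", "control"), each = n), times = 2L)
  total <- length(ctx)
  n_b_t2dm <- max(1L, cfg$n_batches %/% 2L)
  n_b_htn <- max(1L, cfg$n_batches - n_b_t2dm)
  batch <- character(total)
  idx_t2dm <- which(ctx == "T2DM")
  idx_htn <- which(ctx == "HTN")
  batch[idx_t2dm] <- paste0("B", 1L + (seq_along(idx_t2dm) - 1L) %% n_b_t2dm)
  batch[idx_htn] <- paste0("B", n_b_t2dm +
                             1L + (seq_along(idx_htn) - 1L) %% n_b_htn)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(total)),
    condition = cond,
    context = ctx,
    batch = batch,
    sex = sample(c("female", "male"), total, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-condition, multi-batch expression matrix with planted
#' ground truth
#'
#' Generates a log2-scale gene-by-sample matrix under an additive
#' latent-factor model: gene baselines ~ N(8, 1); per-gene batch offsets
#' ~ N(0, batch_sd); module genes share a per-module latent factor with
#' loading chosen so that within-module pairwise correlation equals
#' `module_cor`; planted DEGs are shifted by `deg_effect` (alternating
#' sign) in case samples; each rewired hub's partners track the hub at
#' correlation `rewired_cor` in the T2DM context only; targets of active
#' TFs are shifted by `tf_effect * noise_sd * mor` in T2DM case samples.
#' Module genes carry the shared factor on top of `noise_sd^2` residual
#' noise, so co-regulation raises their variance above background (as it
#' does in real data); all other genes have non-batch variance
#' `noise_sd^2`.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `sim_data` with elements `expr` (gene x sample
#'   matrix), `samples` (sample table: sample_id, condition, context,
#'   batch, sex) and `truth` (ground-truth list: `deg_genes` named signed
#'   effects, `module_assignments` named module ids, `rewired_genes`
#'   named direction "gain_T2DM", `rewired_partners` list,
#'   `active_tfs` named signed shifts).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(.child_seed(cfg$seed, "expression"))
  layout <- .plant_layout(cfg)
  samples <- .sample_sheet(cfg)
  n_s <- nrow(samples)
  ids <- layout$gene_ids

  baseline <- rnorm(cfg$n_genes, mean = 8, sd = 1)
  expr <- matrix(rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
                 nrow = cfg$n_genes, ncol = n_s,
                 dimnames = list(ids, samples$sample_id))

  # module structure: shared latent factor per module added on top of the
  # residual noise, with loading chosen so within-module correlation is
  # exactly module_cor; co-regulation therefore raises module-gene
  # variance above background, as in real data
  if (cfg$n_modules > 0L && cfg$module_size > 0L && cfg$module_cor > 0) {
    if (cfg$module_cor >= 1)
      stop("simulate_expression: module_cor must be < 1 when modules are planted")
    load_f <- cfg$noise_sd * sqrt(cfg$module_cor / (1 - cfg$module_cor))
    for (m in seq_len(cfg$n_modules)) {
      g <- layout$modules[[m]]
      f <- rnorm(n_s)
      expr[g, ] <- expr[g, ] +
        matrix(load_f * f, nrow = length(g), ncol = n_s, byrow = TRUE)
    }
  }

  # rewired hubs: partners track the hub at rewired_cor in T2DM only
  in_t2dm <- samples$context == "T2DM"
  if (cfg$n_rewired > 0L && cfg$rewired_partners > 0L && cfg$rewired_cor > 0) {
    for (h in layout$hubs) {
      hub_z <- expr[h, in_t2dm] / cfg$noise_sd
      for (p in layout$partners[[h]]) {
        e <- rnorm(sum(in_t2dm))
        expr[p, in_t2dm] <- cfg$noise_sd *
          (cfg$rewired_cor * hub_z + sqrt(1 - cfg$rewired_cor^2) * e)
      }
    }
  }

  # planted DEG shifts in case samples of both contexts, alternating sign
  deg_effects <- numeric(0)
  if (cfg$n_degs > 0L) {
    signs <- rep_len(c(1, -1), cfg$n_degs)
    deg_effects <- setNames(signs * cfg$deg_effect, layout$degs)
    is_case <- samples$condition == "case"
    expr[layout$degs, is_case] <- expr[layout$degs, is_case] + deg_effects
  }

  # TF activity: targets of active TFs shifted by mor * tf_effect * noise_sd
  # in T2DM case samples; half of the TFs are active, signs alternate
  regulons <- .generate_regulons(cfg, layout)
  active_tfs <- numeric(0)
  if (cfg$n_tfs > 0L) {
    n_active <- ceiling(cfg$n_tfs / 2)
    act_signs <- rep_len(c(1, -1), n_active)
    active_tfs <- setNames(act_signs * cfg$tf_effect,
                           names(layout$tf_targets)[seq_len(n_active)])
    hit <- samples$condition == "case" & in_t2dm
    for (tf in names(active_tfs)) {
      rows <- regulons[regulons$tf == tf, ]
      shift <- active_tfs[[tf]] * cfg$noise_sd * rows$mor
      expr[rows$target, hit] <- expr[rows$target, hit] + shift
    }
  }

  # baseline and batch offsets last (pure location terms)
  expr <- expr + baseline
  batch_levels <- unique(samples$batch)
  if (cfg$batch_sd > 0 && length(batch_levels) > 1L) {
    for (b in batch_levels) {
      off <- rnorm(cfg$n_genes, sd = cfg$batch_sd)
      expr[, samples$batch == b] <- expr[, samples$batch == b] + off
    }
  }

  module_assign <- integer(0)
  if (cfg$n_modules > 0L && cfg$module_size > 0L) {
    module_assign <- setNames(
      rep(seq_len(cfg$n_modules), each = cfg$module_size),
      unlist(layout$modules)
    )
  }
  truth <- list(
    deg_genes = deg_effects,
    module_assignments = module_assign,
    rewired_genes = setNames(rep("gain_T2DM", length(layout$hubs)),
                             layout$hubs),
    rewired_partners = layout$partners,
    active_tfs = active_tfs
  )
  structure(list(expr = expr, samples = samples, truth = truth),
            class = "sim_data")
}

# Internal deterministic regulon builder shared by simulate_expression
# (which needs the mor signs to plant shifts) and simulate_regulons.
.generate_regulons <- function(cfg, layout) {
  if (cfg$n_tfs == 0L) {
    return(data.frame(tf = character(0), confidence = character(0),
                      target = character(0), mor = numeric(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(.child_seed(cfg$seed, "regulons"))
  rows <- lapply(seq_len(cfg$n_tfs), function(i) {
    tf <- names(layout$tf_targets)[i]
    tg <- layout$tf_targets[[i]]
    data.frame(tf = tf,
               confidence = c("A", "B")[1L + (i - 1L) %% 2L],
               target = tg,
               mor = sample(c(1, -1), length(tg), replace = TRUE,
                            prob = c(0.7, 0.3)),
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  # low-confidence decoy TFs so the A/B filter has something to drop
  n_decoy <- max(1L, cfg$n_tfs %/% 2L)
  decoys <- lapply(seq_len(n_decoy), function(i) {
    tg <- sample(layout$gene_ids, cfg$targets_per_tf)
    data.frame(tf = sprintf("TFLOW%02d", i),
               confidence = c("C", "D", "E")[1L + (i - 1L) %% 3L],
               target = tg,
               mor = sample(c(1, -1), length(tg), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  rbind(reg, do.call(rbind, decoys))
}

#' Simulate a regulon table
#'
#' Deterministically regenerates the regulon table used by
#' [simulate_expression()] for the same configuration: each planted TF
#' has `targets_per_tf` targets with modes of regulation in {+1, -1} and
#' confidence A or B; additional decoy TFs carry confidences C-E so that
#' confidence filtering is exercised downstream.
#'
#' @param config a [sim_config()] object with `n_tfs > 0` and
#'   `targets_per_tf > 0` (an empty table is returned for `n_tfs = 0`).
#' @return data.frame with columns tf, confidence, target, mor.
#' @export
simulate_regulons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tfs > 0L && config$targets_per_tf < 1L)
    stop("simulate_regulons: targets_per_tf must be positive when n_tfs > 0")
  .generate_regulons(config, .plant_layout(config))
}

#' Simulate a STRING-style protein-protein interaction edge list
#'
#' Draws an undirected simple graph over the given genes, either as an
#' Erdos-Renyi graph (`community_structure = FALSE`) or as a planted
#' partition graph with dense within-block and sparse between-block
#' edges. Combined scores are integers on the 0-1000 STRING scale;
#' structural edges receive high-confidence scores (901-1000) so they
#' survive the conventional > 0.9 filter.
#'
#' @param genes character vector of node ids.
#' @param edge_prob edge probability (Erdos-Renyi mode).
#' @param community_structure logical; use a planted-partition model.
#' @param n_blocks,p_within,p_between planted-partition parameters.
#' @param seed integer seed.
#' @return data.frame (protein1, protein2, combined_score) with attribute
#'   `"blocks"` (named block assignment) when community structure is on.
#' @export
simulate_ppi <- function(genes, edge_prob = 0.05,
                         community_structure = FALSE,
                         n_blocks = 2, p_within = 0.9, p_between = 0.05,
                         seed = 1L) {
  if (edge_prob < 0 || edge_prob > 1)
    stop("simulate_ppi: edge_prob must lie in [0, 1]")
  if (community_structure &&
      (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1))
    stop("simulate_ppi: block probabilities must lie in [0, 1]")
  set.seed(as.integer(seed))
  n <- length(genes)
  blocks <- NULL
  if (n < 2L) {
    out <- data.frame(protein1 = character(0), protein2 = character(0),
                      combined_score = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  pairs <- t(utils::combn(n, 2L))
  if (community_structure) {
    blocks <- setNames(rep_len(seq_len(n_blocks), n), genes)
    same <- blocks[pairs[, 1L]] == blocks[pairs[, 2L]]
    p <- ifelse(same, p_within, p_between)
  } else {
    p <- rep(edge_prob, nrow(pairs))
  }
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(
    protein1 = genes[pairs[, 1L]],
    protein2 = genes[pairs[, 2L]],
    combined_score = as.integer(round(runif(nrow(pairs), 901, 1000))),
    stringsAsFactors = FALSE
  )
  if (!is.null(blocks)) attr(out, "blocks") <- blocks
  out
}

#' Simulate a gene-set collection
#'
#' Random gene sets in GMT-compatible form. If `enriched_genes` is given,
#' the first set is seeded with those genes (padded with random genes to
#' `set_size`), providing a planted over-represented set.
#'
#' @param genes gene universe to draw from.
#' @param n_sets,set_size number and size of sets.
#' @param enriched_genes optional character vector planted into set 1.
#' @param seed integer seed.
#' @return named list of character vectors (a `GeneSetCollection`).
#' @export
simulate_genesets <- function(genes, n_sets = 10, set_size = 20,
                              enriched_genes = NULL, seed = 1L) {
  if (n_sets < 1L || set_size < 1L)
    stop("simulate_genesets: n_sets and set_size must be positive")
  if (set_size > length(genes))
    stop("simulate_genesets: set_size exceeds the gene universe")
  set.seed(as.integer(seed))
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  if (!is.null(enriched_genes)) {
    core <- unique(intersect(enriched_genes, genes))
    core <- head(core, set_size)
    pad <- sample(setdiff(genes, core), set_size - length(core))
    sets[[1L]] <- c(core, pad)
  }
  sets
}

#' Simulate a tissue TPM matrix
#'
#' Log-normal baseline TPM across tissues, with designated
#' tissue-specific genes elevated (multiplicative fold) in exactly one
#' tissue, guaranteeing that their tissue Z-score is maximal there.
#'
#' @param genes gene ids (rows).
#' @param tissues tissue names (columns).
#' @param specific optional named character vector: names are gene ids,
#'   values the tissue in which each is elevated.
#' @param fold fold-elevation of specific genes in their tissue.
#' @param seed integer seed.
#' @return gene x tissue numeric matrix of TPM values (>= 0).
#' @export
simulate_tissue_tpm <- function(genes, tissues, specific = NULL,
                                fold = 8, seed = 1L) {
  if (length(genes) < 1L || length(tissues) < 1L)
    stop("simulate_tissue_tpm: genes and tissues must be nonempty")
  set.seed(as.integer(seed))
  tpm <- matrix(exp(rnorm(length(genes) * length(tissues),
                          mean = log(20), sd = 0.5)),
                nrow = length(genes),
                dimnames = list(genes, tissues))
  if (!is.null(specific)) {
    bad <- setdiff(names(specific), genes)
    if (length(bad))
      stop("simulate_tissue_tpm: unknown specific genes: ",
           paste(bad, collapse = ", "))
    bad_t <- setdiff(unname(specific), tissues)
    if (length(bad_t))
      stop("simulate_tissue_tpm: unknown tissues: ",
           paste(bad_t, collapse = ", "))
    for (g in names(specific)) {
      tpm[g, specific[[g]]] <- tpm[g, specific[[g]]] * fold
    }
  }
  tpm
}
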