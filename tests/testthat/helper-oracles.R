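# Independent brute-force oracles used across the suite. These stay
# deliberately naive (enumeration / direct formulas) and never call the
# package's own code paths.

# Shortest-path betweenness by explicit path enumeration over all simple
# paths (feasible for tiny graphs only).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- path
        return(invisible())
      }
      for (nb in which(adj[last, ] > 0)) {
        if (!(nb %in% path)) grow(c(path, nb))
      }
    }
    grow(from)
    out
  }
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    geo <- paths[lens == min(lens)]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_geo <- vapply(geo, function(p) v %in% p, logical(1))
      btw[v] <- btw[v] + sum(on_geo) / length(geo)
    }
  }
  btw
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(assign, maxb) {
    k <- length(assign)
    if (k == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(maxb + 1L)) {
      grow(c(assign, b), max(maxb, b))
    }
  }
  grow(1L, 1L)
  out
}

# Newman modularity of a membership vector on an unweighted graph.
brute_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Maximum modularity over every partition (tiny graphs only).
brute_max_modularity <- function(adj) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) brute_modularity(adj, p), numeric(1)))
}

# Upper-tail hypergeometric by direct combinatorial summation.
brute_hyper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Step-by-step moderated t given hyperparameters (posterior-variance
# formula applied literally, gene by gene).
brute_moderated_t <- function(expr, grp, d0, s0_sq) {
  n1 <- sum(grp); n2 <- sum(!grp)
  v <- 1 / n1 + 1 / n2
  sapply(seq_len(nrow(expr)), function(g) {
    x <- expr[g, grp]; y <- expr[g, !grp]
    fc <- mean(x) - mean(y)
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
    s2p <- if (is.infinite(d0)) s0_sq else
      (d0 * s0_sq + (n1 + n2 - 2) * s2) / (d0 + n1 + n2 - 2)
    fc / sqrt(s2p * v)
  })
}

# Benjamini-Hochberg stepped by hand.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small two-context simulated dataset used by several suites.
tiny_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_genes = 120, n_samples_per_group = 8, n_batches = 2,
                    n_modules = 2, module_size = 20, n_degs = 6,
                    n_rewired = 1, rewired_partners = 5, n_tfs = 2,
                    targets_per_tf = 6, seed = seed, ...)
  simulate_expression(cfg)
}
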