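# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (loops, enumeration, closed forms) kept free of any package
# internals so it can stand as a second route to the same quantity.

# element-by-element signed sum, one sample at a time
oracle_score <- function(x, sig, standardize = FALSE) {
  genes <- sig$entries$gene[sig$entries$gene %in% rownames(x)]
  dirs <- sig$entries$direction[match(genes, sig$entries$gene)]
  v <- x[genes, , drop = FALSE]
  if (standardize) {
    for (g in seq_len(nrow(v))) {
      v[g, ] <- (v[g, ] - mean(v[g, ])) / sd(v[g, ])
    }
  }
  out <- numeric(ncol(x))
  for (s in seq_len(ncol(x))) {
    acc <- 0
    for (g in seq_along(genes)) acc <- acc + dirs[g] * v[g, s]
    out[s] <- acc
  }
  names(out) <- colnames(x)
  out
}

# exhaustive upper-tail hypergeometric: enumerate all C(N, n) draws from a
# universe 1..N whose first K elements are the successes
oracle_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# textbook BH step-up, written as the explicit scan from the largest p
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p2 = 2 * pt(-abs(t), df))
}

# naive O(n^3) agglomerative clustering on a full distance matrix.
# Returns merge heights (in merge order) and the membership vector after
# every merge (so partition at any k can be read off).
oracle_agglomerate <- function(d, linkage = "complete") {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  cluster_dist <- function(a, b) {
    vals <- d[members[[a]], members[[b]], drop = FALSE]
    switch(linkage,
           complete = max(vals),
           single = min(vals),
           average = mean(vals))
  }
  while (length(members) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        dij <- cluster_dist(i, j)
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    memb <- integer(n)
    for (c in seq_along(members)) memb[members[[c]]] <- c
    partitions[[length(partitions) + 1L]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# relabel a partition by order of first appearance so partitions can be
# compared up to cluster relabeling
canonical_partition <- function(v) {
  match(v, unique(v))
}

# tiny deterministic random expression matrix
random_matrix <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%03d", seq_len(n_samples))))
  })
}
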