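# Independent oracles used across the suite.  These deliberately take the
# naive O(n^2) / explicit-loop route so they share no code with the package
# implementation they check.

# Canonical partition labels (smallest member index per block).
canonLabels <- function(membership) {
  as.integer(ave(seq_along(membership), membership, FUN = min))
}

# Brute-force SD partition: all-pairs same-or-adjacent-cell predicate,
# components via igraph.
bruteSdPartition <- function(X, delta) {
  origin <- apply(X, 2L, min)
  cells <- floor(sweep(X, 2L, origin) / delta)
  D <- as.matrix(stats::dist(cells, method = "maximum"))
  adj <- which(upper.tri(D) & D <= 1, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(X), directed = FALSE)
  if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
  canonLabels(igraph::components(g)$membership)
}

# Partition from an edge list via igraph (oracle for union-find).
igraphPartition <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  canonLabels(igraph::components(g)$membership)
}

# Explicit-loop Jaccard over marker sets.
bruteJaccard <- function(a, b) {
  inter <- 0L
  for (v in a) if (any(b == v)) inter <- inter + 1L
  uni <- length(a) + length(b) - inter
  inter / uni
}

# All-pairs Jaccard edge list at threshold t, by explicit loops.
bruteJaccardPairs <- function(markers, t) {
  n <- length(markers)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bruteJaccard(markers[[i]], markers[[j]]) >= t - 1e-12)
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0L, 2L) else out
}

# Purity and F1 by explicit loops over the formulas.
brutePurity <- function(tab) {
  tot <- 0
  for (i in seq_len(nrow(tab))) {
    best <- 0
    for (j in seq_len(ncol(tab))) if (tab[i, j] > best) best <- tab[i, j]
    tot <- tot + best
  }
  tot / sum(tab)
}

bruteF1 <- function(tab) {
  acc <- 0
  for (l in seq_len(ncol(tab))) {
    clsize <- sum(tab[, l])
    best <- 0
    for (c in seq_len(nrow(tab))) {
      R <- tab[c, l] / clsize
      P <- tab[c, l] / sum(tab[c, ])
      f <- if (R + P == 0) 0 else 2 * R * P / (R + P)
      if (f > best) best <- f
    }
    acc <- acc + best
  }
  acc / ncol(tab)
}

# Best (precision, recall) over clusters for one planted component,
# scanning all scales of a result.
bestRecovery <- function(result, labels, component) {
  target <- labels == component
  best <- c(prec = 0, rec = 0, scale = NA)
  for (s in seq_len(nScales(result))) {
    cl <- clusterLabels(result, s)
    for (id in unique(cl[target])) {
      inC <- cl == id
      prec <- sum(inC & target) / sum(inC)
      rec <- sum(inC & target) / sum(target)
      if (min(prec, rec) > min(best["prec"], best["rec"]))
        best <- c(prec = prec, rec = rec, scale = s)
    }
  }
  best
}
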