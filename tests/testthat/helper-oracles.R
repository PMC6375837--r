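# Brute-force oracles used by the tree and permutation tests.

# All unrooted binary topologies on n leaves (n >= 3), built by leaf
# insertion: each tree is a data.frame of edges (node1, node2). Leaves are
# 1..n, internal nodes n+1, n+2, ...
enumerate_topologies <- function(n) {
  base <- data.frame(a = c(n + 1, n + 1, n + 1), b = c(1, 2, 3))
  trees <- list(base)
  next_internal <- n + 2
  for (leaf in seq_len(n)[-(1:3)]) {
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        new <- tr[-e, , drop = FALSE]
        v <- next_internal + (leaf - 4)  # fresh internal node id per level
        new <- rbind(new,
                     data.frame(a = tr$a[e], b = v),
                     data.frame(a = v, b = tr$b[e]),
                     data.frame(a = v, b = leaf))
        out[[length(out) + 1]] <- new
      }
    }
    trees <- out
  }
  trees
}

# Edge-path incidence matrix: rows = leaf pairs (i < j), cols = edges.
path_incidence <- function(tr, n) {
  nodes <- sort(unique(c(tr$a, tr$b)))
  adj <- lapply(nodes, function(v) integer(0))
  names(adj) <- nodes
  for (e in seq_len(nrow(tr))) {
    adj[[as.character(tr$a[e])]] <- c(adj[[as.character(tr$a[e])]], e)
    adj[[as.character(tr$b[e])]] <- c(adj[[as.character(tr$b[e])]], e)
  }
  other <- function(e, v) if (tr$a[e] == v) tr$b[e] else tr$a[e]
  pairs <- t(combn(n, 2))
  inc <- matrix(0, nrow(pairs), nrow(tr))
  for (p in seq_len(nrow(pairs))) {
    # DFS path from leaf i to leaf j
    from <- pairs[p, 1]; to <- pairs[p, 2]
    stack <- list(list(v = from, path = integer(0), prev = -1))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur$v == to) { inc[p, cur$path] <- 1; break }
      for (e in adj[[as.character(cur$v)]]) {
        if (e == cur$prev) next
        stack[[length(stack) + 1]] <-
          list(v = other(e, cur$v), path = c(cur$path, e), prev = e)
      }
    }
  }
  inc
}

# Least-squares branch lengths for a topology against a distance matrix;
# returns the fitted path-length matrix and the residual sum of squares.
ls_fit_topology <- function(tr, d) {
  n <- nrow(d)
  inc <- path_incidence(tr, n)
  dv <- d[t(combn(n, 2))]
  fit <- lm.fit(inc, dv)
  fitted <- inc %*% fit$coefficients
  list(rss = sum((fitted - dv)^2), lengths = fit$coefficients,
       fitted = as.vector(fitted))
}

# Exhaustive Mantel: r for every permutation of d2's labels.
mantel_exhaustive <- function(d1, d2) {
  n <- nrow(d1)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  perms <- combinat_perms(n)
  vapply(perms, function(p) cor(v1, d2[p, p][ut]), numeric(1))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# A random additive distance matrix from a random binary tree.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  d[ord, ord]
}

# Hand-computable IndVal for one OTU (Dufrene-Legendre formulas).
indval_by_hand <- function(x, classes) {
  mu <- tapply(x, classes, mean)
  a <- mu / sum(mu)
  b <- tapply(x > 0, classes, mean)
  as.vector(a * b)
}
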