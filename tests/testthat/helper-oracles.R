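# Independent oracles and small fixture builders used across the suite.

# random symmetric PLI-like matrix with entries in (lo, hi), zero diagonal
rand_pli_matrix <- function(n, lo = 0.05, hi = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  dimnames(m) <- list(paste0("E", seq_len(n)), paste0("E", seq_len(n)))
  m
}

# decode a Pruefer sequence into a tree edge list (n = length(seq) + 2)
prufer_decode <- function(pruefer, n) {
  degree <- rep.int(1L, n)
  for (v in pruefer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = n - 1, ncol = 2)
  ptr <- 0L
  for (v in pruefer) {
    leaf <- which(degree == 1L)[1]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, v)
    degree[leaf] <- 0L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

# exhaustive minimum total 1/PLI over ALL spanning trees of the complete
# graph (Cayley enumeration via Pruefer sequences); n <= 7 in practice
min_spanning_total_bruteforce <- function(m) {
  n <- nrow(m)
  d <- 1 / m
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[r, ], n)
    tot <- sum(d[e])
    if (tot < best) best <- tot
  }
  best
}

# raw betweenness by explicit path enumeration: for every unordered node
# pair walk the unique tree path and count interior visits
bc_bruteforce <- function(tree) {
  n <- tree$n
  adj <- vector("list", n)
  for (k in seq_len(nrow(tree$edges))) {
    i <- tree$edges$i[k]; j <- tree$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  path_between <- function(u, v) {
    parent <- rep.int(0L, n)
    parent[u] <- -1L
    queue <- u
    while (length(queue) > 0) {
      w <- queue[1]; queue <- queue[-1]
      if (w == v) break
      for (x in adj[[w]]) {
        if (parent[x] == 0L) {
          parent[x] <- w
          queue <- c(queue, x)
        }
      }
    }
    path <- v
    while (path[1] != u) path <- c(parent[path[1]], path)
    path
  }
  bc <- numeric(n)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      p <- path_between(u, v)
      interior <- p[-c(1, length(p))]
      bc[interior] <- bc[interior] + 1
    }
  }
  bc
}

# random tree on n nodes (uniform via Pruefer), returned as spanning_tree
rand_tree <- function(n) {
  e <- if (n == 2) matrix(c(1L, 2L), 1) else {
    prufer_decode(sample.int(n, n - 2, replace = TRUE), n)
  }
  pli <- stats::runif(n - 1, 0.2, 1)
  structure(list(
    n = n,
    edges = tibble::tibble(i = pmin(e[, 1], e[, 2]), j = pmax(e[, 1], e[, 2]),
                           pli = pli, dist = 1 / pli),
    labels = NULL
  ), class = "spanning_tree")
}

# spanning tree from an explicit edge list (unit PLI weights by default)
tree_from_edges <- function(n, edges, pli = rep(1, nrow(edges))) {
  structure(list(
    n = n,
    edges = tibble::tibble(i = as.integer(edges[, 1]),
                           j = as.integer(edges[, 2]),
                           pli = pli, dist = 1 / pli),
    labels = NULL
  ), class = "spanning_tree")
}

# subject-level metric table under the null: one metric with no group or
# condition effect, lognormal noise, subject-level covariates
make_null_table <- function(n_per_group = c(eCI = 10, lCI = 10, NH = 10),
                            noise = function(n) stats::rnorm(n)) {
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  tibble::tibble(
    subject_id = rep(sprintf("S%03d", seq_len(n)), each = 2),
    group = rep(groups, each = 2),
    condition = rep(c("EC", "EO"), n),
    age = rep(stats::rnorm(n, 9, 2), each = 2),
    iq = rep(stats::rnorm(n, 110, 8), each = 2),
    value = exp(noise(2 * n))
  )
}
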