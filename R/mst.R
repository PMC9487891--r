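# Minimum spanning tree backbone of a PLI connectivity matrix. Link
# weights are 1/PLI, so the MST keeps the strongest couplings; with N
# nodes it always has N - 1 links, making topology comparable across
# subjects without a density threshold.

#' Build the minimum spanning tree of a PLI matrix
#'
#' Kruskal's algorithm on distances `1/PLI`: edges sorted by ascending
#' distance (ties broken by ascending `(i, j)` index, so the result is
#' deterministic) are accepted unless they close a cycle, until `N - 1`
#' links join all `N` nodes. Zero-PLI entries are floored at `eps` (their
#' distance becomes `1/eps`), which guarantees connectivity while such
#' links are only chosen when no positive-PLI alternative exists; an
#' all-zero matrix is an error.
#'
#' @param m Symmetric channels x channels PLI matrix (values in \[0, 1\]).
#' @param eps Floor applied to zero PLI entries.
#' @return An object of class `spanning_tree`: list with `n` and an edge
#'   tibble (`i`, `j`, `pli`, `dist`).
#' @export
build_mst <- function(m, eps = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be square", call. = FALSE)
  n <- nrow(m)
  if (n < 2) stop("need at least two nodes", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("`m` must be symmetric", call. = FALSE)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  pli <- m[ut]
  if (all(pli == 0)) stop("all-zero connectivity matrix", call. = FALSE)
  w <- pmax(pli, eps)
  ord <- order(1 / w, ut[, 1], ut[, 2])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  take <- integer(n - 1)
  k <- 0
  for (e in ord) {
    ri <- find(ut[e, 1]); rj <- find(ut[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1
      take[k] <- e
      if (k == n - 1) break
    }
  }
  edges <- tibble::tibble(
    i = as.integer(ut[take, 1]), j = as.integer(ut[take, 2]),
    pli = pli[take], dist = 1 / w[take]
  )
  structure(list(n = n, edges = edges, labels = colnames(m)),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d links, total 1/PLI distance %.4g\n",
              x$n, nrow(x$edges), sum(x$edges$dist)))
  invisible(x)
}

tree_adjacency <- function(t) {
  adj <- vector("list", t$n)
  for (k in seq_len(nrow(t$edges))) {
    i <- t$edges$i[k]; j <- t$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop distances from one node by BFS
bfs_hops <- function(adj, start, n) {
  dist <- rep.int(-1L, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[dist[nb] < 0]
    dist[new] <- dist[v] + 1L
    queue <- c(queue, new)
  }
  dist
}

# betweenness as raw counts of unordered node pairs whose unique tree path
# passes through the node: ((n-1)^2 - sum of squared component sizes after
# deleting the node) / 2, via rooted subtree sizes
tree_betweenness <- function(t, adj = tree_adjacency(t)) {
  n <- t$n
  parent <- rep.int(0L, n)
  order_v <- integer(n)
  parent[1] <- -1L
  order_v[1] <- 1L
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order_v[head]
    for (u in adj[[v]]) {
      if (parent[u] == 0L) {
        parent[u] <- v
        tail <- tail + 1L
        order_v[tail] <- u
      }
    }
    head <- head + 1L
  }
  size <- rep.int(1L, n)
  for (k in rev(seq_len(n))) {
    v <- order_v[k]
    if (parent[v] > 0L) size[parent[v]] <- size[parent[v]] + size[v]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    child_sizes <- size[setdiff(adj[[v]], parent[v])]
    comps <- c(child_sizes, n - 1 - sum(child_sizes))
    comps <- comps[comps > 0]
    bc[v] <- ((n - 1)^2 - sum(comps^2)) / 2
  }
  bc
}

#' Topology metric panel of a spanning tree
#'
#' Computes the tree metric panel: maximum degree, leaf number L (nodes of
#' degree 1), hop-based diameter / mean eccentricity / radius, PLI-weight
#' node strengths (max and mean), raw-count betweenness centrality (max
#' and median over nodes), hop-based closeness centrality (max and
#' median), degree-distribution broadness `kappa = <k^2>/<k>`, and tree
#' hierarchy `Th = L / (2 * M * BC_max)` with `M = N - 1` links. A
#' compatibility value `reported_diameter = N + 1 - L` is also emitted:
#' the leaf-complement quantity that the published metric panels tabulate
#' under the name diameter.
#'
#' @param t A [build_mst()] result.
#' @return One-row tibble of the metric panel.
#' @export
tree_metrics <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  n <- t$n
  if (n < 2) stop("tree must have at least two nodes", call. = FALSE)
  deg <- tabulate(c(t$edges$i, t$edges$j), nbins = n)
  strength <- numeric(n)
  for (k in seq_len(nrow(t$edges))) {
    strength[t$edges$i[k]] <- strength[t$edges$i[k]] + t$edges$pli[k]
    strength[t$edges$j[k]] <- strength[t$edges$j[k]] + t$edges$pli[k]
  }
  adj <- tree_adjacency(t)
  ecc <- numeric(n)
  closeness <- numeric(n)
  for (v in seq_len(n)) {
    h <- bfs_hops(adj, v, n)
    ecc[v] <- max(h)
    closeness[v] <- 1 / sum(h)
  }
  bc <- tree_betweenness(t, adj)
  leaf <- sum(deg == 1)
  m_links <- n - 1
  tibble::tibble(
    degree_max = max(deg),
    leaf = leaf,
    diameter = max(ecc),
    reported_diameter = n + 1 - leaf,
    eccentricity_mean = mean(ecc),
    radius = min(ecc),
    strength_max = max(strength),
    strength_mean = mean(strength),
    bc_max = max(bc),
    bc_median = stats::median(bc),
    cc_max = max(closeness),
    cc_median = stats::median(closeness),
    kappa = mean(deg^2) / mean(deg),
    tree_hierarchy = leaf / (2 * m_links * max(bc))
  )
}

#' Per-epoch MST metric panel from a PLI array
#'
#' Builds the spanning tree of every epoch's connectivity matrix and
#' stacks the metric panels.
#'
#' @param pli_arr A `pli_array` from [pli_matrix()].
#' @param eps Zero-PLI floor passed to [build_mst()].
#' @return Tibble with an `epoch` column followed by the metric panel.
#' @export
epoch_tree_metrics <- function(pli_arr, eps = 1e-12) {
  stopifnot(inherits(pli_arr, "pli_array"))
  rows <- purrr::map(seq_len(dim(pli_arr)[1]), function(e) {
    dplyr::bind_cols(tibble::tibble(epoch = e),
                     tree_metrics(build_mst(pli_epoch(pli_arr, e), eps)))
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-epoch metrics to the subject level
#'
#' Arithmetic mean of every metric across epochs within each combination
#' of the grouping columns (typically subject, condition and band). All
#' rows entering one aggregate must share a single band and condition;
#' grouping by those columns enforces this.
#'
#' @param df Tibble of per-epoch metrics with grouping columns.
#' @param by Character vector of grouping columns present in `df`.
#' @return Tibble of means, one row per group, with an `n_epochs` column.
#' @export
aggregate_epochs <- function(df, by = intersect(c("subject_id", "condition",
                                                  "band"), names(df))) {
  stopifnot(is.data.frame(df))
  if (nrow(df) < 1) stop("no epoch metrics to aggregate", call. = FALSE)
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], c(by, "epoch"))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_epochs = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols), mean),
      .groups = "drop"
    )
}
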