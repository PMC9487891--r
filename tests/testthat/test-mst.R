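test_that("two-node matrix yields the single edge with distance 1/PLI", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2)
  t <- build_mst(m)
  expect_equal(nrow(t$edges), 1)
  expect_equal(t$edges$dist, 2)
})

test_that("four-node example picks the strong chain", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.9; m[2, 3] <- 0.8; m[3, 4] <- 0.7
  m[1, 3] <- 0.1; m[1, 4] <- 0.2; m[2, 4] <- 0.3
  m <- m + t(m)
  t <- build_mst(m)
  got <- t$edges[order(t$edges$i, t$edges$j), c("i", "j")]
  expect_equal(as.matrix(got), cbind(i = 1:3, j = 2:4), ignore_attr = TRUE)
})

test_that("kruskal equals exhaustive spanning-tree enumeration and igraph", {
  set.seed(41)
  for (rep_i in 1:20) {
    n <- sample(4:7, 1)
    m <- rand_pli_matrix(n)
    t <- build_mst(m)
    expect_equal(sum(t$edges$dist), min_spanning_total_bruteforce(m),
                 tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(1 / m, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ig <- igraph::mst(g, algorithm = "prim")
    expect_equal(sum(t$edges$dist),
                 sum(igraph::E(ig)$weight), tolerance = 1e-12)
  }
})

test_that("zero-PLI entries are floored, an all-zero matrix errors", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.5
  t <- build_mst(m)                 # still spans via the epsilon floor
  expect_equal(nrow(t$edges), 2)
  expect_true(any(t$edges$dist > 1e11))
  expect_error(build_mst(matrix(0, 3, 3)), "all-zero")
  expect_error(build_mst(matrix(1, 2, 3)), "square")
})

test_that("tie-breaking makes equal-weight trees deterministic", {
  m <- matrix(0.5, 4, 4); diag(m) <- 0
  t1 <- build_mst(m); t2 <- build_mst(m)
  expect_identical(t1$edges, t2$edges)
  # ascending (i, j) order among ties: the star at node 1
  expect_equal(t1$edges$i, rep(1L, 3))
})

test_that("path and star hand computations match the metric panel", {
  path4 <- tree_metrics(tree_from_edges(4, cbind(1:3, 2:4)))
  expect_equal(path4$leaf, 2)
  expect_equal(path4$diameter, 3)
  expect_equal(path4$radius, 2)
  expect_equal(path4$kappa, 10 / 6)
  expect_equal(path4$bc_max, 2)
  expect_equal(path4$tree_hierarchy, 2 / (2 * 3 * 2))
  expect_equal(path4$reported_diameter, 4 + 1 - 2)

  star5 <- tree_metrics(tree_from_edges(5, cbind(rep(1, 4), 2:5)))
  expect_equal(star5$leaf, 4)
  expect_equal(star5$diameter, 2)
  expect_equal(star5$radius, 1)
  expect_equal(star5$kappa, 2.5)
  expect_equal(star5$bc_max, choose(4, 2))
  expect_equal(star5$tree_hierarchy, 4 / (2 * 4 * 6))
})

test_that("betweenness matches brute-force path counting on random trees", {
  set.seed(77)
  for (n in c(5, 12, 30)) {
    t <- rand_tree(n)
    expect_equal(mstnet:::tree_betweenness(t), bc_bruteforce(t))
  }
})

test_that("tree metric invariants hold on random trees", {
  set.seed(13)
  for (rep_i in 1:25) {
    n <- sample(5:60, 1)
    t <- rand_tree(n)
    mt <- tree_metrics(t)
    deg <- tabulate(c(t$edges$i, t$edges$j), n)
    expect_equal(sum(deg), 2 * (n - 1))
    expect_gte(mt$kappa, mean(deg))
    expect_true(mt$leaf >= 2 && mt$leaf <= n - 1)
    expect_lte(mt$radius, mt$eccentricity_mean)
    expect_lte(mt$eccentricity_mean, mt$diameter)
    expect_lte(mt$diameter, 2 * mt$radius)
    # Th identity: Th * 2 * M * bc_max = L exactly
    expect_equal(mt$tree_hierarchy * 2 * (n - 1) * mt$bc_max, mt$leaf)
  }
})

test_that("path minimizes and star maximizes leaf and kappa among trees", {
  n <- 12
  path <- tree_metrics(tree_from_edges(n, cbind(1:(n - 1), 2:n)))
  star <- tree_metrics(tree_from_edges(n, cbind(rep(1, n - 1), 2:n)))
  expect_equal(path$leaf, 2)           # minimum possible
  expect_equal(star$leaf, n - 1)       # maximum possible
  expect_equal(star$kappa, n / 2)
  set.seed(99)
  for (rep_i in 1:10) {
    mt <- tree_metrics(rand_tree(n))
    expect_gte(mt$leaf, path$leaf)
    expect_lte(mt$leaf, star$leaf)
    expect_gte(mt$kappa, path$kappa - 1e-12)
    expect_lte(mt$kappa, star$kappa + 1e-12)
  }
})

test_that("strength uses PLI weights on tree edges", {
  t <- tree_from_edges(3, cbind(c(1, 2), c(2, 3)), pli = c(0.9, 0.6))
  mt <- tree_metrics(t)
  expect_equal(mt$strength_max, 1.5)         # node 2: 0.9 + 0.6
  expect_equal(mt$strength_mean, (0.9 + 1.5 + 0.6) / 3)
})

test_that("epoch aggregation averages each metric", {
  df <- tibble::tibble(
    subject_id = "S1", condition = "EC", band = "theta",
    epoch = 1:2, leaf = c(60, 70), kappa = c(3, 4)
  )
  agg <- aggregate_epochs(df)
  expect_equal(agg$leaf, 65)
  expect_equal(agg$kappa, 3.5)
  expect_equal(agg$n_epochs, 2)
  same <- aggregate_epochs(dplyr::mutate(df, leaf = 60, kappa = 3))
  expect_equal(same$leaf, 60)
  expect_error(aggregate_epochs(df[0, ]), "no epoch metrics")
})

test_that("epoch-level aggregation stabilizes metrics roughly as 1/sqrt(k)", {
  sp <- coupling_spec("alpha", data.frame(i = 1, j = 2:5, delta = pi / 2,
                                          kappa = 4), noise_sd = 0.3)
  leafs <- vapply(1:30, function(s) {
    rec <- generate_recording(sp, 10, 8, 128, seed = 7000 + s)
    pli <- pli_matrix(instantaneous_phase(epoch_and_select(rec, 2, NULL)))
    epoch_tree_metrics(pli)$leaf
  }, numeric(4))
  sd_single <- stats::sd(leafs[1, ])
  sd_mean4 <- stats::sd(colMeans(leafs))
  expect_lt(sd_mean4, sd_single)
})
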