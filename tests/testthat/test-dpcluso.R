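test_that("cluster density matches its definition on hand cases and random graphs", {
  tri <- two_triangles()
  expect_equal(cluster_density(c("A", "B", "C"), tri), 1.0)
  path <- net_from_pairs("A", "B", "B", "C")
  expect_equal(cluster_density(c("A", "B", "C"), path), 2 / 3)
  expect_error(cluster_density("A", tri), "two members")

  for (seed in 1:5) {
    net <- random_net(10, 0.5, seed)
    set.seed(seed + 100)
    mem <- sample(net$nodes, 6)
    m <- length(mem)
    expect_equal(cluster_density(mem, net),
                 oracle_internal_edges(mem, net) / (m * (m - 1) / 2))
  }
})

test_that("cluster property follows |E_nk| / (d_k |N_k|)", {
  # 4-node cluster of density 0.5 (path a-b-c-d), outside node x with 2 edges in
  net <- net_from_pairs("a", "b", "b", "c", "c", "d", "x", "a", "x", "c")
  expect_equal(cluster_property("x", c("a", "b", "c", "d"), net), 1.0)
  # no edges into the cluster -> 0
  net2 <- net_from_pairs("a", "b", "b", "c", "c", "a", "x", "y")
  expect_equal(cluster_property("x", c("a", "b", "c"), net2), 0.0)
  # adjacent to every member of a complete triangle -> 3/(1*3) = 1
  net3 <- net_from_pairs("a", "b", "b", "c", "c", "a",
                         "x", "a", "x", "b", "x", "c")
  expect_equal(cluster_property("x", c("a", "b", "c"), net3), 1.0)
  expect_error(cluster_property("a", c("a", "b"), net3), "outside")
})

test_that("hand-worked fixtures cluster exactly as the greedy rule dictates", {
  cs <- cluster_graph(two_triangles(), d_min = 0.8, cp_min = 0.5)
  expect_length(cs$clusters, 2)
  expect_equal(lapply(cs$clusters, `[[`, "members"),
               list(c("A", "B", "C"), c("D", "E", "F")))
  expect_equal(vapply(cs$clusters, `[[`, numeric(1), "density"), c(1, 1))

  # star: pairs only, the hub overlaps all three clusters
  cs2 <- cluster_graph(star4(), d_min = 0.8, cp_min = 0.5)
  expect_equal(lapply(cs2$clusters, `[[`, "members"),
               list(c("c", "l1"), c("c", "l2"), c("c", "l3")))

  # K5 absorbs everything in one cluster at d_min 0.5
  cs3 <- cluster_graph(complete_net(5), d_min = 0.5, cp_min = 0.5)
  expect_length(cs3$clusters, 1)
  expect_length(cs3$clusters[[1]]$members, 5)

  expect_error(cluster_graph(two_triangles(), d_min = 0), "d_min")
})

test_that("clustering invariants hold on random graphs", {
  for (seed in 1:50) {
    n <- sample(6:16, 1)
    net <- random_net(n, stats::runif(1, 0.2, 0.6), seed)
    d_min <- sample(c(0.5, 0.6, 0.7, 0.8, 0.9), 1)
    cs <- cluster_graph(net, d_min, cp_min = 0.5)
    covered <- character(0)
    for (i in seq_along(cs$clusters)) {
      cl <- cs$clusters[[i]]
      m <- length(cl$members)
      # stored density is exact and >= d_min
      expect_equal(cl$density,
                   oracle_internal_edges(cl$members, net) / (m * (m - 1) / 2))
      expect_gte(cl$density, d_min)
      # maximality: no neighbor passes both acceptance conditions
      nbrs <- unique(c(
        net$edges$to[net$edges$from %in% cl$members],
        net$edges$from[net$edges$to %in% cl$members]))
      for (v in setdiff(nbrs, cl$members)) {
        e_in <- sum((net$edges$from == v & net$edges$to %in% cl$members) |
                      (net$edges$to == v & net$edges$from %in% cl$members))
        dens_new <- (cl$internal_edges + e_in) / ((m + 1) * m / 2)
        cp <- e_in / (cl$density * m)
        expect_false(dens_new >= d_min && cp >= 0.5,
                     info = sprintf("seed %d: cluster extensible by %s", seed, v))
      }
      covered <- union(covered, cl$members)
    }
    # coverage: every non-isolated node (all nodes here) is in some cluster
    expect_setequal(covered, net$nodes)
  }
})

test_that("clustering is deterministic across repeated runs", {
  net <- random_net(20, 0.35, 99)
  a <- cluster_graph(net, 0.6, 0.5)
  b <- cluster_graph(net, 0.6, 0.5)
  expect_identical(a, b)
})

test_that("higher density thresholds yield at least as many clusters on planted networks", {
  # statistical trend over seeds, not a per-instance guarantee
  diffs <- vapply(1:20, function(s) {
    ds <- generate_synthetic(synthetic_spec(
      n_background = 40, n_modules = 2, module_size = c(10, 14),
      known_frac_background = 0.05, seed = s))
    lo <- length(cluster_graph(ds$network, 0.5, 0.5)$clusters)
    hi <- length(cluster_graph(ds$network, 0.9, 0.5)$clusters)
    hi - lo
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs >= 0), 0.8)
})
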