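# Group mean network, thresholding, weighted centralities, permutation
# nulls, layout and export.

test_that("mean network averages present ratings per ordered pair", {
  recs <- toy_records()
  net <- build_mean_network(recs)
  # participants a and b both rated (1,13): (6 + 5) / 2
  e <- net$edges
  w_1_13 <- e$weight[e$from == 1 & e$to == 13]
  expect_equal(w_1_13, 5.5)
  expect_equal(e$n[e$from == 1 & e$to == 13], 2L)
  # (2,13) rated by participant a only
  expect_equal(e$weight[e$from == 2 & e$to == 13], 8)
  # min_n filters low-support edges
  net2 <- build_mean_network(recs, min_n = 2L)
  expect_true(all(net2$edges$n >= 2))
  expect_false(any(net2$edges$from == 2))
  # node frequency attribute: mean over all participants (a: 2, b: 1)
  expect_equal(net$nodes$frequency[net$nodes$id == 1], 1.5)
})

test_that("thresholding shrinks edges monotonically and respects strictness", {
  set.seed(20)
  net <- random_weighted_net(10)
  expect_identical(threshold_network(net, 0, strict = FALSE)$edges,
                   net$edges)
  expect_identical(nrow(threshold_network(net, 10, strict = TRUE)$edges), 0L)
  prev <- nrow(net$edges)
  for (cc in c(2, 4.5, 7, 9)) {
    cur <- nrow(threshold_network(net, cc)$edges)
    expect_lte(cur, prev)
    prev <- cur
  }
  # strict vs non-strict at an attained weight
  w0 <- net$edges$weight[1]
  n_strict <- nrow(threshold_network(net, w0, strict = TRUE)$edges)
  n_loose <- nrow(threshold_network(net, w0, strict = FALSE)$edges)
  expect_identical(n_loose - n_strict, 1L)
  # brute-force filter agreement at 4.5
  expect_identical(threshold_network(net, 4.5)$edges$weight,
                   net$edges$weight[net$edges$weight > 4.5])
})

test_that("weighted degrees are directed sums with isolated-node zeros", {
  net <- symptom_network(tibble::tibble(id = 1:4),
                         data.frame(from = 1, to = 2, weight = 6))
  d <- weighted_degrees(net)
  expect_equal(d$outdegree, c(6, 0, 0, 0))
  expect_equal(d$indegree, c(0, 6, 0, 0))
  # complete digraph with uniform weights: out = in = (n-1) w
  pairs <- expand.grid(from = 1:5, to = 1:5)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$weight <- 2
  netc <- symptom_network(tibble::tibble(id = 1:5), pairs)
  dc <- weighted_degrees(netc)
  expect_true(all(dc$outdegree == 8) && all(dc$indegree == 8))
  # random fixture equals brute-force sums, and mass balance holds
  set.seed(21)
  netr <- random_weighted_net(8)
  dr <- weighted_degrees(netr)
  for (i in 1:8) {
    expect_equal(dr$outdegree[i],
                 sum(netr$edges$weight[netr$edges$from == i]))
  }
  expect_equal(sum(dr$outdegree), sum(netr$edges$weight))
  expect_equal(sum(dr$indegree), sum(netr$edges$weight))
})

test_that("weighted betweenness matches structural expectations", {
  # chain 1 -> 2 -> 3: only the middle node lies on a path
  net <- symptom_network(tibble::tibble(id = 1:3),
                         data.frame(from = c(1, 2), to = c(2, 3),
                                    weight = c(3, 7)))
  expect_equal(betweenness_weighted(net)$betweenness, c(0, 1, 0))
  # complete digraph, uniform weights: direct edges always minimal
  pairs <- expand.grid(from = 1:5, to = 1:5)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$weight <- 4
  netc <- symptom_network(tibble::tibble(id = 1:5), pairs)
  expect_equal(betweenness_weighted(netc)$betweenness, rep(0, 5))
  # a strong two-hop route beats a weak direct edge
  net2 <- symptom_network(tibble::tibble(id = 1:3),
                          data.frame(from = c(1, 1, 2), to = c(3, 2, 3),
                                     weight = c(1, 9, 9)))
  expect_equal(betweenness_weighted(net2)$betweenness[2], 1)
})

test_that("betweenness equals the exhaustive path oracle and igraph", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    net <- random_weighted_net(n, p_edge = 0.5)
    W <- net_weight_matrix(net)
    got <- betweenness_weighted(net)$betweenness
    expect_equal(got, oracle_betweenness(W), tolerance = 1e-9)
    # independent cross-check: igraph on inverse-weight costs
    if (nrow(net$edges) > 0) {
      g <- as_igraph(net)
      ig <- unname(igraph::betweenness(g, directed = TRUE,
                                       weights = 1 / igraph::E(g)$weight))
      expect_equal(got, ig, tolerance = 1e-9)
    }
  }
})

test_that("unit-weight betweenness equals the unweighted measure", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    net <- random_weighted_net(n, p_edge = 0.35)
    net$edges$weight <- rep(1, nrow(net$edges))
    got <- betweenness_weighted(net)$betweenness
    g <- as_igraph(net)
    ig <- unname(igraph::betweenness(g, directed = TRUE, weights = NA))
    expect_equal(got, ig, tolerance = 1e-9)
  }
})

test_that("zero-weight edges are excluded from paths", {
  net <- symptom_network(tibble::tibble(id = 1:3),
                         data.frame(from = c(1, 2), to = c(2, 3),
                                    weight = c(0, 5)))
  expect_equal(betweenness_weighted(net)$betweenness, c(0, 0, 0))
})

test_that("permutation null is invariant, deterministic and monotone", {
  pairs <- expand.grid(from = 1:6, to = 1:6)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$weight <- 3
  net <- symptom_network(tibble::tibble(id = 1:6), pairs)
  rep1 <- permutation_null(net, n_perm = 100, seed = 1)
  # equal weights: permuting changes nothing; zero-width intervals, no flags
  expect_true(all(rep1$p2.5 == rep1$p97.5))
  expect_false(any(rep1$extreme))
  # determinism
  set.seed(33)
  netr <- random_weighted_net(7)
  a <- permutation_null(netr, n_perm = 100, seed = 42)
  b <- permutation_null(netr, n_perm = 100, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # percentiles are monotone in the level
  expect_true(all(a$p2.5 <= a$p50 & a$p50 <= a$p97.5))
  # rewire_pairs mode runs and reports the same shape
  c_ <- permutation_null(netr, n_perm = 100, seed = 42, mode = "rewire_pairs")
  expect_identical(dim(as.data.frame(c_)), dim(as.data.frame(a)))
})

test_that("a dominant hub is flagged for outdegree", {
  # node 1 sends maximal-weight edges to everyone; the rest share weak edges
  edges <- rbind(
    data.frame(from = 1, to = 2:8, weight = 10),
    data.frame(from = 2:8, to = c(3:8, 2), weight = 0.5)
  )
  net <- symptom_network(tibble::tibble(id = 1:8), edges)
  rep_ <- permutation_null(net, n_perm = 1000, seed = 7)
  out1 <- rep_[rep_$measure == "outdegree" & rep_$id == 1, ]
  expect_true(out1$extreme)
  expect_gt(out1$observed, out1$p97.5)
})

test_that("layout is seeded, centered and clusters connected nodes", {
  set.seed(24)
  # a mutually connected triad plus an isolated node
  edges <- data.frame(from = c(1, 2, 3, 2, 3, 1), to = c(2, 3, 1, 1, 2, 3),
                      weight = 8)
  net <- symptom_network(tibble::tibble(id = 1:4), edges)
  xy1 <- layout_fruchterman_reingold(net, seed = 5)
  xy2 <- layout_fruchterman_reingold(net, seed = 5)
  expect_identical(xy1, xy2)
  expect_equal(colMeans(xy1), c(x = 0, y = 0))
  triad <- xy1[1:3, , drop = FALSE]
  d_triad <- mean(dist(triad))
  d_iso <- mean(sqrt(rowSums(sweep(triad, 2, xy1[4, ])^2)))
  expect_lt(d_triad, d_iso)
  # single node sits at the origin
  net1 <- symptom_network(tibble::tibble(id = 1L),
                          data.frame(from = integer(0), to = integer(0),
                                     weight = numeric(0)))
  expect_equal(unname(layout_fruchterman_reingold(net1, seed = 1)[1, ]),
               c(0, 0))
})

test_that("exports write readable GraphML and edge lists", {
  set.seed(25)
  net <- random_weighted_net(6)
  gpath <- withr::local_tempfile(fileext = ".graphml")
  epath <- withr::local_tempfile(fileext = ".csv")
  write_network_graphml(net, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight))
  write_edge_list(net, epath)
  back <- read.csv(epath)
  expect_identical(nrow(back), nrow(net$edges))
  expect_named(back, c("source", "target", "weight", "n"))
})
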