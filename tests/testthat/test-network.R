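test_that("thresholds are strict and edges imply nodes", {
  # 20 patients with hand-set prevalences
  m <- matrix(0L, 20, 3, dimnames = list(paste0("p", 1:20), c("A", "B", "C")))
  m[1:10, "A"] <- 1L          # 50%
  m[1:6, "B"] <- 1L           # 30%, co-prevalence with A = 30%
  m[1, "C"] <- 1L             # exactly 5%
  net <- build_network(m, rownames(m), 0.05, 0.05)
  expect_setequal(net$nodes$phenotype, c("A", "B"))   # C excluded at 5.0%
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$coprevalence, 0.3)
  expect_true(all(c(net$edges$p1, net$edges$p2) %in% net$nodes$phenotype))
  # hand enumeration on a random toy matrix
  set.seed(42)
  m2 <- matrix(rbinom(20 * 6, 1, 0.4), 20, 6,
               dimnames = list(paste0("q", 1:20), paste0("P", 1:6)))
  net2 <- build_network(m2, rownames(m2), 0.2, 0.2)
  for (i in 1:5) for (j in (i + 1):6) {
    co <- mean(m2[, i] & m2[, j])
    present <- any(net2$edges$p1 == paste0("P", i) &
                     net2$edges$p2 == paste0("P", j))
    expect_equal(present, co > 0.2 & mean(m2[, i]) > 0.2 & mean(m2[, j]) > 0.2)
  }
  expect_error(build_network(m, character(0)), "empty")
})

test_that("threshold monotonicity: raising thresholds never adds elements", {
  set.seed(14)
  m <- matrix(rbinom(50 * 10, 1, 0.3), 50, 10,
              dimnames = list(paste0("p", 1:50), paste0("P", 1:10)))
  lo <- build_network(m, rownames(m), 0.05, 0.05)
  hi <- build_network(m, rownames(m), 0.25, 0.25)
  expect_true(all(hi$nodes$phenotype %in% lo$nodes$phenotype))
  expect_true(all(paste(hi$edges$p1, hi$edges$p2) %in%
                    paste(lo$edges$p1, lo$edges$p2)))
})

test_that("triangle and path graphs have the hand-derived metric values", {
  tri <- matrix(0L, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  tri[upper.tri(tri)] <- 1L; tri <- tri + t(tri)
  mt <- node_metrics(tri)
  expect_equal(mt$degree, rep(2L, 3))
  expect_equal(mt$clustering_coefficient, rep(1, 3))
  expect_equal(mt$eccentricity, rep(1, 3))
  expect_equal(mt$radiality, rep(1, 3))
  expect_equal(mt$stress, rep(0, 3))
  expect_equal(mt$betweenness_centrality, rep(0, 3))
  expect_equal(mt$neighborhood_connectivity, rep(2, 3))
  expect_equal(mt$topological_coefficient, rep(1, 3))
  # 5-node path a-b-c-d-e: stress(c) counts (a,d),(a,e),(b,d),(b,e)
  pathg <- matrix(0L, 5, 5, dimnames = rep(list(letters[1:5]), 2))
  for (i in 1:4) pathg[i, i + 1] <- pathg[i + 1, i] <- 1L
  mp <- node_metrics(pathg)
  expect_equal(mp$stress[3], 4)
  expect_equal(mp$stress, c(0, 3, 4, 3, 0))
  expect_equal(mp$average_shortest_path_length[1], mean(1:4))
  # eccentricity >= aspl within a connected component
  expect_true(all(mp$eccentricity >= mp$average_shortest_path_length))
})

test_that("isolated-node conventions hold", {
  adj <- matrix(0L, 3, 3, dimnames = rep(list(c("i", "j", "k")), 2))
  adj["i", "j"] <- adj["j", "i"] <- 1L
  mt <- node_metrics(adj)
  k <- mt[mt$phenotype == "k", ]
  expect_equal(k$degree, 0L)
  expect_equal(k$closeness_centrality, 0)
  expect_equal(k$eccentricity, 0)
  expect_equal(k$average_shortest_path_length, 0)
  expect_equal(k$radiality, 1)
  expect_equal(k$neighborhood_connectivity, 0)
})

test_that("all ten metrics match the brute-force oracle on random graphs", {
  set.seed(77)
  for (i in 1:12) {
    nv <- sample(4:8, 1)
    adj <- random_adjacency(nv, runif(1, 0.25, 0.7))
    mine <- node_metrics(adj)
    ref <- oracle_node_metrics(adj)
    for (col in names(ref))
      expect_equal(mine[[col]], ref[[col]], tolerance = 1e-12, label = col)
  }
})

test_that("stress conservation: total stress counts internal path vertices", {
  set.seed(8)
  for (i in 1:5) {
    adj <- random_adjacency(7, 0.4)
    d <- oracle_distance_matrix(adj)
    mine <- node_metrics(adj)
    total_internal <- 0
    for (s in 1:6) for (t in (s + 1):7) {
      if (is.infinite(d[s, t])) next
      for (p in oracle_shortest_paths(adj, d, s, t))
        total_internal <- total_internal + max(0, length(p) - 2)
    }
    expect_equal(sum(mine$stress), total_internal)
  }
})

test_that("network KW comparison distinguishes constructed topologies", {
  star <- matrix(0L, 21, 21); star[1, 2:21] <- star[2:21, 1] <- 1L
  dimnames(star) <- rep(list(paste0("s", 1:21)), 2)
  pathg <- matrix(0L, 21, 21)
  for (i in 1:20) pathg[i, i + 1] <- pathg[i + 1, i] <- 1L
  dimnames(pathg) <- rep(list(paste0("p", 1:21)), 2)
  cyc <- pathg; cyc[1, 21] <- cyc[21, 1] <- 1L
  tabs <- list(star = node_metrics(star), path = node_metrics(pathg),
               cycle = node_metrics(cyc))
  r <- compare_networks_kw(tabs, "degree")
  expect_lt(r$p_value, 0.05)
  expect_equal(nrow(r$posthoc), 3)
  # identical networks: p ~ 1 for every metric
  same <- list(a = tabs$path, b = tabs$path, c = tabs$path)
  for (m in c("degree", "closeness_centrality", "radiality"))
    expect_gt(compare_networks_kw(same, m)$p_value, 0.99)
  expect_error(compare_networks_kw(tabs, "no_such_metric"), "no_such_metric")
})

test_that("AD vs control metric comparison and the U rank-sum identity", {
  star <- matrix(0L, 15, 15); star[1, 2:15] <- star[2:15, 1] <- 1L
  dimnames(star) <- rep(list(paste0("s", 1:15)), 2)
  cyc <- matrix(0L, 15, 15)
  for (i in 1:14) cyc[i, i + 1] <- cyc[i + 1, i] <- 1L
  cyc[1, 15] <- cyc[15, 1] <- 1L
  dimnames(cyc) <- rep(list(paste0("c", 1:15)), 2)
  t1 <- node_metrics(star); t2 <- node_metrics(cyc)
  r <- compare_ad_vs_control(t1, t2, "closeness_centrality")
  u_flip <- compare_ad_vs_control(t2, t1, "closeness_centrality")
  expect_equal(r$U + u_flip$U, 15 * 15)
  same <- compare_ad_vs_control(t1, t1, "degree")
  expect_gt(same$p_value, 0.99)
  expect_error(compare_ad_vs_control(t1[0, ], t2, "degree"), "empty")
})

test_that("top pairs sort by co-prevalence with lexicographic ties", {
  net <- structure(list(edges = data.frame(
    p1 = c("B", "A", "C", "A"), p2 = c("C", "B", "D", "D"),
    coprevalence = c(0.41, 0.43, 0.40, 0.41), stringsAsFactors = FALSE)),
    class = "cooccurrence_network")
  tp <- top_pairs(net, k = 3)
  expect_equal(tp$coprevalence, c(0.43, 0.41, 0.41))
  expect_equal(tp$p1, c("A", "A", "B"))  # tie at 0.41 -> A,D before B,C
  expect_equal(nrow(top_pairs(net, k = 10)), 4)
  empty <- structure(list(edges = net$edges[0, ]),
                     class = "cooccurrence_network")
  expect_warning(tp0 <- top_pairs(empty), "no edges")
  expect_equal(nrow(tp0), 0)
})

test_that("visualization subnetwork: strict 25% cut and GraphML round-trip", {
  set.seed(55)
  m <- matrix(0L, 1000, 4,
              dimnames = list(paste0("p", 1:1000), c("W", "X", "Y", "Z")))
  m[1:249, "W"] <- 1L   # 24.9%
  m[1:251, "X"] <- 1L   # 25.1%
  m[1:400, "Y"] <- 1L
  m[100:500, "Z"] <- 1L
  tmp <- withr::local_tempfile(fileext = ".graphml")
  net <- visualization_subnetwork(m, rownames(m), threshold = 0.25,
                                  graphml_path = tmp,
                                  categories = c(W = "c1", X = "c1",
                                                 Y = "c2", Z = "c2"))
  expect_false("W" %in% net$nodes$phenotype)
  expect_true("X" %in% net$nodes$phenotype)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$phenotype)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  # visualization node set is a subset of the 5% analysis node set
  full <- build_network(m, rownames(m), 0.05, 0.05)
  expect_true(all(net$nodes$phenotype %in% full$nodes$phenotype))
})
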