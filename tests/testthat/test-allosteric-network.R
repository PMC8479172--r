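# Residue networks, communities, community graphs, centralities,
# suboptimal paths, partition similarity.

test_that("edges follow the threshold rule and the -ln|C| weight map", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.7
  C[1, 3] <- C[3, 1] <- 0.69
  C[2, 3] <- C[3, 2] <- -0.8
  dimnames(C) <- list(letters[1:3], letters[1:3])
  net <- build_network(C, threshold = 0.7)
  g <- net$graph
  expect_equal(igraph::ecount(g), 2)  # 0.69 misses the strict-at rule
  w_ab <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("a", "b"))]
  expect_equal(w_ab, -log(0.7), tolerance = 1e-12)
  # anticorrelation connects via |C|
  w_bc <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("b", "c"))]
  expect_equal(w_bc, -log(0.8), tolerance = 1e-12)
  expect_error(build_network(C, threshold = 1.2), "inside")
  # weight at |C| = 1 is zero: free communication
  C2 <- diag(2); C2[1, 2] <- C2[2, 1] <- 1
  net2 <- build_network(C2)
  expect_equal(igraph::E(net2$graph)$weight, 0)
})

test_that("two cliques joined by one edge split into two communities", {
  n <- 10
  C <- diag(n)
  for (i in 1:5) for (j in 1:5) if (i != j) C[i, j] <- 0.9
  for (i in 6:10) for (j in 6:10) if (i != j) C[i, j] <- 0.9
  C[5, 6] <- C[6, 5] <- 0.75
  dimnames(C) <- list(1:n, 1:n)
  net <- build_network(C)
  part <- detect_communities(net)
  expect_equal(length(unique(part$membership)), 2)
  expect_length(unique(part$membership[1:5]), 1)
  expect_length(unique(part$membership[6:10]), 1)
  # brute-force check: no 2-way partition has higher modularity
  adj <- (abs(C) >= 0.7) * abs(C); diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    memb <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1) + 1
    m <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    best <- max(best, m)
  }
  expect_gte(part$modularity + 1e-12, best)
})

test_that("single clique stays one community; edgeless network warns", {
  C <- matrix(0.9, 4, 4); diag(C) <- 1
  dimnames(C) <- list(1:4, 1:4)
  part <- detect_communities(build_network(C))
  expect_equal(length(unique(part$membership)), 1)
  C0 <- diag(4); dimnames(C0) <- list(1:4, 1:4)
  expect_warning(p0 <- detect_communities(build_network(C0)), "edgeless")
  expect_equal(length(unique(p0$membership)), 4)
})

test_that("communities recover programmed correlation blocks", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 2000, dt = 0.1,
                         hinge = list(pivot = NULL, axis = c(1, 0, 0),
                                      mean = 0, sd = 0, tau = 5),
                         corr_blocks = list(list(resid = 5:10, rho = 0.9),
                                            list(resid = 15:20, rho = 0.9)),
                         noise_sd = 0.1, seed = 61)
  sim <- simulate_ensemble(spec)
  cc <- cross_correlation(sim$ensemble)
  net <- build_network(cc)
  part <- detect_communities(net)
  m1 <- part$membership[as.character(5:10)]
  m2 <- part$membership[as.character(15:20)]
  expect_length(unique(m1), 1)
  expect_length(unique(m2), 1)
  expect_false(unique(m1) == unique(m2))
})

test_that("community graphs apply the radius and weight scalings", {
  # communities of 27 and 9 nodes bridged by max |C| = 0.7
  memb <- setNames(rep(1:2, c(27, 9)), 1:36)
  C <- diag(36)
  for (b in list(1:27, 28:36)) {
    C[b, b] <- 0.95
  }
  diag(C) <- 1
  C[1, 28] <- C[28, 1] <- 0.7
  C[2, 29] <- C[29, 2] <- 0.65
  dimnames(C) <- list(1:36, 1:36)
  net <- build_network(C)
  part <- structure(list(membership = memb, modularity = 0.1,
                         sizes = table(memb)),
                    class = "community_partition")
  overlay <- community_graph(part, net, variant = "overlay")
  expect_equal(overlay$nodes$radius[overlay$nodes$id == 1], 9)  # 27/3
  expect_equal(overlay$edges$weight, -log(0.7) / 4, tolerance = 1e-12)
  simp <- community_graph(part, net, variant = "simplified")
  expect_equal(simp$edges$weight, -log(0.7), tolerance = 1e-12)
  expect_equal(simp$edges$weight / overlay$edges$weight, 4)
  # an isolated community is pruned
  memb2 <- setNames(rep(1:3, each = 12), 1:36)
  C2 <- diag(36)
  C2[1:12, 1:12] <- 0.9; C2[13:24, 13:24] <- 0.9; C2[25:36, 25:36] <- 0.9
  diag(C2) <- 1
  C2[1, 13] <- C2[13, 1] <- 0.8
  dimnames(C2) <- list(1:36, 1:36)
  part2 <- structure(list(membership = memb2, modularity = 0.1,
                          sizes = table(memb2)),
                     class = "community_partition")
  cg2 <- community_graph(part2, build_network(C2), variant = "simplified")
  expect_setequal(cg2$nodes$id, 1:2)
})

test_that("centralities match closed forms and brute-force counting", {
  # star: center carries all n(n-1)/2 pair paths, leaves none
  n_leaves <- 6
  C <- diag(n_leaves + 1)
  C[1, 2:(n_leaves + 1)] <- C[2:(n_leaves + 1), 1] <- 0.8
  dimnames(C) <- list(0:n_leaves, 0:n_leaves)
  cent <- network_centrality(build_network(C))
  expect_equal(cent$betweenness[1], n_leaves * (n_leaves - 1) / 2)
  expect_true(all(cent$betweenness[-1] == 0))
  expect_equal(cent$degree[1], n_leaves)
  # path graph a-b-c: b sits on exactly one shortest path
  Cp <- diag(3)
  Cp[1, 2] <- Cp[2, 1] <- 0.8
  Cp[2, 3] <- Cp[3, 2] <- 0.8
  dimnames(Cp) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cp <- network_centrality(build_network(Cp))
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  # random weighted graphs vs brute-force enumeration
  for (s in 1:4) {
    C12 <- random_corr_graph(12, p_edge = 0.4, seed = s + 300)
    net <- build_network(C12)
    got <- network_centrality(net)
    adj <- matrix(NA_real_, 12, 12)
    keep <- abs(C12) >= 0.7; diag(keep) <- FALSE
    adj[keep] <- -log(abs(C12[keep]))
    want <- brute_force_betweenness(adj)
    expect_equal(got$betweenness, want, tolerance = 1e-9)
  }
})

test_that("suboptimal paths equal exhaustive enumeration on small graphs", {
  tri <- diag(3)
  tri[1, 2] <- tri[2, 1] <- exp(-1)
  tri[2, 3] <- tri[3, 2] <- exp(-1)
  tri[1, 3] <- tri[3, 1] <- exp(-3)
  dimnames(tri) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- build_network(tri, threshold = 0.04)
  ps <- suboptimal_paths(net, "a", "c", k = 10)
  expect_equal(ps$paths, list(c("a", "b", "c"), c("a", "c")))
  expect_equal(ps$weights, c(2, 3), tolerance = 1e-12)
  for (s in 1:10) {
    n <- sample(6:10, 1)
    C <- random_corr_graph(n, p_edge = 0.5, seed = s)
    net <- build_network(C)
    src <- "1"; snk <- as.character(n)
    ps <- suppressWarnings(suboptimal_paths(net, src, snk, k = 20))
    adj <- matrix(NA_real_, n, n)
    keep <- abs(C) >= 0.7; diag(keep) <- FALSE
    adj[keep] <- -log(abs(C[keep]))
    bf <- enumerate_simple_paths(adj, 1, n)
    if (!length(bf$paths)) {
      expect_length(ps$paths, 0)
      next
    }
    ord <- order(bf$weights,
                 vapply(bf$paths, paste, character(1), collapse = ">"))
    keep_n <- head(ord, 20)
    expect_equal(ps$weights, bf$weights[keep_n], tolerance = 1e-9)
    expect_equal(ps$paths,
                 lapply(bf$paths[keep_n], as.character))
    # saturation: k beyond the path count returns everything
    ps_all <- suppressWarnings(suboptimal_paths(net, src, snk, k = 10000))
    expect_length(ps_all$paths, length(bf$paths))
  }
})

test_that("disconnected source-sink pairs yield an empty set with warning", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[3, 4] <- C[4, 3] <- 0.9
  dimnames(C) <- list(1:4, 1:4)
  net <- build_network(C)
  expect_warning(ps <- suboptimal_paths(net, "1", "4"), "connected")
  expect_length(ps$paths, 0)
  expect_error(fraction_through(ps, "2"), "empty")
})

test_that("fraction_through counts interior nodes only", {
  paths <- structure(list(
    paths = c(replicate(4, c("s", "x", "t"), simplify = FALSE),
              replicate(6, c("s", "y", "t"), simplify = FALSE)),
    weights = seq(1, 2, length.out = 10),
    sources = "s", sinks = "t"), class = "path_set")
  expect_equal(fraction_through(paths, "x"), 0.4)
  expect_equal(fraction_through(paths, c("x", "y")), 1)
  expect_equal(fraction_through(paths, "z"), 0)
  expect_equal(fraction_through(paths, "s"), 0)  # endpoints excluded
})

test_that("partition similarity reports best-match overlaps", {
  pA <- structure(list(membership = setNames(rep(1:2, each = 6), 1:12)),
                  class = "community_partition")
  expect_true(all(partition_similarity(pA, pA)$overlap_pct == 100))
  # one community split evenly: best match 50% (Jaccard 1/2 here: 3 of 6)
  pB <- structure(list(membership = setNames(c(rep(1, 3), rep(3, 3),
                                               rep(2, 6)), 1:12)),
                  class = "community_partition")
  sim <- partition_similarity(pA, pB)
  expect_equal(sim$overlap_pct[sim$community == 1], 50)
  expect_equal(sim$overlap_pct[sim$community == 2], 100)
  # community ids permuted: label-invariant
  pC <- structure(list(membership = setNames(rep(c(9, 4), each = 6), 1:12)),
                  class = "community_partition")
  expect_true(all(partition_similarity(pA, pC)$overlap_pct == 100))
})

test_that("network exports round-trip through edge lists and GraphML", {
  C <- random_corr_graph(8, seed = 5)
  net <- build_network(C)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".graphml")
  write_network_tsv(net, f1)
  tab <- read.table(f1, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), igraph::ecount(net$graph))
  write_network_graphml(net, f2)
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  unlink(c(f1, f2))
})
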