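# the five topological screens against worked examples and brute-force oracles

test_that("clustering coefficient matches hand-computed small graphs", {
  tri <- make_net(c("A-B", "B-C", "A-C"))
  expect_equal(unname(clustering_coefficient(tri)[c("A", "B", "C")]),
               c(1, 1, 1))
  star <- make_net(c("C-L1", "C-L2", "C-L3", "C-L4"))
  expect_equal(unname(clustering_coefficient(star)["C"]), 0)
  path <- make_net(c("A-B", "B-C"))
  expect_equal(unname(clustering_coefficient(path)["B"]), 0)
  # degree < 2 convention
  expect_equal(unname(clustering_coefficient(path)["A"]), 0)
})

test_that("MNC matches hand-computed small graphs", {
  tri <- make_net(c("A-B", "B-C", "A-C"))
  expect_equal(unname(mnc(tri)["A"]), 2)
  star <- make_net(c("C-L1", "C-L2", "C-L3", "C-L4"))
  expect_equal(unname(mnc(star)["C"]), 1)
  iso <- make_net(c("A-B"), nodes = c("A", "B", "Z"))
  expect_equal(unname(mnc(iso)["Z"]), 0)
})

test_that("betweenness matches enumerated shortest paths on worked examples", {
  path <- make_net(c("A-B", "B-C"))
  expect_equal(unname(betweenness(path)[c("A", "B", "C")]), c(0, 1, 0))
  star <- make_net(c("C-L1", "C-L2", "C-L3", "C-L4"))
  expect_equal(unname(betweenness(star)["C"]), choose(4, 2))
  k4 <- make_net(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))
  expect_equal(unname(betweenness(k4)), rep(0, 4))
})

test_that("bottleneck matches per-root tree enumeration on worked examples", {
  star <- make_net(c("C-L1", "C-L2", "C-L3", "C-L4"))
  bn <- bottleneck(star)
  expect_equal(unname(bn["C"]), 4)
  expect_equal(unname(bn[c("L1", "L2", "L3", "L4")]), rep(0, 4))
  path <- make_net(c("A-B", "B-C"))
  expect_equal(unname(bottleneck(path)[c("A", "B", "C")]), c(0, 2, 0))
  k4 <- make_net(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))
  expect_equal(unname(bottleneck(k4)), rep(0, 4))
})

test_that("all four centralities agree with brute-force oracles on random graphs", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(4:8, 1)
      net <- random_connected_net(n, p = stats::runif(1, 0.3, 0.7))
      expect_equal(betweenness(net), oracle_betweenness(net),
                   tolerance = 1e-12)
      expect_equal(bottleneck(net), oracle_bottleneck(net))
      expect_equal(mnc(net), oracle_mnc(net))
      expect_equal(clustering_coefficient(net), oracle_clustcoef(net),
                   tolerance = 1e-12)
    }
  })
})

test_that("betweenness and clustering coefficient agree with igraph", {
  skip_if_not_installed("igraph")
  withr::with_seed(11, {
    for (i in 1:20) {
      net <- random_connected_net(sample(5:9, 1), p = 0.5)
      g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                         vertices = net$nodes)
      expect_equal(betweenness(net)[net$nodes],
                   igraph::betweenness(g)[net$nodes], tolerance = 1e-10)
      cc_ig <- unname(igraph::transitivity(g, type = "localundirected",
                                           vids = net$nodes,
                                           isolates = "zero"))
      # degree-1 nodes give NaN under this igraph type; the convention is 0
      cc_ig[is.na(cc_ig)] <- 0
      expect_equal(unname(clustering_coefficient(net)[net$nodes]),
                   cc_ig, tolerance = 1e-10)
    }
  })
})

test_that("score bounds hold on random graphs", {
  withr::with_seed(13, {
    for (i in 1:20) {
      net <- random_connected_net(sample(4:8, 1), p = 0.5)
      n <- length(net$nodes)
      deg <- table(factor(c(net$edges$node1, net$edges$node2),
                          levels = net$nodes))
      cc <- clustering_coefficient(net)
      expect_true(all(cc >= 0 & cc <= 1))
      m <- mnc(net)
      expect_true(all(m <= as.numeric(deg[names(m)])))
      bc <- betweenness(net)
      expect_true(all(bc <= (n - 1) * (n - 2) / 2))
      for (cx in mcode_complexes(net)) {
        expect_lte(cx$score, cx$size)
      }
    }
  })
})

test_that("label-independent scores are invariant under node relabeling", {
  # bottleneck is excluded by design: its deterministic lexicographic BFS
  # parent rule makes tree shapes (and thus counts) depend on symbols
  withr::with_seed(17, {
    net <- random_connected_net(7, p = 0.5)
    perm <- sample(LETTERS[1:7])
    names(perm) <- net$nodes
    relab <- ppi_network(data.frame(node1 = perm[net$edges$node1],
                                    node2 = perm[net$edges$node2],
                                    confidence = net$edges$confidence,
                                    stringsAsFactors = FALSE),
                         nodes = unname(perm))
    for (f in list(betweenness, mnc, clustering_coefficient,
                   mcode_vertex_weights)) {
      orig <- f(net)
      new <- f(relab)
      expect_equal(unname(new[perm[net$nodes]]), unname(orig[net$nodes]),
                   tolerance = 1e-12)
    }
  })
})

test_that("MCODE vertex weights follow the core-clustering definition", {
  k4p <- make_net(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D", "A-P"))
  w <- mcode_vertex_weights(k4p)
  expect_equal(unname(w[c("A", "B", "C", "D")]), rep(3, 4))
  expect_equal(unname(w["P"]), 1)  # N[P] is a single edge: 1-core, density 1
  iso <- make_net(c("A-B"), nodes = c("A", "B", "Z"))
  expect_equal(unname(mcode_vertex_weights(iso)["Z"]), 0)
})

test_that("MCODE complexes reproduce the worked traces", {
  k4p <- make_net(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D", "A-P"))
  cx <- mcode_complexes(k4p)
  expect_length(cx, 1)
  expect_equal(cx[[1]]$members, c("A", "B", "C", "D"))
  expect_equal(cx[[1]]$score, 4)

  two_tri <- make_net(c("A-B", "B-C", "A-C", "X-Y", "Y-Z", "X-Z"))
  cx2 <- mcode_complexes(two_tri)
  expect_length(cx2, 2)
  expect_equal(vapply(cx2, `[[`, 0, "score"), c(3, 3))
  expect_equal(cx2[[1]]$seed, "A")  # tie broken by seed symbol
  expect_equal(cx2[[2]]$members, c("X", "Y", "Z"))

  empty <- ppi_network(nodes = c("A", "B"))
  expect_length(mcode_complexes(empty), 0)
})

test_that("top_k_nodes selects by score with lexicographic tie-break", {
  s <- stats::setNames(c(5, 3, 3, 1, 1), c("E", "B", "A", "D", "C"))
  expect_equal(top_k_nodes(s, 4), c("E", "A", "B", "C"))
  expect_equal(top_k_nodes(s, 8), c("E", "A", "B", "C", "D"))
  s16 <- stats::setNames(16:1, sprintf("G%02d", 1:16))
  expect_length(top_k_nodes(s16, 8), 8)
})

test_that("consensus is the intersection of all per-method lists", {
  same <- list(a = c("X", "Y"), b = c("Y", "X"), c = c("X", "Y"),
               d = c("X", "Y"), e = c("Y", "X"))
  expect_equal(consensus_hubs(same)$consensus, c("X", "Y"))
  disjoint <- list(a = "X", b = "Y")
  expect_equal(consensus_hubs(disjoint)$consensus, character(0))
  expect_error(consensus_hubs(list(a = "X")), "at least two")
  withr::with_seed(19, {
    net <- random_connected_net(8, p = 0.5)
    res <- screen_hubs(net, top_k = 4)
    for (m in res$per_method) {
      expect_true(all(res$consensus %in% m))
    }
  })
})
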