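test_that("dijkstra_sssp finds distances and path multiplicities", {
  # unique path A-B-C
  net <- make_net(c("A", "B"), c("B", "C"))
  r <- dijkstra_sssp(net, "A")
  expect_equal(r$dist[["C"]], 2)
  expect_equal(r$sigma[["C"]], 1)
  expect_equal(r$dist[["A"]], 0)
  expect_equal(r$sigma[["A"]], 1)

  # diamond: two tied shortest paths
  r <- dijkstra_sssp(diamond_net(), "A")
  expect_equal(r$dist[["D"]], 2)
  expect_equal(r$sigma[["D"]], 2)

  # unreachable nodes: dist Inf, sigma 0
  net <- make_net(c("A", "C"), c("B", "D"))
  r <- dijkstra_sssp(net, "A")
  expect_equal(r$dist[["C"]], Inf)
  expect_equal(r$sigma[["C"]], 0)
  expect_setequal(r$reachable, c("A", "B"))

  expect_error(dijkstra_sssp(net, "ZZ"), "not in network")
})

test_that("dijkstra distances agree with igraph on random graphs", {
  library(igraph)
  for (seed in 1:20) {
    net <- random_test_graph(15, 0.3, c(1:5, 100:850), seed = seed)
    g <- graph_from_data_frame(net$edges[c("node_a", "node_b")],
                               directed = FALSE,
                               vertices = net$nodes)
    src <- net$nodes[1L]
    ref <- distances(g, v = src, weights = net$edges$weight)[1L, ]
    r <- dijkstra_sssp(net, src)
    expect_equal(r$dist[names(ref)], ref)
  }
})

test_that("sigma equals exhaustive shortest-path enumeration", {
  for (seed in 1:15) {
    net <- random_test_graph(10, 0.35, 1:3, seed = 1000 + seed)
    src <- net$nodes[1L]
    r <- dijkstra_sssp(net, src)
    n <- length(net$nodes)
    W <- matrix(Inf, n, n)
    ai <- match(net$edges$node_a, net$nodes)
    bi <- match(net$edges$node_b, net$nodes)
    W[cbind(ai, bi)] <- W[cbind(bi, ai)] <- net$edges$weight
    for (tgt in net$nodes[-1L]) {
      # oracle: enumerate all simple paths, keep the minimum-weight ones
      paths <- seedpath:::enumerate_min_paths(W, match(src, net$nodes),
                                              match(tgt, net$nodes))
      if (is.null(paths)) {
        expect_equal(r$sigma[[tgt]], 0)
      } else {
        p1 <- paths[[1L]]
        cost <- sum(W[cbind(p1[-length(p1)], p1[-1L])])
        expect_equal(r$dist[[tgt]], cost)
        expect_equal(r$sigma[[tgt]], length(paths))
      }
    }
  }
})

test_that("seed_pair_betweenness matches hand-traced small cases", {
  # single inner node
  net <- make_net(c("A", "B"), c("B", "C"))
  for (m in c("all-paths", "per-pair")) {
    tab <- seed_pair_betweenness(net, c("A", "C"), mode = m)
    expect_equal(tab$gene, "B")
    expect_equal(tab$betweenness, 1)
  }
  # diamond: both tied paths credit their single inner node once
  for (m in c("all-paths", "per-pair")) {
    tab <- seed_pair_betweenness(diamond_net(), c("A", "D"), mode = m)
    expect_equal(sort(tab$gene), c("B", "C"))
    expect_equal(tab$betweenness, c(1, 1))
  }
  # adjacent seeds with a light direct edge: no inner nodes at all
  net <- make_net(c("A", "A", "B"), c("B", "C", "C"),
                  c(999L, 500L, 500L))
  tab <- seed_pair_betweenness(net, c("A", "B"))
  expect_equal(nrow(tab), 0L)
  # disconnected pair is skipped and tallied
  net <- make_net(c("A", "C"), c("B", "D"))
  tab <- seed_pair_betweenness(net, c("A", "C"))
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "skipped_pairs"), 1L)
})

test_that("tied paths through a shared inner node multiply in all-paths mode", {
  net <- shared_inner_net()
  p1_all <- seed_pair_betweenness(net, c("s1", "t1"), mode = "all-paths")
  p2_all <- seed_pair_betweenness(net, c("s2", "t2"), mode = "all-paths")
  p1_pp <- seed_pair_betweenness(net, c("s1", "t1"), mode = "per-pair")
  p2_pp <- seed_pair_betweenness(net, c("s2", "t2"), mode = "per-pair")
  x <- function(tab) tab$betweenness[tab$gene == "X"]
  expect_equal(x(p1_all), 2)  # via a or b
  expect_equal(x(p2_all), 3)  # via a, c or d
  expect_equal(x(p1_all) + x(p2_all), 5)
  expect_equal(x(p1_pp) + x(p2_pp), 2)
  # the oracle agrees on the combined 4-seed call too
  seeds <- c("s1", "t1", "s2", "t2")
  for (m in c("all-paths", "per-pair")) {
    expect_same_table(seed_pair_betweenness(net, seeds, mode = m),
                      brute_force_betweenness(net, seeds, mode = m))
  }
})

test_that("brute-force oracle refuses large networks", {
  net <- random_test_graph(15, 0.3, 1:10, seed = 5)
  expect_error(brute_force_betweenness(net, net$nodes[1:2]), "refuses")
})

test_that("per-pair counts are bounded and dominated by all-paths counts", {
  for (seed in 1:25) {
    net <- random_test_graph(11, 0.35, 1:3, seed = 2000 + seed)
    k <- sample(2:5, 1)
    seeds <- random_seeds(net, k, seed)
    ap <- seed_pair_betweenness(net, seeds, mode = "all-paths")
    pp <- seed_pair_betweenness(net, seeds, mode = "per-pair")
    n_pairs <- choose(k, 2) - attr(pp, "skipped_pairs")
    expect_true(all(pp$betweenness <= n_pairs))
    # pointwise dominance on the union of genes
    genes <- union(ap$gene, pp$gene)
    a <- ap$betweenness[match(genes, ap$gene)]; a[is.na(a)] <- 0
    p <- pp$betweenness[match(genes, pp$gene)]; p[is.na(p)] <- 0
    expect_true(all(a >= p))
    expect_true(all(pp$betweenness >= 1))
  }
})

test_that("an overweight shortcut edge changes nothing", {
  net <- make_net(c("A", "B", "C"), c("B", "C", "D"),
                  c(900L, 900L, 900L))           # weights 100
  seeds <- c("A", "D")
  base_ap <- seed_pair_betweenness(net, seeds)
  # add an 850-weight edge between nodes already at distance 200
  aug <- make_net(c("A", "B", "C", "A"), c("B", "C", "D", "C"),
                  c(900L, 900L, 900L, 150L))
  expect_same_table(seed_pair_betweenness(aug, seeds), base_ap)
})

test_that("node relabeling permutes the table but preserves counts", {
  net <- random_test_graph(10, 0.4, 1:3, seed = 77)
  seeds <- random_seeds(net, 3, 77)
  tab <- seed_pair_betweenness(net, seeds)
  relab <- setNames(sprintf("Z%02d", seq_along(net$nodes)), net$nodes)
  net2 <- build_network(data.frame(
    protein_a = relab[net$edges$node_a],
    protein_b = relab[net$edges$node_b],
    score = 1000L - net$edges$weight, stringsAsFactors = FALSE))
  tab2 <- seed_pair_betweenness(net2, unname(relab[seeds]))
  expect_equal(sort(unname(relab[tab$gene])), sort(tab2$gene))
  m <- match(relab[tab$gene], tab2$gene)
  expect_equal(tab2$betweenness[m], tab$betweenness)
})
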