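# Fixture builders shared across the suite. Everything is generated in
# code; no files ship with the tests.

# network from parallel vectors of endpoints and scores
make_net <- function(a, b, score = 999L) {
  build_network(data.frame(protein_a = a, protein_b = b,
                           score = as.integer(score),
                           stringsAsFactors = FALSE))
}

# Erdos-Renyi test graph with weights drawn from a pool; small pools
# produce the distance ties that exercise path counting.
random_test_graph <- function(n_nodes, edge_prob, weight_pool, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2L)
  sel <- stats::runif(ncol(pairs)) < edge_prob
  if (!any(sel)) sel[sample.int(ncol(pairs), 1L)] <- TRUE
  w <- sample(weight_pool, sum(sel), replace = TRUE)
  build_network(data.frame(protein_a = nodes[pairs[1L, sel]],
                           protein_b = nodes[pairs[2L, sel]],
                           score = as.integer(1000L - w),
                           stringsAsFactors = FALSE))
}

# seeds drawn from the nodes of a network
random_seeds <- function(net, k, seed) {
  set.seed(seed)
  sample(net$nodes, k)
}

# unit-weight path A - X - B plus A - Y - C; seeds {A, B, C}.
# The B-C shortest path is B-X-A-Y-C, so seed A is itself an inner node.
toy_two_branch <- function() {
  make_net(c("A", "X", "A", "Y"), c("X", "B", "Y", "C"))
}

# diamond A-B-D / A-C-D with unit weights: two tied shortest A-D paths
diamond_net <- function() {
  make_net(c("A", "B", "A", "C"), c("B", "D", "C", "D"))
}

# two seed pairs sharing inner node X: pair (s1, t1) has 2 shortest paths
# through X (via a or b), pair (s2, t2) has 3 (via a, c or d)
shared_inner_net <- function() {
  make_net(c("s1", "s1", "a", "b", "X", "s2", "s2", "s2", "c", "d", "X"),
           c("a", "b", "X", "X", "t1", "a", "c", "d", "X", "X", "t2"))
}

expect_same_table <- function(x, y) {
  expect_equal(x$gene, y$gene)
  expect_equal(x$betweenness, y$betweenness)
  expect_equal(x$is_seed, y$is_seed)
  expect_identical(attr(x, "skipped_pairs"), attr(y, "skipped_pairs"))
}

# normalized synthetic network ready for fitting
fit_ready_network <- function(sim) {
  rec <- parse_string_links(sim$links, sim$spec$taxon_prefix)
  rec$protein_a <- normalize_id(rec$protein_a, sim$spec$taxon_prefix)
  rec$protein_b <- normalize_id(rec$protein_b, sim$spec$taxon_prefix)
  build_network(rec)
}
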