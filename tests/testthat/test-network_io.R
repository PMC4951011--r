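test_that("parse_string_links skips headers, filters by taxon, keeps scores", {
  lines <- c("protein1 protein2 combined_score",
             "3702.AT1G01010.1 3702.AT1G01020.1 900",
             "9606.P1 9606.P2 400")
  rec <- parse_string_links(lines, taxon_prefix = "3702.")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$score, 900L)
  expect_equal(attr(rec, "n_raw_records"), 2L)

  expect_equal(nrow(parse_string_links(character())), 0L)

  fixture <- c("protein1 protein2 combined_score",
               "",
               "3702.AT1G01010.1 3702.AT1G01020.1 900",
               "3702.AT1G01010.1 3702.AT1G01030.1 400",
               "9606.P1 9606.P2 300",
               "3702.AT1G01030.1 3702.AT1G01040.2 150",
               "9606.P3 9606.P1 999",
               "3702.AT1G01040.2 3702.AT1G01050.1 999",
               "4932.Y1 4932.Y2 500",
               "3702.AT1G01050.1 3702.AT1G01010.1 151")
  rec <- parse_string_links(fixture, taxon_prefix = "3702.")
  expect_equal(nrow(rec), 5L)     # 2 header/blank + 3 other-taxon skipped
  expect_equal(attr(rec, "n_raw_records"), 8L)
  # keep-all behaviour with empty prefix
  expect_equal(nrow(parse_string_links(fixture, taxon_prefix = "")), 8L)
})

test_that("parse_string_links reports malformed lines by number", {
  expect_error(parse_string_links(c("a b 100", "a b x")), "line.*2")
  expect_error(parse_string_links(c("a b 100", "", "a b")), "line.*3")
  expect_error(parse_string_links("a b 1.5"), "non-integer")
})

test_that("normalize_id strips prefixes and isoform suffixes, idempotently", {
  expect_equal(normalize_id("3702.AT5G63310.1", "3702."), "AT5G63310")
  expect_equal(normalize_id("AT5G63310", "3702.", collapse_isoform = FALSE),
               "AT5G63310")
  expect_equal(normalize_id("3702.AT5G63310.2", "3702.",
                            collapse_isoform = FALSE), "AT5G63310.2")
  # vectorized and idempotent
  ids <- c("3702.AT1G01010.1", "AT1G01020", "3702.AT1G01030")
  once <- normalize_id(ids, "3702.")
  expect_equal(normalize_id(once, "3702."), once)
  expect_error(normalize_id("3702.", "3702."), "empty")
})

test_that("build_network applies the weight transform and dedups edges", {
  # direct substitution: score 999 -> weight 1
  net <- make_net("A", "B", 999L)
  expect_equal(net$edges$weight, 1L)
  # reciprocal records merge to one undirected edge
  net <- make_net(c("A", "B"), c("B", "A"), c(150L, 150L))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 850L)
  # conflicting scores: max score (min weight) wins, conflict counted
  net <- make_net(c("A", "B"), c("B", "A"), c(400L, 700L))
  expect_equal(net$edges$weight, 300L)
  expect_equal(net$n_conflicts, 1L)
  # self-loops dropped
  net <- make_net(c("A", "A"), c("A", "B"), c(500L, 500L))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$n_self_loops, 1L)
  # score outside [150, 999] is an error naming the record
  expect_error(build_network(data.frame(protein_a = "A", protein_b = "B",
                                        score = 149L)), "150")
  expect_error(build_network(data.frame(protein_a = "A", protein_b = "B",
                                        score = 1000L)), "999")
})

test_that("weight + score = 1000 and weights lie in [1, 850] on random input", {
  set.seed(42)
  for (rep in 1:5) {
    score <- sample(150:999, 40, replace = TRUE)
    a <- sprintf("G%02d", sample(15, 40, replace = TRUE))
    b <- sprintf("G%02d", sample(15, 40, replace = TRUE))
    keep <- a != b
    rec <- data.frame(protein_a = a[keep], protein_b = b[keep],
                      score = score[keep])
    net <- build_network(rec)
    expect_lte(nrow(net$edges), nrow(rec))
    expect_true(all(net$edges$weight >= 1L & net$edges$weight <= 850L))
    # recover each kept edge's score and check the transform exactly
    key <- paste(pmin(rec$protein_a, rec$protein_b),
                 pmax(rec$protein_a, rec$protein_b))
    best <- tapply(rec$score, key, max)
    ekey <- paste(net$edges$node_a, net$edges$node_b)
    expect_true(all(net$edges$weight + best[ekey] == 1000L))
  }
})

test_that("read_seed_list intersects with the network and collapses dups", {
  net <- make_net(c("A", "B", "C", "D"), c("B", "C", "D", "A"))
  ss <- read_seed_list(c("A", "B", "C", "D", "ZZ"), net)
  expect_equal(length(ss$in_network), 4L)
  expect_equal(ss$dropped_count, 1L)
  ss <- read_seed_list(c("# comment", "A", "A", "", "B"), net)
  expect_equal(sort(ss$in_network), c("A", "B"))
  expect_length(ss$requested, 2L)
  expect_error(read_seed_list(c("Q1", "Q2"), net), "cannot run")
})

test_that("edge tables round-trip losslessly", {
  net <- make_net(c("A", "B", "C"), c("B", "C", "A"), c(999L, 500L, 150L))
  path <- withr::local_tempfile()
  write_edge_table(net, path)
  lines <- readLines(path)
  expect_length(lines, 4L) # header + 3 edges
  back <- read_edge_table(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)

  # empty network: header only
  empty <- build_network(data.frame(protein_a = character(),
                                    protein_b = character(),
                                    score = integer()))
  write_edge_table(empty, path)
  expect_equal(readLines(path), "node_a\tnode_b\tweight")
  expect_equal(nrow(read_edge_table(path)$edges), 0L)

  # parse -> build -> write -> read identity on a random network
  net <- random_test_graph(12, 0.4, 1:850, seed = 99)
  write_edge_table(net, path)
  back <- read_edge_table(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
})
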