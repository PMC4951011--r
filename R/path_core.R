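#' Single-source shortest paths with path multiplicities
#'
#' Dijkstra search from one node on the weighted network, returning both
#' the shortest-path distance to every node and `sigma`, the number of
#' distinct shortest paths from the source to each node (accumulated over
#' the shortest-path predecessor structure, never by explicit path
#' enumeration). Weights are integers, so distances and counts are exact.
#'
#' @param network a `ppi_network`.
#' @param source a node identifier present in the network.
#' @return list with `source`, named numeric `dist` (`Inf` for
#'   unreachable nodes), named numeric `sigma` (0 for unreachable) and
#'   `reachable`, the character vector of reachable nodes.
#' @examples
#' net <- build_network(data.frame(protein_a = c("A", "B", "A", "C"),
#'                                 protein_b = c("B", "D", "C", "D"),
#'                                 score = 999L))
#' dijkstra_sssp(net, "A")$sigma[["D"]]  # 2 tied shortest paths
#' @export
dijkstra_sssp <- function(network, source) {
  stopifnot(inherits(network, "ppi_network"))
  src <- match(source, network$nodes)
  if (is.na(src)) stop("source node not in network: ", source, call. = FALSE)
  adj <- sp_adjacency(network)
  res <- cpp_sssp(adj$n, adj$head, adj$nbr, adj$wt, src - 1L)
  dist <- res$dist
  sigma <- res$sigma
  names(dist) <- names(sigma) <- network$nodes
  list(source = source, dist = dist, sigma = sigma,
       reachable = network$nodes[is.finite(dist)])
}

#' Seed-pair shortest-path betweenness
#'
#' For every unordered pair of seed genes with a finite network distance,
#' finds all shortest paths between the pair and credits their inner
#' (non-endpoint) nodes. In `"all-paths"` mode a node `v` on a shortest
#' s-t path receives `sigma_s(v) * sigma_t(v)` — the number of distinct
#' shortest s-t paths passing through it; in `"per-pair"` mode it receives
#' 1 per pair. Pair endpoints are never credited for their own pair, but
#' seed genes lying on other pairs' shortest paths are credited normally.
#' Disconnected pairs are skipped and tallied.
#'
#' @param network a `ppi_network`.
#' @param seeds a `seed_set` (or character vector of node IDs) with at
#'   least two members in the network.
#' @param mode counting convention, `"all-paths"` (default) or
#'   `"per-pair"`.
#' @return A `betweenness_table`: data.frame with columns `gene`,
#'   `betweenness` (integer-valued numeric) and `is_seed`, containing only
#'   genes with positive counts, sorted by decreasing betweenness then
#'   gene ID. Attributes `mode` and `skipped_pairs` record the convention
#'   and the number of disconnected seed pairs.
#' @export
seed_pair_betweenness <- function(network, seeds,
                                  mode = c("all-paths", "per-pair")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "ppi_network"))
  seed_ids <- seed_members(seeds, network)
  adj <- sp_adjacency(network)
  idx <- match(seed_ids, network$nodes)
  res <- betweenness_engine(adj, idx, mode)
  make_betweenness_table(network$nodes, res$counts, seed_ids, mode,
                         res$skipped)
}

seed_members <- function(seeds, network) {
  ids <- if (inherits(seeds, "seed_set")) seeds$in_network
         else unique(as.character(seeds))
  missing <- setdiff(ids, network$nodes)
  if (length(missing)) {
    stop("seed node(s) not in network: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(ids) < 2L) {
    stop("need at least 2 in-network seed genes, got ", length(ids),
         call. = FALSE)
  }
  ids
}

# Core counting loop over seed pairs, on integer node indices.
# dist/sigma rows are computed once per seed and reused for all its pairs.
betweenness_engine <- function(adj, seed_idx, mode) {
  k <- length(seed_idx)
  n <- adj$n
  D <- matrix(0, k, n)
  S <- matrix(0, k, n)
  for (i in seq_len(k)) {
    r <- cpp_sssp(n, adj$head, adj$nbr, adj$wt, seed_idx[i] - 1L)
    D[i, ] <- r$dist
    S[i, ] <- r$sigma
  }
  counts <- numeric(n)
  skipped <- 0L
  for (i in seq_len(k - 1L)) {
    di <- D[i, ]; si <- S[i, ]
    for (j in (i + 1L):k) {
      dst <- di[seed_idx[j]]
      if (!is.finite(dst)) {
        skipped <- skipped + 1L
        next
      }
      on <- which(di + D[j, ] == dst) # finite by construction when equal
      on <- on[on != seed_idx[i] & on != seed_idx[j]]
      if (!length(on)) next
      if (mode == "all-paths") {
        counts[on] <- counts[on] + si[on] * S[j, on]
      } else {
        counts[on] <- counts[on] + 1
      }
    }
  }
  list(counts = counts, skipped = skipped)
}

make_betweenness_table <- function(nodes, counts, seed_ids, mode, skipped) {
  keep <- which(counts > 0)
  tab <- data.frame(gene = nodes[keep], betweenness = counts[keep],
                    is_seed = nodes[keep] %in% seed_ids,
                    stringsAsFactors = FALSE)
  ord <- order(-tab$betweenness, tab$gene, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, mode = mode, skipped_pairs = skipped,
            class = c("betweenness_table", "data.frame"))
}

#' Brute-force seed-pair betweenness (exhaustive oracle)
#'
#' Enumerates every simple path between each seed pair, keeps the paths of
#' minimum total weight, and counts inner-node occurrences. Exponential in
#' the node count, so it refuses networks with more than `max_nodes`
#' nodes; it exists as an independent reference for
#' [seed_pair_betweenness()] on small graphs.
#'
#' @inheritParams seed_pair_betweenness
#' @param max_nodes refusal bound on network size (default 14).
#' @return A `betweenness_table`, identical in layout to
#'   [seed_pair_betweenness()].
#' @export
brute_force_betweenness <- function(network, seeds,
                                    mode = c("all-paths", "per-pair"),
                                    max_nodes = 14L) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "ppi_network"))
  n <- length(network$nodes)
  if (n > max_nodes) {
    stop("brute-force oracle refuses networks with more than ", max_nodes,
         " nodes (got ", n, ")", call. = FALSE)
  }
  seed_ids <- seed_members(seeds, network)
  idx <- match(seed_ids, network$nodes)

  # dense adjacency for the DFS
  W <- matrix(Inf, n, n)
  ai <- match(network$edges$node_a, network$nodes)
  bi <- match(network$edges$node_b, network$nodes)
  W[cbind(ai, bi)] <- network$edges$weight
  W[cbind(bi, ai)] <- network$edges$weight

  counts <- numeric(n)
  skipped <- 0L
  k <- length(idx)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      paths <- enumerate_min_paths(W, idx[i], idx[j])
      if (is.null(paths)) {
        skipped <- skipped + 1L
        next
      }
      inner <- lapply(paths, function(p) p[-c(1L, length(p))])
      if (mode == "all-paths") {
        for (v in unlist(inner)) counts[v] <- counts[v] + 1
      } else {
        for (v in unique(unlist(inner))) counts[v] <- counts[v] + 1
      }
    }
  }
  make_betweenness_table(network$nodes, counts, seed_ids, mode, skipped)
}

# All minimum-weight simple paths s..t as index vectors; NULL if none.
enumerate_min_paths <- function(W, s, t) {
  n <- nrow(W)
  best <- Inf
  found <- list()
  visit <- function(path, cost) {
    u <- path[length(path)]
    if (u == t) {
      if (cost < best) {
        best <<- cost
        found <<- list(path)
      } else if (cost == best) {
        found[[length(found) + 1L]] <<- path
      }
      return(invisible())
    }
    for (v in seq_len(n)) {
      w <- W[u, v]
      if (is.finite(w) && !(v %in% path) && cost + w <= best) {
        visit(c(path, v), cost + w)
      }
    }
  }
  visit(s, 0)
  if (length(found) == 0L) NULL else found
}

#' Write a betweenness table as TSV
#'
#' Columns `gene`, `betweenness`, `is_seed`, rows sorted by descending
#' betweenness then gene ID; optional `#` comment header lines carry the
#' run configuration.
#'
#' @param table a `betweenness_table`.
#' @param path output file.
#' @param comments character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_betweenness_table <- function(table, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines("gene\tbetweenness\tis_seed", con)
  if (nrow(table)) {
    writeLines(paste(table$gene, format_count(table$betweenness),
                     ifelse(table$is_seed, "TRUE", "FALSE"), sep = "\t"),
               con)
  }
  invisible(path)
}

# counts are integer-valued doubles; print without scientific notation
format_count <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
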