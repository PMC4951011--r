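#' Seed-based shortest-path gene prioritization
#'
#' Fits the full prioritization model to a weighted interaction network
#' and a seed gene set: scores every gene by the number of seed-pair
#' shortest paths passing through it as an inner node, builds a null
#' distribution from random gene sets of the same size, assigns each
#' extracted gene a permutation FDR = M/N (M = runs whose betweenness for
#' that gene exceeds the observed value), and retains genes with FDR
#' strictly below `threshold` as candidates.
#'
#' Identical inputs and `rng_seed` reproduce the fit exactly. With a
#' `checkpoint_dir` the per-permutation betweenness tables are persisted
#' as TSV and reused on resume, so partial runs are never wasted;
#' `max_compute` caps how many missing permutations a single call
#' computes (an incomplete fit returns a `seedpath_partial` progress
#' object instead of a fit).
#'
#' @param network a `ppi_network` from [build_network()] or
#'   [read_edge_table()].
#' @param seeds a `seed_set` from [read_seed_list()], or a character
#'   vector of node IDs (at least 2 in the network).
#' @param mode counting convention: `"all-paths"` credits an inner node
#'   with the number of distinct shortest paths through it per seed pair
#'   (default); `"per-pair"` credits at most 1 per pair.
#' @param n_permutations number of random gene sets (default 1000).
#' @param threshold candidate FDR cutoff, strict `<` (default 0.05).
#' @param comparison exceedance rule for M: `"gt"` (strictly greater,
#'   default) or `"ge"`.
#' @param universe random-set sampling universe: `"all-nodes"` (default)
#'   or `"non-seed-nodes"`.
#' @param rng_seed integer seed for the random sets.
#' @param checkpoint_dir optional directory for per-permutation tables.
#' @param max_compute at most this many permutation tables are computed in
#'   this call (default `Inf`); only meaningful with a checkpoint.
#' @param verbose print progress every 100 permutations?
#' @return An object of class `seedpath`: a list with `betweenness` (the
#'   observed [seed_pair_betweenness()] table), `fdr` (the full FDR table
#'   with a `candidate` column), `candidates` (the retained rows),
#'   `report` (all run counts, see [summarize()]), `config` (the
#'   effective configuration echo), `seeds` and `call`.
#' @seealso [summarize()], [candidates()], [run_seedpath_analysis()]
#' @export
seedpath <- function(network, seeds,
                     mode = c("all-paths", "per-pair"),
                     n_permutations = 1000L, threshold = 0.05,
                     comparison = c("gt", "ge"),
                     universe = c("all-nodes", "non-seed-nodes"),
                     rng_seed = 1L, checkpoint_dir = NULL,
                     max_compute = Inf, verbose = FALSE) {
  mode <- match.arg(mode)
  comparison <- match.arg(comparison)
  universe <- match.arg(universe)
  stopifnot(inherits(network, "ppi_network"))
  if (!inherits(seeds, "seed_set")) {
    ids <- unique(as.character(seeds))
    seeds <- structure(list(requested = ids,
                            in_network = ids[ids %in% network$nodes],
                            dropped = setdiff(ids, network$nodes),
                            dropped_count = sum(!ids %in% network$nodes)),
                       class = "seed_set")
  }
  seed_ids <- with_stage("path_core", seed_members(seeds, network))
  cl <- match.call()

  adj <- sp_adjacency(network)
  seed_idx <- match(seed_ids, network$nodes)
  obs_raw <- with_stage("betweenness",
                        betweenness_engine(adj, seed_idx, mode))
  observed <- make_betweenness_table(network$nodes, obs_raw$counts,
                                     seed_ids, mode, obs_raw$skipped)

  config <- permutation_config(n_permutations, length(seed_ids),
                               universe, comparison, rng_seed)
  cfg_echo <- config_echo(mode, threshold, config)

  sets <- with_stage("permutation", sample_random_sets(network, config,
                                                       seeds))
  ckpt <- if (!is.null(checkpoint_dir)) {
    checkpoint_open(checkpoint_dir, cfg_echo, network, seed_ids)
  }

  obs_genes <- observed$gene
  obs_counts <- observed$betweenness
  M <- numeric(length(obs_genes))
  computed <- 0L
  done <- 0L
  for (i in seq_along(sets)) {
    perm_counts <- NULL
    if (!is.null(ckpt)) perm_counts <- checkpoint_read(ckpt, i, obs_genes)
    if (is.null(perm_counts)) {
      if (computed >= max_compute) break
      idx <- match(sets[[i]], network$nodes)
      res <- with_stage("permutation",
                        betweenness_engine(adj, idx, mode))
      computed <- computed + 1L
      if (!is.null(ckpt)) {
        checkpoint_write(ckpt, i, network$nodes, res$counts)
      }
      perm_counts <- res$counts[match(obs_genes, network$nodes)]
    }
    M <- M + exceeds(perm_counts, obs_counts, comparison)
    done <- done + 1L
    if (verbose && done %% 100L == 0L) {
      message("permutations done: ", done, "/", length(sets))
    }
  }

  if (done < config$n_permutations) {
    message("partial run: ", done, " of ", config$n_permutations,
            " permutations available; re-run with the same checkpoint_dir",
            " to resume")
    return(structure(list(status = "partial", done = done,
                          n_permutations = config$n_permutations,
                          checkpoint_dir = checkpoint_dir,
                          config = cfg_echo),
                     class = "seedpath_partial"))
  }

  fdr_tab <- structure(
    data.frame(gene = obs_genes, betweenness = obs_counts,
               M = as.integer(M), fdr = M / config$n_permutations,
               is_seed = observed$is_seed, stringsAsFactors = FALSE),
    n_permutations = config$n_permutations, comparison = comparison,
    mode = mode, class = c("fdr_table", "data.frame"))

  flt <- with_stage("filter", filter_candidates(fdr_tab, threshold))

  report <- list(
    n_records_parsed = network$n_records,
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    n_seeds_in_network = length(seed_ids),
    n_extracted_genes = nrow(observed),
    n_extracted_validated = sum(observed$is_seed),
    n_extracted_novel = sum(!observed$is_seed),
    n_candidates = flt$n_total,
    n_candidate_validated = flt$n_validated,
    n_candidate_novel = flt$n_novel,
    skipped_pairs = attr(observed, "skipped_pairs"),
    config_echo = cfg_echo)

  structure(list(betweenness = observed, fdr = flt$table,
                 candidates = flt$candidates, report = report,
                 config = cfg_echo, seeds = seeds, call = cl),
            class = "seedpath")
}

config_echo <- function(mode, threshold, config) {
  list(version = as.character(utils::packageVersion("seedpath")),
       mode = mode, threshold = threshold,
       n_permutations = config$n_permutations,
       set_size = config$set_size,
       universe = config$universe,
       comparison = config$comparison,
       rng_seed = config$rng_seed)
}

config_echo_lines <- function(cfg) {
  unname(vapply(names(cfg), function(k) paste0(k, ": ", cfg[[k]]), ""))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

# --- checkpointing ---------------------------------------------------------

checkpoint_open <- function(dir, cfg, network, seed_ids) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta_path <- file.path(dir, "checkpoint_meta.tsv")
  meta <- c(config_echo_lines(cfg),
            paste0("n_nodes: ", length(network$nodes)),
            paste0("n_edges: ", nrow(network$edges)),
            paste0("n_seeds: ", length(seed_ids)))
  if (file.exists(meta_path)) {
    old <- readLines(meta_path, warn = FALSE)
    if (!identical(old, meta)) {
      stop("checkpoint directory ", dir,
           " was created under a different configuration; ",
           "refusing to mix runs", call. = FALSE)
    }
  } else {
    writeLines(meta, meta_path)
  }
  list(dir = dir)
}

checkpoint_file <- function(ckpt, i) {
  file.path(ckpt$dir, sprintf("perm_%05d.tsv", i))
}

# returns counts aligned to `genes`, or NULL when permutation i is absent
checkpoint_read <- function(ckpt, i, genes) {
  path <- checkpoint_file(ckpt, i)
  if (!file.exists(path)) return(NULL)
  lines <- readLines(path, warn = FALSE)
  out <- numeric(length(genes))
  if (length(lines) > 1L) {
    toks <- strsplit(lines[-1L], "\t", fixed = TRUE)
    g <- vapply(toks, `[`, "", 1L)
    v <- as.numeric(vapply(toks, `[`, "", 2L))
    hit <- match(genes, g)
    out[!is.na(hit)] <- v[hit[!is.na(hit)]]
  }
  out
}

checkpoint_write <- function(ckpt, i, nodes, counts) {
  keep <- which(counts > 0)
  path <- checkpoint_file(ckpt, i)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w", encoding = "UTF-8")
  writeLines("gene\tbetweenness", con)
  if (length(keep)) {
    writeLines(paste(nodes[keep], format_count(counts[keep]), sep = "\t"),
               con)
  }
  close(con)
  file.rename(tmp, path)
}

# --- methods ---------------------------------------------------------------

#' @export
print.seedpath <- function(x, ...) {
  r <- x$report
  cat("Seed-based shortest-path gene prioritization\n")
  cat("  network: ", r$n_nodes, " nodes, ", r$n_edges, " edges; seeds: ",
      r$n_seeds_in_network, "\n", sep = "")
  cat("  extracted ", r$n_extracted_genes, " genes (",
      r$n_extracted_validated, " validated, ", r$n_extracted_novel,
      " novel); ", r$skipped_pairs, " disconnected seed pairs\n", sep = "")
  cat("  candidates at fdr < ", x$config$threshold, " (",
      r$config_echo$n_permutations, " permutations, ",
      x$config$comparison, "): ", r$n_candidates, " (",
      r$n_candidate_validated, " validated, ", r$n_candidate_novel,
      " novel)\n", sep = "")
  invisible(x)
}

#' @export
print.seedpath_partial <- function(x, ...) {
  cat("Partial prioritization run: ", x$done, " of ", x$n_permutations,
      " permutations computed\n  checkpoint: ", x$checkpoint_dir,
      "\n  re-run seedpath() with the same arguments to resume\n",
      sep = "")
  invisible(x)
}

#' @export
summary.seedpath <- function(object, ...) {
  structure(list(report = object$report, config = object$config),
            class = "summary.seedpath")
}

#' @export
print.summary.seedpath <- function(x, ...) {
  summarize(x$report)
  invisible(x)
}

#' Extract the candidate gene table
#'
#' @param fit a `seedpath` object.
#' @return data.frame of candidate genes (fdr below the fitted threshold)
#'   with their betweenness, M, fdr and validated/novel status.
#' @export
candidates <- function(fit) {
  stopifnot(inherits(fit, "seedpath"))
  fit$candidates
}

#' @export
coef.seedpath <- function(object, ...) {
  stats::setNames(object$fdr$fdr, object$fdr$gene)
}

#' @export
as.data.frame.seedpath <- function(x, ...) {
  as.data.frame(x$fdr)
}

#' @export
plot.seedpath <- function(x, ...) {
  tab <- x$fdr
  col <- ifelse(tab$candidate, "#c0392b", "grey50")
  pch <- ifelse(tab$is_seed, 17, 19)
  graphics::plot(tab$betweenness, tab$fdr, log = "x", col = col, pch = pch,
                 xlab = "seed-pair path betweenness (log scale)",
                 ylab = "permutation FDR",
                 main = "Gene prioritization", ...)
  graphics::abline(h = x$config$threshold, lty = 2)
  graphics::legend("topright",
                   legend = c("candidate", "not retained", "seed gene"),
                   col = c("#c0392b", "grey50", "black"),
                   pch = c(19, 19, 17), bty = "n", cex = 0.8)
  invisible(x)
}

#' Human-readable run summary
#'
#' Writes all run counts (parsed records, network size, seed counts, the
#' extracted validated/novel split, the candidate validated/novel split,
#' skipped disconnected pairs) plus the conventions in effect (counting
#' mode, exceedance comparison, sampling universe, strict threshold).
#'
#' @param report a `seedpath` fit or its `$report` list.
#' @param file a connection or file name passed to [cat()]; `""` prints
#'   to stdout.
#' @return the report, invisibly.
#' @export
summarize <- function(report, file = "") {
  if (inherits(report, "seedpath")) report <- report$report
  cfg <- report$config_echo
  strictness <- if (cfg$comparison == "gt") "strict" else "with ties"
  txt <- c(
    "Shortest-path gene prioritization run",
    sprintf("  records parsed:        %d", report$n_records_parsed),
    sprintf("  network nodes:         %d", report$n_nodes),
    sprintf("  network edges:         %d", report$n_edges),
    sprintf("  seeds in network:      %d", report$n_seeds_in_network),
    sprintf("  extracted genes:       %d", report$n_extracted_genes),
    sprintf("  extracted validated:   %d", report$n_extracted_validated),
    sprintf("  extracted novel:       %d", report$n_extracted_novel),
    sprintf("  candidates:            %d", report$n_candidates),
    sprintf("  candidate validated:   %d", report$n_candidate_validated),
    sprintf("  candidate novel:       %d", report$n_candidate_novel),
    sprintf("  skipped seed pairs:    %d (disconnected)",
            report$skipped_pairs),
    sprintf("  selection: fdr < %s (%s exceedance, fdr = M/N)",
            format(cfg$threshold), strictness),
    sprintf("  mode: %s | universe: %s | permutations: %d | rng_seed: %d",
            cfg$mode, cfg$universe, cfg$n_permutations, cfg$rng_seed))
  cat(paste0(txt, "\n", collapse = ""), file = file)
  invisible(report)
}
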