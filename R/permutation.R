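#' Permutation test configuration
#'
#' Bundles the knobs of the random-set null: how many random gene sets to
#' draw, their size (defaulting to the observed seed-set size), which
#' universe they are drawn from, how exceedances are counted, and the RNG
#' seed that makes the whole test reproducible.
#'
#' @param n_permutations number of random gene sets (default 1000).
#' @param set_size size of each random set; `NULL` means the number of
#'   in-network seed genes.
#' @param universe `"all-nodes"` (random sets may contain seed genes,
#'   default) or `"non-seed-nodes"`.
#' @param comparison exceedance strictness for M: `"gt"` counts
#'   permutation betweenness strictly greater than observed (default, the
#'   FDR(g) = M/N definition); `"ge"` counts ties as exceedances (the more
#'   conservative permutation-p convention).
#' @param rng_seed integer seed driving the random-set draws.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 1000L, set_size = NULL,
                               universe = c("all-nodes", "non-seed-nodes"),
                               comparison = c("gt", "ge"),
                               rng_seed = 1L) {
  universe <- match.arg(universe)
  comparison <- match.arg(comparison)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("n_permutations must be a positive integer", call. = FALSE)
  }
  structure(list(n_permutations = n_permutations,
                 set_size = if (is.null(set_size)) NULL
                            else as.integer(set_size),
                 universe = universe, comparison = comparison,
                 rng_seed = as.integer(rng_seed)),
            class = "permutation_config")
}

# run `expr` under a deterministic RNG stream without disturbing the
# caller's RNG state
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Draw the random gene sets of the permutation null
#'
#' Samples `n_permutations` gene sets, each of exactly `set_size` distinct
#' genes, uniformly without replacement from the chosen universe of
#' network nodes. Fully reproducible from `config$rng_seed`.
#'
#' @param network a `ppi_network`.
#' @param config a [permutation_config()]; `set_size` must be set here or
#'   derivable from `seeds`.
#' @param seeds optional `seed_set` (or character vector) supplying the
#'   default `set_size` and, under the `"non-seed-nodes"` policy, the
#'   genes excluded from the universe.
#' @return list of character vectors, one per permutation.
#' @export
sample_random_sets <- function(network, config, seeds = NULL) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(config, "permutation_config"))
  seed_ids <- if (is.null(seeds)) character()
              else if (inherits(seeds, "seed_set")) seeds$in_network
              else as.character(seeds)
  size <- config$set_size
  if (is.null(size)) {
    if (!length(seed_ids)) {
      stop("set_size not given and no seeds to take it from", call. = FALSE)
    }
    size <- length(seed_ids)
  }
  universe <- switch(config$universe,
                     "all-nodes" = network$nodes,
                     "non-seed-nodes" = setdiff(network$nodes, seed_ids))
  if (length(universe) < size) {
    stop("sampling universe (", length(universe),
         " nodes) smaller than set_size (", size, ")", call. = FALSE)
  }
  with_rng(config$rng_seed, {
    lapply(seq_len(config$n_permutations),
           function(i) sample(universe, size))
  })
}

#' Per-gene permutation FDR
#'
#' For each gene in the observed betweenness table, `M` is the number of
#' permutation runs in which that gene's betweenness (for the random set)
#' exceeds its observed betweenness — strictly under `comparison = "gt"`,
#' with ties under `"ge"`. Genes absent from a permuted table count as
#' betweenness 0 in that run. The FDR is `M / n_permutations` exactly, so
#' values lie on the grid \{0, 1/N, ..., 1\}.
#'
#' @param observed a `betweenness_table` for the seed set.
#' @param permuted list of `betweenness_table`s (or data.frames with
#'   `gene` and `betweenness`), one per permutation run.
#' @param config a [permutation_config()] (only `comparison` is used; the
#'   number of permutations is taken from `length(permuted)`).
#' @return An `fdr_table`: data.frame `gene`, `betweenness`, `M`, `fdr`,
#'   `is_seed`, sorted like the observed table; attributes
#'   `n_permutations` and `comparison`.
#' @export
permutation_fdr <- function(observed, permuted,
                            config = permutation_config()) {
  stopifnot(inherits(observed, "betweenness_table"))
  if (!length(permuted)) {
    stop("no permutation runs supplied", call. = FALSE)
  }
  M <- numeric(nrow(observed))
  for (p in permuted) {
    pb <- perm_counts_for(p, observed$gene)
    M <- M + exceeds(pb, observed$betweenness, config$comparison)
  }
  n <- length(permuted)
  tab <- data.frame(gene = observed$gene,
                    betweenness = observed$betweenness,
                    M = as.integer(M), fdr = M / n,
                    is_seed = observed$is_seed, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, n_permutations = n, comparison = config$comparison,
            mode = attr(observed, "mode"),
            class = c("fdr_table", "data.frame"))
}

perm_counts_for <- function(p, genes) {
  stopifnot(is.data.frame(p), all(c("gene", "betweenness") %in% names(p)))
  out <- p$betweenness[match(genes, p$gene)]
  out[is.na(out)] <- 0
  out
}

exceeds <- function(perm, obs, comparison) {
  if (comparison == "gt") perm > obs else perm >= obs
}

#' Filter candidate genes by permutation FDR
#'
#' Retains genes with FDR strictly below the threshold (a gene at exactly
#' the threshold is excluded) and partitions them into validated (seed)
#' and novel genes.
#'
#' @param fdr_table an `fdr_table` from [permutation_fdr()].
#' @param threshold FDR cutoff in (0, 1\]; default 0.05.
#' @param seeds optional `seed_set` or character vector; defaults to the
#'   table's `is_seed` column.
#' @return list with `candidates` (the retained rows, plus a `candidate`
#'   column on the full table under `$table`), and counts `n_total`,
#'   `n_validated`, `n_novel`.
#' @export
filter_candidates <- function(fdr_table, threshold = 0.05, seeds = NULL) {
  stopifnot(inherits(fdr_table, "fdr_table"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  is_seed <- if (is.null(seeds)) {
    fdr_table$is_seed
  } else {
    ids <- if (inherits(seeds, "seed_set")) seeds$in_network
           else as.character(seeds)
    fdr_table$gene %in% ids
  }
  keep <- fdr_table$fdr < threshold
  full <- fdr_table
  full$candidate <- keep
  cand <- full[keep, , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, table = full,
       n_total = sum(keep),
       n_validated = sum(keep & is_seed),
       n_novel = sum(keep & !is_seed),
       threshold = threshold)
}

#' Write an FDR / candidate table as TSV
#'
#' Columns `gene`, `betweenness`, `M`, `fdr`, `is_seed`, `candidate`, with
#' optional `#` comment lines carrying the run configuration. FDR values
#' are written as exact decimal fractions of the permutation count.
#'
#' @param table data.frame with the columns above (`candidate` optional).
#' @param path output file.
#' @param comments character vector of `# ` header lines.
#' @return `path`, invisibly.
#' @export
write_fdr_table <- function(table, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  cand <- if ("candidate" %in% names(table)) table$candidate
          else rep(NA, nrow(table))
  writeLines("gene\tbetweenness\tM\tfdr\tis_seed\tcandidate", con)
  if (nrow(table)) {
    writeLines(paste(table$gene, format_count(table$betweenness), table$M,
                     format(table$fdr, scientific = FALSE, trim = TRUE,
                            drop0trailing = TRUE),
                     ifelse(table$is_seed, "TRUE", "FALSE"),
                     ifelse(is.na(cand), "NA",
                            ifelse(cand, "TRUE", "FALSE")),
                     sep = "\t"), con)
  }
  invisible(path)
}
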