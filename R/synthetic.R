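#' Specification for a synthetic planted-module benchmark network
#'
#' Describes a random background interaction network plus a dense,
#' high-confidence planted functional module. Part of the module's nodes
#' are designated seeds; the rest are hidden members the prioritization
#' should recover. Optional decoy seeds are background nodes added to the
#' seed list to check that off-module seeds do not inflate module FDRs.
#'
#' Defaults encode the package's standard benchmark: a 400-node
#' Erdos-Renyi background (edge probability 0.02) with weak scores
#' U\[150, 400\], a 30-node module at edge probability 0.6 with strong
#' scores U\[850, 999\], 15 of the 30 module nodes used as seeds and no
#' decoys.
#'
#' @param n_background number of background nodes.
#' @param background_edge_prob background edge probability.
#' @param background_score_range integer score interval for background
#'   (and bridge) edges, within \[150, 999\].
#' @param module_size number of planted-module nodes.
#' @param module_edge_prob intra-module edge probability.
#' @param module_score_range integer score interval for module edges.
#' @param n_seed_members module nodes designated as seeds.
#' @param n_decoy_seeds background nodes added to the seed list.
#' @param rng_seed integer generator seed.
#' @param taxon_prefix taxon prefix used in emitted STRING-dialect IDs.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_background = 400L,
                           background_edge_prob = 0.02,
                           background_score_range = c(150L, 400L),
                           module_size = 30L,
                           module_edge_prob = 0.6,
                           module_score_range = c(850L, 999L),
                           n_seed_members = 15L,
                           n_decoy_seeds = 0L,
                           rng_seed = 1L,
                           taxon_prefix = "32630.") {
  spec <- list(n_background = as.integer(n_background),
               background_edge_prob = background_edge_prob,
               background_score_range = as.integer(background_score_range),
               module_size = as.integer(module_size),
               module_edge_prob = module_edge_prob,
               module_score_range = as.integer(module_score_range),
               n_seed_members = as.integer(n_seed_members),
               n_decoy_seeds = as.integer(n_decoy_seeds),
               rng_seed = as.integer(rng_seed),
               taxon_prefix = taxon_prefix)
  for (r in list(spec$background_score_range, spec$module_score_range)) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 150L || r[2L] > 999L) {
      stop("score ranges must be increasing intervals within [150, 999]",
           call. = FALSE)
    }
  }
  if (spec$n_seed_members > spec$module_size) {
    stop("n_seed_members cannot exceed module_size", call. = FALSE)
  }
  if (spec$n_decoy_seeds > spec$n_background) {
    stop("n_decoy_seeds cannot exceed n_background", call. = FALSE)
  }
  if (!(spec$background_edge_prob >= 0 && spec$background_edge_prob <= 1 &&
        spec$module_edge_prob >= 0 && spec$module_edge_prob <= 1)) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$module_score_range[1L] < spec$background_score_range[2L]) {
    warning("module scores overlap background scores; ",
            "the benchmark will not be cleanly separable",
            call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic planted-module network
#'
#' Draws the background graph edgewise with `background_edge_prob` and
#' uniform scores on the background interval, the module subgraph with
#' `module_edge_prob` and uniform scores on the module interval, and wires
#' every module node into the background with at least one bridging edge
#' (background-strength score), so no module node is isolated. The output
#' is the exact STRING `protein.links` dialect plus a seed list and a
#' truth table; everything is reproducible from `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_network` object: list with `links` (character
#'   lines, header included), `seeds` (character lines, gene-level IDs),
#'   `truth` (data.frame `node`, `role` with roles `background`,
#'   `module-seed`, `module-hidden`, `decoy-seed`), `n_nodes`, `n_edges`
#'   and the originating `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$rng_seed, {
    bg <- sprintf("BG%04d", seq_len(spec$n_background))
    md <- sprintf("MD%03d", seq_len(spec$module_size))

    bg_e <- draw_gnp_edges(bg, spec$background_edge_prob,
                           spec$background_score_range)
    md_e <- draw_gnp_edges(md, spec$module_edge_prob,
                           spec$module_score_range)
    # one bridge per module node, background-strength evidence
    bridge <- data.frame(
      a = md,
      b = sample(bg, spec$module_size, replace = TRUE),
      score = sample_scores(spec$module_size, spec$background_score_range),
      stringsAsFactors = FALSE)

    edges <- rbind(bg_e, md_e, bridge)
    seed_members <- sort(sample(md, spec$n_seed_members))
    decoys <- sort(sample(bg, spec$n_decoy_seeds))
    hidden <- setdiff(md, seed_members)

    truth <- data.frame(
      node = c(bg, md),
      role = c(ifelse(bg %in% decoys, "decoy-seed", "background"),
               ifelse(md %in% seed_members, "module-seed",
                      "module-hidden")),
      stringsAsFactors = FALSE)

    links <- c("protein1 protein2 combined_score",
               paste(paste0(spec$taxon_prefix, edges$a),
                     paste0(spec$taxon_prefix, edges$b),
                     edges$score))
    structure(list(links = links,
                   seeds = c(seed_members, decoys),
                   truth = truth,
                   n_nodes = length(bg) + length(md),
                   n_edges = nrow(edges),
                   spec = spec),
              class = "synthetic_network")
  })
}

draw_gnp_edges <- function(nodes, p, score_range) {
  n <- length(nodes)
  if (n < 2L || p <= 0) {
    return(data.frame(a = character(), b = character(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(n, 2L)
  sel <- stats::runif(ncol(pairs)) < p
  data.frame(a = nodes[pairs[1L, sel]], b = nodes[pairs[2L, sel]],
             score = sample_scores(sum(sel), score_range),
             stringsAsFactors = FALSE)
}

sample_scores <- function(n, range) {
  if (n == 0L) return(integer())
  sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' @export
print.synthetic_network <- function(x, ...) {
  s <- x$spec
  cat("Synthetic planted-module network\n")
  cat("  ", x$n_nodes, " nodes (", s$n_background, " background + ",
      s$module_size, " module), ", x$n_edges, " edges\n", sep = "")
  cat("  seeds: ", s$n_seed_members, " module members + ",
      s$n_decoy_seeds, " decoys; hidden members: ",
      s$module_size - s$n_seed_members, "\n", sep = "")
  invisible(x)
}

#' Write the synthetic network to disk
#'
#' Emits `links.txt` (STRING dialect), `seeds.txt` (one gene per line) and
#' `truth.tsv` (`node<TAB>role`).
#'
#' @param sim a `synthetic_network`.
#' @param dir output directory (created if missing).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(links = file.path(dir, "links.txt"),
             seeds = file.path(dir, "seeds.txt"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(sim$links, paths[["links"]])
  writeLines(sim$seeds, paths[["seeds"]])
  writeLines(c("node\trole",
               paste(sim$truth$node, sim$truth$role, sep = "\t")),
             paths[["truth"]])
  invisible(paths)
}

#' Hidden-member recovery metrics
#'
#' Scores a candidate gene set against the generator's truth table:
#' recall is the fraction of hidden module members recovered; precision
#' is computed over the non-seed candidates only (seed genes re-found as
#' candidates are neither rewarded nor penalized).
#'
#' @param candidates character vector of candidate gene IDs (or a
#'   `seedpath` fit, whose candidate genes are used).
#' @param truth a truth data.frame (`node`, `role`) or a
#'   `synthetic_network`.
#' @return list with `recall`, `precision` (NA when there are no non-seed
#'   candidates), `n_hidden`, `n_recovered`, `n_nonseed_candidates`.
#' @export
recovery_metrics <- function(candidates, truth) {
  if (inherits(candidates, "seedpath")) {
    candidates <- candidates$candidates$gene
  }
  if (inherits(truth, "synthetic_network")) truth <- truth$truth
  stopifnot(is.data.frame(truth), all(c("node", "role") %in% names(truth)))
  hidden <- truth$node[truth$role == "module-hidden"]
  if (length(hidden) == 0L) {
    stop("truth table contains no hidden module members", call. = FALSE)
  }
  seeds <- truth$node[truth$role %in% c("module-seed", "decoy-seed")]
  candidates <- unique(as.character(candidates))
  nonseed <- setdiff(candidates, seeds)
  hit <- intersect(candidates, hidden)
  list(recall = length(hit) / length(hidden),
       precision = if (length(nonseed)) length(hit) / length(nonseed)
                   else NA_real_,
       n_hidden = length(hidden),
       n_recovered = length(hit),
       n_nonseed_candidates = length(nonseed))
}
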