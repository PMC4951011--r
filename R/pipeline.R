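#' Run the full prioritization pipeline and write all output tables
#'
#' Orchestrates parse -> build -> betweenness -> permutation -> filter ->
#' report as one reproducible run. Accepts either a raw STRING-style
#' links source (parsed and filtered by taxon) or an already-built
#' network / edge-table file. Writes, under `out_dir`:
#' `edge_table.tsv`, `betweenness.tsv`, `fdr.tsv`, `candidates.tsv`,
#' `run_report.tsv` (machine-readable key-value) and `summary.txt`. Every
#' table embeds the effective configuration and package version as `#`
#' header lines; re-running with identical inputs and `rng_seed` yields
#' byte-identical tables.
#'
#' @param links a STRING-style links file path or character vector of
#'   lines; ignored when `network` is given.
#' @param seeds seed-list file path or character vector of lines.
#' @param out_dir output directory (created if missing).
#' @param network optional: a `ppi_network`, or the path of an edge table
#'   written by [write_edge_table()].
#' @param taxon_prefix taxon filter/normalization prefix (e.g. `"3702."`).
#' @param collapse_isoform collapse `.<digits>` isoform suffixes?
#' @inheritParams seedpath
#' @return the fitted [seedpath()] object, invisibly (or a
#'   `seedpath_partial` progress object for an incomplete checkpointed
#'   run).
#' @export
run_seedpath_analysis <- function(links = NULL, seeds, out_dir,
                                  network = NULL,
                                  taxon_prefix = "",
                                  collapse_isoform = TRUE,
                                  mode = c("all-paths", "per-pair"),
                                  n_permutations = 1000L,
                                  threshold = 0.05,
                                  comparison = c("gt", "ge"),
                                  universe = c("all-nodes",
                                               "non-seed-nodes"),
                                  rng_seed = 1L, checkpoint_dir = NULL,
                                  max_compute = Inf, verbose = FALSE) {
  mode <- match.arg(mode)
  comparison <- match.arg(comparison)
  universe <- match.arg(universe)

  net <- if (inherits(network, "ppi_network")) {
    network
  } else if (!is.null(network)) {
    with_stage("network_io", read_edge_table(network))
  } else {
    if (is.null(links)) {
      stop("either `links` or `network` must be supplied", call. = FALSE)
    }
    with_stage("network_io", {
      rec <- parse_string_links(links, taxon_prefix)
      rec$protein_a <- normalize_id(rec$protein_a, taxon_prefix,
                                    collapse_isoform)
      rec$protein_b <- normalize_id(rec$protein_b, taxon_prefix,
                                    collapse_isoform)
      n_raw <- attr(rec, "n_raw_records")
      net <- build_network(rec)
      net$n_raw_records <- n_raw
      net
    })
  }

  seed_set <- with_stage("network_io",
                         read_seed_list(seeds, net, taxon_prefix,
                                        collapse_isoform))

  fit <- seedpath(net, seed_set, mode = mode,
                  n_permutations = n_permutations, threshold = threshold,
                  comparison = comparison, universe = universe,
                  rng_seed = rng_seed, checkpoint_dir = checkpoint_dir,
                  max_compute = max_compute, verbose = verbose)
  if (inherits(fit, "seedpath_partial")) return(invisible(fit))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- config_echo_lines(fit$config)
  with_stage("write_outputs", {
    write_edge_table(net, file.path(out_dir, "edge_table.tsv"))
    write_betweenness_table(fit$betweenness,
                            file.path(out_dir, "betweenness.tsv"),
                            comments = hdr)
    write_fdr_table(fit$fdr, file.path(out_dir, "fdr.tsv"),
                    comments = hdr)
    write_fdr_table(fit$candidates, file.path(out_dir, "candidates.tsv"),
                    comments = hdr)
    write_run_report(fit$report, file.path(out_dir, "run_report.tsv"))
    summarize(fit$report, file = file.path(out_dir, "summary.txt"))
  })
  invisible(fit)
}

# machine-readable key-value report (TSV key<TAB>value)
write_run_report <- function(report, path) {
  cfg <- report$config_echo
  scalar <- report[setdiff(names(report), "config_echo")]
  kv <- c(vapply(names(scalar),
                 function(k) paste(k, scalar[[k]], sep = "\t"), ""),
          vapply(names(cfg),
                 function(k) paste(paste0("config_", k), cfg[[k]],
                                   sep = "\t"), ""))
  writeLines(kv, path)
  invisible(path)
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key: value` or `key=value`; `#` comments and blank
#' lines ignored. Recognized keys: `mode`, `n_permutations`, `threshold`,
#' `comparison`, `universe`, `rng_seed`, `taxon_prefix`,
#' `collapse_isoform`.
#'
#' @param path config file path.
#' @return named list of configuration values with proper types.
#' @export
read_run_config <- function(path) {
  lines <- read_input_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ",
         paste(utils::head(lines[bad], 5L), collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(m, `[`, "", 2L)
  vals <- vapply(m, `[`, "", 3L)
  out <- stats::setNames(as.list(vals), keys)
  for (k in intersect(names(out), c("n_permutations", "rng_seed"))) {
    out[[k]] <- as.integer(out[[k]])
  }
  if ("threshold" %in% names(out)) {
    out$threshold <- as.numeric(out$threshold)
  }
  if ("collapse_isoform" %in% names(out)) {
    out$collapse_isoform <- toupper(out$collapse_isoform) %in%
      c("TRUE", "T", "YES", "1")
  }
  out
}
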