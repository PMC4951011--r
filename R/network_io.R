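#' Parse a STRING-style protein.links edge list
#'
#' Reads whitespace-separated interaction records of the form
#' `protein1 protein2 combined_score`, the dialect of STRING
#' `protein.links` dumps. Multi-organism dumps are filtered by a taxon
#' prefix (e.g. `"3702."` keeps only Arabidopsis thaliana lines). An
#' optional header line (third token non-numeric) and blank lines are
#' skipped.
#'
#' @param source path to a links file, or a character vector of lines
#'   (treated as lines when it has length > 1 or contains whitespace).
#' @param taxon_prefix keep only lines whose two protein IDs both start with
#'   this prefix; `""` keeps all lines.
#' @return A data.frame of interaction records with columns `protein_a`,
#'   `protein_b` and integer `score`, one row per kept line. The attribute
#'   `n_raw_records` holds the number of data lines before taxon filtering
#'   (STRING dumps list each pair in both directions, so this is the count
#'   to reconcile with published "number of PPIs" figures).
#' @seealso [build_network()], [normalize_id()]
#' @examples
#' lines <- c("protein1 protein2 combined_score",
#'            "3702.AT1G01010.1 3702.AT1G01020.1 900",
#'            "9606.P1 9606.P2 400")
#' parse_string_links(lines, taxon_prefix = "3702.")
#' @export
parse_string_links <- function(source, taxon_prefix = "") {
  lines <- read_input_lines(source)
  if (length(lines) == 0L) {
    return(empty_records(n_raw = 0L))
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(empty_records(n_raw = 0L))
  }

  toks <- strsplit(trimws(lines), "\\s+")
  ntok <- lengths(toks)

  # header: a leading line whose third token is non-numeric
  # (e.g. "combined_score"); later non-numeric scores are parse errors
  is_header <- rep(FALSE, length(toks))
  is_header[1L] <- ntok[1L] >= 3L &&
    is.na(suppressWarnings(as.numeric(toks[[1L]][3L])))
  if (any(is_header)) {
    toks <- toks[!is_header]
    lineno <- lineno[!is_header]
    ntok <- ntok[!is_header]
  }
  if (length(toks) == 0L) {
    return(empty_records(n_raw = 0L))
  }
  if (any(ntok < 3L)) {
    bad <- lineno[ntok < 3L]
    stop("malformed links line(s) with fewer than 3 fields at line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }

  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  score_chr <- vapply(toks, `[`, "", 3L)
  score <- suppressWarnings(as.integer(score_chr))
  bad_score <- is.na(score) | score_chr != as.character(score)
  if (any(bad_score)) {
    stop("non-integer combined score at line(s): ",
         paste(utils::head(lineno[bad_score], 10L), collapse = ", "),
         call. = FALSE)
  }

  n_raw <- length(a)
  if (nzchar(taxon_prefix)) {
    sel <- startsWith(a, taxon_prefix) & startsWith(b, taxon_prefix)
    a <- a[sel]
    b <- b[sel]
    score <- score[sel]
  }
  rec <- data.frame(protein_a = a, protein_b = b, score = score,
                    stringsAsFactors = FALSE)
  attr(rec, "n_raw_records") <- n_raw
  rec
}

empty_records <- function(n_raw) {
  rec <- data.frame(protein_a = character(), protein_b = character(),
                    score = integer(), stringsAsFactors = FALSE)
  attr(rec, "n_raw_records") <- n_raw
  rec
}

# A character vector is a set of lines if it cannot be a single path.
read_input_lines <- function(source) {
  if (is.character(source) &&
      (length(source) != 1L || grepl("[\n[:space:]]", source)) ) {
    return(as.character(source))
  }
  if (is.character(source)) {
    if (!file.exists(source)) {
      stop("input file not found: ", source, call. = FALSE)
    }
    return(readLines(source, warn = FALSE))
  }
  if (inherits(source, "connection")) {
    return(readLines(source, warn = FALSE))
  }
  stop("unsupported input source of class ", class(source)[1L], call. = FALSE)
}

#' Normalize a protein identifier to a gene-level identifier
#'
#' Strips a leading taxon prefix (STRING IDs look like
#' `3702.AT5G63310.1`) and, optionally, a trailing `.<digits>` isoform
#' suffix, yielding gene-level IDs such as `AT5G63310`. Idempotent.
#'
#' @param token character vector of identifiers.
#' @param taxon_prefix prefix to strip when present (e.g. `"3702."`).
#' @param collapse_isoform drop a trailing `.<digits>` suffix?
#' @return character vector of normalized identifiers.
#' @examples
#' normalize_id("3702.AT5G63310.1", "3702.")         # "AT5G63310"
#' normalize_id("3702.AT5G63310.2", "3702.", FALSE)  # "AT5G63310.2"
#' @export
normalize_id <- function(token, taxon_prefix = "", collapse_isoform = TRUE) {
  stopifnot(is.character(token))
  if (any(!nzchar(token))) stop("empty identifier token", call. = FALSE)
  out <- token
  if (nzchar(taxon_prefix)) {
    has <- startsWith(out, taxon_prefix)
    out[has] <- substring(out[has], nchar(taxon_prefix) + 1L)
  }
  if (collapse_isoform) {
    out <- sub("\\.[0-9]+$", "", out)
  }
  if (any(!nzchar(out))) {
    stop("identifier reduced to empty string after normalization: ",
         paste(utils::head(token[!nzchar(out)], 5L), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Build an undirected weighted network from interaction records
#'
#' Converts validated interaction records into an undirected weighted
#' graph. Each edge weight is `1000 - score`, so stronger interactions
#' (higher combined scores) get lighter edges and are favoured by
#' shortest-path search. Self-loops are dropped; reciprocal duplicates
#' `{a,b}`/`{b,a}` are merged; when the same pair carries conflicting
#' scores the maximum score (minimum weight) is kept and the conflict is
#' counted.
#'
#' @param records data.frame with columns `protein_a`, `protein_b`, `score`
#'   (as from [parse_string_links()]), IDs already normalized if desired.
#' @param validate check that all scores lie in \[150, 999\]?
#' @return A `ppi_network` object: list with `nodes` (character vector),
#'   `edges` (data.frame `node_a`, `node_b`, integer `weight`, with
#'   `node_a < node_b` lexicographically) and bookkeeping counts
#'   `n_records`, `n_self_loops`, `n_duplicates`, `n_conflicts`.
#' @examples
#' rec <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
#'                   score = c(400L, 700L))
#' net <- build_network(rec)
#' net$edges    # single A-B edge, weight 300
#' @export
build_network <- function(records, validate = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("protein_a", "protein_b", "score") %in% names(records)))
  a <- as.character(records$protein_a)
  b <- as.character(records$protein_b)
  score <- as.integer(records$score)
  if (validate && length(score)) {
    bad <- which(score < 150L | score > 999L | is.na(score))
    if (length(bad)) {
      stop("combined score outside [150, 999] in record(s) ",
           paste(utils::head(bad, 10L), collapse = ", "),
           " (e.g. ", a[bad[1L]], " - ", b[bad[1L]], " score ",
           score[bad[1L]], ")", call. = FALSE)
    }
  }
  n_records <- length(a)

  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; score <- score[!self]

  # canonical unordered pair: node_a < node_b
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")

  n_dup <- 0L
  n_conflict <- 0L
  if (anyDuplicated(key)) {
    best <- tapply(score, key, max)
    rng <- tapply(score, key, function(s) length(unique(s)) > 1L)
    n_conflict <- sum(rng)
    first <- !duplicated(key)
    n_dup <- length(key) - sum(first)
    a <- a[first]; b <- b[first]
    score <- as.integer(best[key[first]])
  }

  ord <- order(a, b, method = "radix")
  a <- a[ord]; b <- b[ord]; score <- score[ord]

  nodes <- sort(unique(c(a, b)))
  edges <- data.frame(node_a = a, node_b = b,
                      weight = 1000L - score, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 n_records = n_records, n_self_loops = n_self,
                 n_duplicates = n_dup, n_conflicts = n_conflict),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("Weighted undirected interaction network\n")
  cat("  nodes:", length(x$nodes), "  edges:", nrow(x$edges), "\n")
  cat("  built from", x$n_records, "records (",
      x$n_self_loops, "self-loops dropped,",
      x$n_duplicates, "duplicate pairs merged,",
      x$n_conflicts, "score conflicts resolved by max score )\n")
  if (nrow(x$edges)) {
    cat("  weight range: [", min(x$edges$weight), ",",
        max(x$edges$weight), "]\n")
  }
  invisible(x)
}

#' Read a seed (validated) gene list
#'
#' One identifier per line, `#` comments and blank lines ignored,
#' duplicates collapsed. Identifiers are normalized with the same options
#' as the network, then intersected with the network's nodes; absent IDs
#' are counted, not fatal.
#'
#' @param source path or character vector of lines.
#' @param network a `ppi_network`.
#' @inheritParams normalize_id
#' @return A `seed_set` object: list with `requested` (unique normalized
#'   IDs as read), `in_network` (subset present among network nodes),
#'   `dropped` and `dropped_count`.
#' @export
read_seed_list <- function(source, network, taxon_prefix = "",
                           collapse_isoform = TRUE) {
  stopifnot(inherits(network, "ppi_network"))
  lines <- read_input_lines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(if (length(lines)) {
    normalize_id(lines, taxon_prefix, collapse_isoform)
  } else character())
  in_net <- ids[ids %in% network$nodes]
  dropped <- setdiff(ids, in_net)
  if (length(in_net) == 0L) {
    stop("none of the ", length(ids),
         " seed identifiers are present in the network; analysis cannot run",
         call. = FALSE)
  }
  structure(list(requested = ids, in_network = in_net,
                 dropped = dropped, dropped_count = length(dropped)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("Seed gene set:", length(x$requested), "requested,",
      length(x$in_network), "in network,",
      x$dropped_count, "dropped\n")
  invisible(x)
}

#' Write / read the network edge table
#'
#' Serializes a network as a TSV `node_a<TAB>node_b<TAB>weight` with a
#' header row, edges in lexicographic order (the on-disk mirror of an
#' "edge information" supplementary table). `read_edge_table()` is the
#' lossless inverse; it also accepts leading `#` comment lines.
#'
#' @param network a `ppi_network`.
#' @param path output (input) file path.
#' @return `write_edge_table()` returns `path` invisibly;
#'   `read_edge_table()` returns a `ppi_network`.
#' @export
write_edge_table <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("node_a\tnode_b\tweight", con)
  if (nrow(network$edges)) {
    writeLines(paste(network$edges$node_a, network$edges$node_b,
                     network$edges$weight, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L || lines[1L] != "node_a\tnode_b\tweight") {
    stop("not an edge table: expected header 'node_a\\tnode_b\\tweight'",
         call. = FALSE)
  }
  lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(build_network(empty_records(0L), validate = FALSE))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) != 3L)) {
    stop("malformed edge table row(s)", call. = FALSE)
  }
  w <- as.integer(vapply(toks, `[`, "", 3L))
  if (anyNA(w)) stop("non-integer weight in edge table", call. = FALSE)
  rec <- data.frame(protein_a = vapply(toks, `[`, "", 1L),
                    protein_b = vapply(toks, `[`, "", 2L),
                    score = 1000L - w, stringsAsFactors = FALSE)
  build_network(rec, validate = FALSE)
}

# CSR adjacency (0-based) for the C++ kernel; undirected edges stored in
# both directions.
sp_adjacency <- function(network) {
  n <- length(network$nodes)
  ai <- match(network$edges$node_a, network$nodes)
  bi <- match(network$edges$node_b, network$nodes)
  from <- c(ai, bi)
  to <- c(bi, ai)
  w <- rep.int(as.numeric(network$edges$weight), 2L)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; w <- w[ord]
  head <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(n = n, head = as.integer(head), nbr = as.integer(to - 1L), wt = w)
}
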