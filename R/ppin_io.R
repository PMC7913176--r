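# Readers, writers and canonicalization for protein-protein interaction
# networks, seed gene lists and symbol maps.

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. All symbol comparison in the
#' package happens after this pass, so case mismatches between a seed list and
#' an interactome never silently lose genes.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @keywords internal
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct an interaction network
#'
#' Builds a simple undirected network of gene symbols from parallel vectors of
#' edge endpoints. Self-loops and duplicate edges (in either orientation) are
#' removed and counted.
#'
#' @param from,to Character vectors of edge endpoints (already normalized).
#' @param source_label Free-text provenance label.
#' @param extra_log Named list of additional bookkeeping counts to carry.
#' @return An `interaction_network` object: a list with elements `graph`
#'   (an undirected simple [igraph::graph]), `source_label`, and `log`
#'   (named list of counts: `self_loops_removed`, `duplicates_removed`, ...).
#' @export
interaction_network <- function(from, to, source_label = "", extra_log = list()) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]
  to <- to[!loops]
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  dup <- duplicated(key)
  n_dups <- sum(dup)
  from <- from[!dup]
  to <- to[!dup]
  if (length(from) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                                  stringsAsFactors = FALSE),
                                       directed = FALSE)
  }
  structure(list(graph = g,
                 source_label = source_label,
                 log = c(list(self_loops_removed = n_loops,
                              duplicates_removed = n_dups),
                         extra_log)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network '%s': %d nodes, %d edges>\n",
              x$source_label, network_nodes_count(x), network_edges_count(x)))
  invisible(x)
}

#' Node symbols of a network
#' @param net An `interaction_network`.
#' @return Character vector of node symbols.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname network_nodes
#' @export
network_nodes_count <- function(net) igraph::vcount(net$graph)

#' Edge list of a network
#' @param net An `interaction_network`.
#' @return Two-column character matrix; each row one undirected edge, the
#'   smaller symbol first.
#' @export
network_edges <- function(net) {
  if (igraph::ecount(net$graph) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  m <- cbind(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @rdname network_nodes
#' @export
network_edges_count <- function(net) igraph::ecount(net$graph)

#' Node degrees in a network
#' @param net An `interaction_network`.
#' @return Named integer vector of degrees.
#' @export
network_degrees <- function(net) igraph::degree(net$graph)

biogrid_find_col <- function(nms, pattern) {
  hit <- grep(pattern, nms, ignore.case = TRUE)
  if (length(hit) == 0L) {
    stop("biogrid_tab3 file lacks a column matching '", pattern, "'",
         call. = FALSE)
  }
  hit[1]
}

is_human_organism <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x == "9606" | x == "homo sapiens" | x == "human"
}

# Header auto-detection for generic two-column edge lists: the first row is
# treated as a header when either field contains characters outside the usual
# symbol alphabet (alphanumerics plus - _ . @ /) or matches a common header
# word. Pass header = TRUE/FALSE to override.
looks_like_header <- function(fields) {
  words <- c("gene", "gene_a", "gene_b", "genea", "geneb", "source", "target",
             "node1", "node2", "from", "to", "interactor_a", "interactor_b",
             "symbol_a", "symbol_b", "protein1", "protein2")
  any(tolower(trimws(fields)) %in% words) ||
    any(grepl("[^A-Za-z0-9_.@/-]", trimws(fields)))
}

#' Read a protein-protein interaction network
#'
#' Parses an edge-list file into a simple undirected network of normalized
#' gene symbols. Three dialects are supported:
#'
#' * `generic_tsv`: two tab-separated symbol columns; an optional header row
#'   is auto-detected (disable with `header = FALSE`).
#' * `biogrid_tab3`: tab-delimited with named columns; only the official
#'   symbol columns for interactors A/B and the organism columns are consumed,
#'   and rows where either organism is not human (taxid 9606) are dropped.
#' * `hprd_flat`: headerless tab-delimited flat file with gene symbols at
#'   fixed positions 1 and 4.
#'
#' Rows with empty or missing symbols are dropped and counted, then self-loops
#' and duplicate edges are removed.
#'
#' @param path Path to the file.
#' @param dialect One of `"generic_tsv"`, `"biogrid_tab3"`, `"hprd_flat"`.
#' @param header For `generic_tsv` only: `NA` (auto-detect, default), `TRUE`
#'   or `FALSE`.
#' @param source_label Provenance label; defaults to the file name.
#' @return An [interaction_network]. Its `log` records `rows_read`,
#'   `rows_dropped_missing`, `rows_dropped_nonhuman`, `self_loops_removed`
#'   and `duplicates_removed`.
#' @export
read_network <- function(path,
                         dialect = c("generic_tsv", "biogrid_tab3", "hprd_flat"),
                         header = NA,
                         source_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read network file: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  n_nonhuman <- 0L
  if (dialect == "generic_tsv") {
    if (ncol(raw) < 2L) stop("generic_tsv requires two columns", call. = FALSE)
    if (is.na(header)) header <- looks_like_header(unlist(raw[1, 1:2]))
    if (isTRUE(header)) raw <- raw[-1, , drop = FALSE]
    a <- raw[[1]]; b <- raw[[2]]
  } else if (dialect == "biogrid_tab3") {
    nms <- unlist(raw[1, ])
    ia <- biogrid_find_col(nms, "official[ ._]*symbol[ ._]*interactor[ ._]*a")
    ib <- biogrid_find_col(nms, "official[ ._]*symbol[ ._]*interactor[ ._]*b")
    oa <- biogrid_find_col(nms, "organism[ ._]*(id|name)[ ._]*interactor[ ._]*a")
    ob <- biogrid_find_col(nms, "organism[ ._]*(id|name)[ ._]*interactor[ ._]*b")
    raw <- raw[-1, , drop = FALSE]
    human <- is_human_organism(raw[[oa]]) & is_human_organism(raw[[ob]])
    n_nonhuman <- sum(!human)
    raw <- raw[human, , drop = FALSE]
    a <- raw[[ia]]; b <- raw[[ib]]
  } else { # hprd_flat
    if (ncol(raw) < 4L) {
      stop("hprd_flat requires at least four columns", call. = FALSE)
    }
    a <- raw[[1]]; b <- raw[[4]]
  }
  a <- normalize_symbols(a)
  b <- normalize_symbols(b)
  missing <- is.na(a) | is.na(b) | a == "" | b == "" | a == "-" | b == "-"
  n_missing <- sum(missing)
  n_rows <- length(missing) + n_nonhuman
  a <- a[!missing]; b <- b[!missing]
  net <- interaction_network(a, b, source_label = source_label,
                             extra_log = list(
                               rows_read = n_rows,
                               rows_dropped_missing = n_missing,
                               rows_dropped_nonhuman = n_nonhuman))
  if (network_edges_count(net) == 0L) {
    stop("empty network after cleaning (dialect ", dialect, "): ", path,
         call. = FALSE)
  }
  net
}

#' Construct or read a seed gene list
#'
#' `seed_list()` builds the object from a character vector; `read_seed_list()`
#' parses a plain-text file with one symbol per line (`#` starts a comment).
#' Symbols are normalized and de-duplicated. A seed list may contain symbols
#' absent from any given network; mapping loss is reported downstream, never
#' fatal here.
#'
#' @param symbols Character vector of gene symbols.
#' @param provenance Free-text label for the origin of the list.
#' @return A `seed_list` object: list with `symbols` (unique, normalized)
#'   and `provenance`.
#' @export
seed_list <- function(symbols, provenance = "") {
  s <- unique(normalize_symbols(symbols))
  s <- s[s != "" & !is.na(s)]
  structure(list(symbols = s, provenance = provenance), class = "seed_list")
}

#' @rdname seed_list
#' @param path Path to a seed-list file.
#' @export
read_seed_list <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("cannot read seed list: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  seed_list(lines[trimws(lines) != ""], provenance = provenance)
}

#' @export
print.seed_list <- function(x, ...) {
  cat(sprintf("<seed_list '%s': %d symbols>\n", x$provenance,
              length(x$symbols)))
  invisible(x)
}

#' Construct or read an alias-to-approved symbol map
#'
#' The map must be single-valued: an alias listed with two different approved
#' symbols is an error. Aliases absent from the map pass through unchanged
#' when the map is applied.
#'
#' @param alias,approved Parallel character vectors.
#' @return A `symbol_map`: named character vector, names are aliases.
#' @export
symbol_map <- function(alias, approved) {
  alias <- normalize_symbols(alias)
  approved <- normalize_symbols(approved)
  keep <- alias != "" & approved != ""
  alias <- alias[keep]; approved <- approved[keep]
  dup <- duplicated(alias)
  if (any(dup)) {
    conflict <- tapply(approved, alias, function(v) length(unique(v)) > 1L)
    if (any(conflict)) {
      stop("symbol map is not single-valued for alias(es): ",
           paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
    }
    alias <- alias[!dup]; approved <- approved[!dup]
  }
  structure(stats::setNames(approved, alias), class = "symbol_map")
}

#' @rdname symbol_map
#' @param path Path to a two-column TSV (alias, approved), optional header
#'   auto-detected.
#' @export
read_symbol_map <- function(path) {
  if (!file.exists(path)) stop("cannot read symbol map: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("symbol map requires two columns", call. = FALSE)
  if (nrow(raw) > 0L && looks_like_header(unlist(raw[1, 1:2]))) {
    raw <- raw[-1, , drop = FALSE]
  }
  symbol_map(raw[[1]], raw[[2]])
}

map_one <- function(symbols, map) {
  hit <- match(symbols, names(map))
  out <- symbols
  out[!is.na(hit)] <- unname(unclass(map)[hit[!is.na(hit)]])
  out
}

#' Apply a symbol map
#'
#' Relabels every node (or seed symbol) through the alias map; symbols absent
#' from the map are kept verbatim. When two network nodes collapse onto one
#' approved symbol their edge sets merge; self-loops or duplicate edges
#' created by the merge are removed, and the merge count is logged.
#'
#' @param x An [interaction_network] or [seed_list].
#' @param map A [symbol_map].
#' @return Object of the same class with relabeled symbols.
#' @export
apply_symbol_map <- function(x, map) UseMethod("apply_symbol_map")

#' @export
apply_symbol_map.interaction_network <- function(x, map) {
  el <- network_edges(x)
  nodes_before <- network_nodes(x)
  a <- map_one(el[, 1], map)
  b <- map_one(el[, 2], map)
  n_merged <- length(nodes_before) - length(unique(map_one(nodes_before, map)))
  n_unmapped <- sum(!(nodes_before %in% names(map)))
  interaction_network(a, b, source_label = x$source_label,
                      extra_log = list(nodes_merged = n_merged,
                                       nodes_unmapped = n_unmapped))
}

#' @export
apply_symbol_map.seed_list <- function(x, map) {
  seed_list(map_one(x$symbols, map), provenance = x$provenance)
}

#' Largest connected component
#'
#' Returns the connected component with the most nodes. Ties are broken
#' deterministically by the lexicographically smallest member symbol.
#'
#' @param net An [interaction_network].
#' @return An [interaction_network] restricted to the giant component.
#' @export
giant_component <- function(net) {
  if (network_nodes_count(net) == 0L) {
    stop("giant_component: network is empty", call. = FALSE)
  }
  comp <- igraph::components(net$graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    smallest <- vapply(best, function(ci) {
      min(igraph::V(net$graph)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(smallest)][1]
  }
  g <- igraph::induced_subgraph(net$graph,
                                which(comp$membership == best),
                                impl = "auto")
  structure(list(graph = g, source_label = net$source_label,
                 log = c(net$log,
                         list(components_total = comp$no,
                              giant_fraction = max(comp$csize) /
                                network_nodes_count(net)))),
            class = "interaction_network")
}

results_columns <- c("gene", "degree_ppin", "degree_disease", "bc_disease",
                     "mean_bc_random", "relative_bc", "n_g", "r_g",
                     "p_value", "p_adjusted", "is_seed", "is_significant",
                     "is_novel")

#' Write a prioritization result table
#'
#' Writes the per-gene table as TSV with a fixed header, rows sorted by
#' p-value then gene symbol. `read_results()` round-trips the file.
#'
#' @param results A data.frame as produced by [summarize_prioritization()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  missing_cols <- setdiff(results_columns, names(results))
  if (length(missing_cols) > 0L) {
    stop("results table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- results[order(results$p_value, results$gene), results_columns,
                 drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()` returns the table as a data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("cannot read results: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
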