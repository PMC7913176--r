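# Disease-specific subnetwork construction: seeds + first neighbors,
# single-pass pruning of peripheral non-seed nodes, giant component.

#' Extract a disease-specific subnetwork
#'
#' Builds the disease module from a seed gene list in three fixed steps:
#'
#' 1. Induce the subgraph on the mapped seeds and all their first neighbors.
#'    Node induction automatically keeps seed-seed, seed-neighbor and
#'    neighbor-neighbor edges.
#' 2. Prune, in a single pass, every node whose degree in that subgraph is 1
#'    and which is not a mapped seed. (`prune_mode = "fixpoint"` iterates the
#'    pruning until no such node remains; the default single pass removes only
#'    the peripheral fringe.)
#' 3. Keep the largest connected component (ties broken by smallest member
#'    symbol).
#'
#' @param ppin An [interaction_network], normally already restricted to its
#'   giant component.
#' @param seeds A [seed_list].
#' @param prune_mode `"single_pass"` (default) or `"fixpoint"`.
#' @return A `disease_network`: list with `network` (the pruned
#'   [interaction_network]), `seed_flags` (named logical over its nodes),
#'   `mapped_seeds` (seeds found in `ppin`), `mapped_seed_count`,
#'   `lost_seed_count` and `pruned_count`.
#' @export
extract_disease_network <- function(ppin, seeds,
                                    prune_mode = c("single_pass", "fixpoint")) {
  prune_mode <- match.arg(prune_mode)
  stopifnot(inherits(ppin, "interaction_network"), inherits(seeds, "seed_list"))
  nodes <- network_nodes(ppin)
  mapped <- intersect(seeds$symbols, nodes)
  lost <- setdiff(seeds$symbols, nodes)
  if (length(mapped) == 0L) {
    stop(sprintf(
      "no seed from '%s' maps into network '%s'",
      seeds$provenance, ppin$source_label), call. = FALSE)
  }
  g <- ppin$graph
  seed_ids <- match(mapped, nodes)
  nbr <- unique(unlist(igraph::adjacent_vertices(g, seed_ids)))
  keep_ids <- sort(unique(c(seed_ids, nbr)))
  sub <- igraph::induced_subgraph(g, keep_ids)

  pruned <- 0L
  repeat {
    deg <- igraph::degree(sub)
    drop <- deg == 1 & !(igraph::V(sub)$name %in% mapped)
    if (!any(drop)) break
    pruned <- pruned + sum(drop)
    sub <- igraph::delete_vertices(sub, which(drop))
    if (prune_mode == "single_pass") break
  }

  subnet <- structure(list(graph = sub, source_label = ppin$source_label,
                           log = list()), class = "interaction_network")
  gc_net <- giant_component(subnet)
  final_nodes <- network_nodes(gc_net)
  flags <- stats::setNames(final_nodes %in% mapped, final_nodes)
  structure(list(network = gc_net,
                 seed_flags = flags,
                 mapped_seeds = mapped,
                 mapped_seed_count = length(mapped),
                 lost_seed_count = length(lost),
                 pruned_count = pruned,
                 prune_mode = prune_mode,
                 seed_provenance = seeds$provenance),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf(
    "<disease_network: %d nodes (%d seeds), %d edges; %d/%d seeds mapped, %d pruned>\n",
    network_nodes_count(x$network), sum(x$seed_flags),
    network_edges_count(x$network), x$mapped_seed_count,
    x$mapped_seed_count + x$lost_seed_count, x$pruned_count))
  invisible(x)
}

#' Per-interval seed counts
#'
#' Counts, for each degree interval of the stratification, how many mapped
#' seed genes have a full-interactome degree in that interval. These counts
#' are the per-bin quotas used by the stratified background sampler, so the
#' random seed sets reproduce the true seed set's degree profile bin by bin.
#'
#' @param disease_net A `disease_network` from [extract_disease_network()].
#' @param strata A `degree_strata` from [build_strata()] on the same full
#'   interactome.
#' @return Named integer vector, one entry per interval (zeros included);
#'   its sum equals `disease_net$mapped_seed_count`.
#' @export
seed_degree_profile <- function(disease_net, strata) {
  stopifnot(inherits(disease_net, "disease_network"),
            inherits(strata, "degree_strata"))
  idx <- strata$interval_index[disease_net$mapped_seeds]
  if (anyNA(idx)) {
    stop("seed gene(s) missing from strata (inconsistent inputs): ",
         paste(disease_net$mapped_seeds[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  counts <- tabulate(idx, nbins = length(strata$labels))
  stats::setNames(as.integer(counts), strata$labels)
}
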