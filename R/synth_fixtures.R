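# Synthetic fixtures: scale-free interactomes from preferential attachment,
# seed modules, and planted low-degree bridge genes, so the entire pipeline
# is testable without downloading a real interactome.

#' Fixture specification
#'
#' @param n_nodes Total node count.
#' @param attachment Edges added per new node in the preferential-attachment
#'   construction (default 2); also the number of initial nodes, so the edge
#'   count is exactly `attachment * (n_nodes - attachment)`.
#' @param n_modules Number of seed modules (default 2).
#' @param seeds_per_module Seed genes per module (default 25, so that a
#'   two-module fixture on a few hundred nodes has a seed fraction within
#'   reach of real disease gene lists, which cover a sizable fraction of the
#'   curated interactome).
#' @param bridge_degree Degree of the planted bridge node, >= 2 (default 2).
#' @param rng_seed Integer seed; fixtures are reproducible from
#'   (spec, rng_seed) alone.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_nodes, attachment = 2L, n_modules = 2L,
                         seeds_per_module = 25L, bridge_degree = 2L,
                         rng_seed = 1L) {
  spec <- list(n_nodes = as.integer(n_nodes),
               attachment = as.integer(attachment),
               n_modules = as.integer(n_modules),
               seeds_per_module = as.integer(seeds_per_module),
               bridge_degree = as.integer(bridge_degree),
               rng_seed = as.integer(rng_seed))
  with(spec, {
    if (any(vapply(spec, is.na, logical(1))) ||
          n_nodes <= attachment || attachment < 1L || n_modules < 1L ||
          seeds_per_module < 1L || bridge_degree < 2L) {
      stop("infeasible fixture spec", call. = FALSE)
    }
  })
  structure(spec, class = "fixture_spec")
}

fixture_symbols <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a scale-free interactome
#'
#' Preferential attachment: start from `attachment` unconnected nodes; each
#' new node attaches to `attachment` distinct existing nodes chosen with
#' probability proportional to degree + 1. The result is connected with
#' exactly `attachment * (n_nodes - attachment)` edges and a heavy-tailed
#' degree distribution, emulating the scale-free character of real protein
#' interaction networks at test scale.
#'
#' @param spec A [fixture_spec()].
#' @return An [interaction_network] with nodes "G0001", "G0002", ...
#' @export
generate_ppin <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_nodes
  m <- spec$attachment
  set.seed(spec$rng_seed)
  deg <- integer(n)
  n_edges <- m * (n - m)
  from <- integer(n_edges); to <- integer(n_edges)
  e <- 0L
  for (i in (m + 1L):n) {
    pool <- seq_len(i - 1L)
    w <- deg[pool] + 1
    targets <- pool[sample.int(i - 1L, m, prob = w)]
    for (t in targets) {
      e <- e + 1L
      from[e] <- t; to[e] <- i
      deg[t] <- deg[t] + 1L
    }
    deg[i] <- m
  }
  sym <- fixture_symbols(n)
  interaction_network(sym[from], sym[to],
                      source_label = sprintf("synthetic-pa[n=%d,m=%d,seed=%d]",
                                             n, m, spec$rng_seed))
}

#' Select clustered seed modules
#'
#' Deterministically picks `n_modules` pairwise distant module centers (the
#' first is the highest-degree node, each next maximizes the minimum graph
#' distance to previous centers; ties by smallest symbol) and grows each
#' module to `seeds_per_module` genes by breadth-first proximity to its
#' center. Modules are disjoint.
#'
#' @param net An [interaction_network].
#' @param spec A [fixture_spec()].
#' @return List of character vectors, one per module.
#' @export
select_seed_modules <- function(net, spec) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(spec, "fixture_spec"))
  g <- net$graph
  nodes <- network_nodes(net)
  deg <- network_degrees(net)
  d_all <- igraph::distances(g)
  first <- nodes[order(-deg, nodes)][1]
  centers <- first
  while (length(centers) < spec$n_modules) {
    mind <- apply(d_all[, centers, drop = FALSE], 1, min)
    cand <- nodes[order(-mind, nodes)]
    cand <- setdiff(cand, centers)
    centers <- c(centers, cand[1])
  }
  taken <- character(0)
  lapply(centers, function(ctr) {
    ord <- nodes[order(d_all[, ctr], nodes)]
    ord <- setdiff(ord, taken)
    mod <- ord[seq_len(min(spec$seeds_per_module, length(ord)))]
    taken <<- c(taken, mod)
    mod
  })
}

#' Plant a low-degree bridge between two seed modules
#'
#' Rewires the network so that, among the two seed modules and their
#' immediate surroundings, every shortest route from one module to the other
#' passes through one designated low-degree bridge node: every edge between
#' the closed neighborhood of module A (the module plus its first neighbors;
#' common neighbors of both modules are assigned to side A) and the closed
#' neighborhood of module B is cut, and a new bridge node is added with
#' `bridge_degree` edges split between the two sides, anchored at the
#' lowest-degree seed of each module. Within any seed-plus-first-neighbor
#' subnetwork of the modules the bridge is therefore a cut vertex, but nodes
#' outside both neighborhoods keep all their edges, so the global
#' interactome still routes around the bridge — which is exactly what makes
#' the bridge disease-specific rather than globally central.
#'
#' @param ppin An [interaction_network] containing both modules.
#' @param module_a_seeds,module_b_seeds Disjoint character vectors of seed
#'   symbols.
#' @param bridge_degree Total bridge degree, >= 2.
#' @param bridge_symbol Symbol for the new node (default "BRX0001").
#' @return List with `network` (rewired [interaction_network]) and `bridge`
#'   (the bridge symbol).
#' @export
plant_bridge <- function(ppin, module_a_seeds, module_b_seeds,
                         bridge_degree = 2L, bridge_symbol = "BRX0001") {
  stopifnot(inherits(ppin, "interaction_network"))
  if (length(intersect(module_a_seeds, module_b_seeds)) > 0L) {
    stop("seed modules must be disjoint", call. = FALSE)
  }
  nodes <- network_nodes(ppin)
  if (!all(c(module_a_seeds, module_b_seeds) %in% nodes)) {
    stop("module seeds must be network nodes", call. = FALSE)
  }
  if (bridge_symbol %in% nodes) {
    stop("bridge symbol already present in network", call. = FALSE)
  }
  bridge_degree <- as.integer(bridge_degree)
  if (bridge_degree < 2L) stop("bridge_degree must be >= 2", call. = FALSE)

  el <- network_edges(ppin)
  g <- ppin$graph
  closed_nbhd <- function(members) {
    ids <- match(members, nodes)
    union(members,
          nodes[unique(unlist(igraph::adjacent_vertices(g, ids)))])
  }
  side_a <- setdiff(closed_nbhd(module_a_seeds), module_b_seeds)
  side_b <- setdiff(setdiff(closed_nbhd(module_b_seeds), module_a_seeds),
                    side_a)
  cross <- (el[, 1] %in% side_a & el[, 2] %in% side_b) |
    (el[, 1] %in% side_b & el[, 2] %in% side_a)
  el <- el[!cross, , drop = FALSE]

  deg <- network_degrees(ppin)
  k_a <- as.integer(ceiling(bridge_degree / 2))
  k_b <- bridge_degree - k_a
  pick <- function(seeds, k) {
    if (k > length(seeds)) {
      stop("bridge_degree too large for module size", call. = FALSE)
    }
    seeds[order(deg[seeds], seeds)][seq_len(k)]
  }
  bridge_edges <- cbind(rep(bridge_symbol, bridge_degree),
                        c(pick(module_a_seeds, k_a),
                          pick(module_b_seeds, k_b)))

  all_edges <- rbind(el, bridge_edges)
  out <- interaction_network(all_edges[, 1], all_edges[, 2],
                             source_label = paste0(ppin$source_label,
                                                   "+bridge"))
  if (!igraph::is_connected(out$graph) ||
        network_nodes_count(out) != length(nodes) + 1L) {
    stop("rewiring would disconnect the network", call. = FALSE)
  }
  list(network = out, bridge = bridge_symbol)
}

#' Generate a complete bridged fixture
#'
#' Convenience wrapper: generate a scale-free interactome, select two distant
#' seed modules, and plant a low-degree bridge between them. The seed list is
#' the union of the module seeds; the bridge is deliberately *not* a seed, so
#' the pipeline must surface it on topology alone.
#'
#' @param spec A [fixture_spec()] (uses its first two modules).
#' @return List with `network`, `seeds` (a [seed_list]), `bridge`, and
#'   `modules` (the per-module symbol vectors).
#' @export
generate_bridge_fixture <- function(spec) {
  net <- generate_ppin(spec)
  modules <- select_seed_modules(net, spec)
  pb <- plant_bridge(net, modules[[1]], modules[[2]],
                     bridge_degree = spec$bridge_degree)
  seeds <- seed_list(unlist(modules[1:2]),
                     provenance = sprintf("fixture-modules[seed=%d]",
                                          spec$rng_seed))
  list(network = pb$network, seeds = seeds, bridge = pb$bridge,
       modules = modules[1:2])
}

#' Write a fixture to disk
#'
#' Emits a generic two-column TSV edge list and a plain-text seed list that
#' round-trip through [read_network()] and [read_seed_list()].
#'
#' @param net An [interaction_network].
#' @param seeds A [seed_list].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths.
#' @export
write_fixture <- function(net, seeds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edge_path <- file.path(dir, "edges.tsv")
  seed_path <- file.path(dir, "seeds.txt")
  el <- network_edges(net)
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(seeds$symbols, seed_path)
  c(edges = edge_path, seeds = seed_path)
}
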