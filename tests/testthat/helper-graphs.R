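# Shared builders for small deterministic graphs and random fixtures.

# interaction_network from "A-B" edge strings
net_from_strings <- function(edges, label = "test") {
  parts <- strsplit(edges, "-", fixed = TRUE)
  interaction_network(vapply(parts, `[`, "", 1),
                      vapply(parts, `[`, "", 2),
                      source_label = label)
}

path_net <- function(symbols) {
  interaction_network(symbols[-length(symbols)], symbols[-1],
                      source_label = "path")
}

star_net <- function(center, leaves) {
  interaction_network(rep(center, length(leaves)), leaves,
                      source_label = "star")
}

cycle_net <- function(symbols) {
  interaction_network(symbols, c(symbols[-1], symbols[1]),
                      source_label = "cycle")
}

clique_edges <- function(symbols) {
  t(utils::combn(symbols, 2))
}

# Random connected graph on n nodes (n small), via G(n, p) rejection
random_connected_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  repeat {
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    sym <- sprintf("N%02d", seq_len(n))
    g <- igraph::graph_from_data_frame(
      data.frame(from = sym[pairs[1, keep]], to = sym[pairs[2, keep]]),
      directed = FALSE, vertices = data.frame(name = sym))
    if (igraph::is_connected(g)) {
      return(interaction_network(sym[pairs[1, keep]], sym[pairs[2, keep]],
                                 source_label = sprintf("gnp-%d", seed)))
    }
  }
}

edge_set <- function(net) {
  el <- network_edges(net)
  sort(paste(el[, 1], el[, 2], sep = "|"))
}
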