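# Betweenness centrality: fast path (igraph's Brandes implementation) and an
# independent brute-force oracle used only for testing.

#' Betweenness centrality of every node
#'
#' For node v, BC(v) = sum over unordered node pairs (s, t), s != v != t, of
#' sigma_st(v) / sigma_st, where sigma_st counts unweighted shortest s-t paths
#' and sigma_st(v) those passing through v. Values are unnormalized pair
#' counts by default, so small worked examples come out as exact integers or
#' halves; set `normalized = TRUE` to divide by (n-1)(n-2)/2 when comparing
#' networks of different sizes.
#'
#' @param net A connected [interaction_network].
#' @param normalized Logical; divide by the number of ordered... see above.
#' @return Named numeric vector of BC values (a centrality table); the
#'   network's `source_label` is attached as attribute `"label"`.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  if (network_nodes_count(net) == 0L) {
    stop("betweenness: empty network", call. = FALSE)
  }
  if (!igraph::is_connected(net$graph)) {
    stop("betweenness: network is disconnected (pipeline bug upstream?)",
         call. = FALSE)
  }
  bc <- igraph::betweenness(net$graph, directed = FALSE, weights = NA,
                            normalized = FALSE)
  if (normalized) {
    n <- length(bc)
    bc <- if (n > 2) bc / ((n - 1) * (n - 2) / 2) else bc * 0
  }
  bc <- stats::setNames(as.numeric(bc), igraph::V(net$graph)$name)
  attr(bc, "label") <- net$source_label
  bc
}

#' Brute-force betweenness oracle
#'
#' Same contract as [betweenness_centrality()], computed by explicit per-pair
#' shortest-path counting: one breadth-first search per node yields distances
#' and path counts, then for every unordered pair (s, t) each intermediate v
#' with d(s,v) + d(v,t) = d(s,t) contributes sigma_sv * sigma_vt / sigma_st.
#' Structurally independent of the Brandes accumulation used by the fast
#' path; guarded to small networks because it is cubic.
#'
#' @param net A connected [interaction_network].
#' @param max_nodes Guard on network size (default 64).
#' @inheritParams betweenness_centrality
#' @return Named numeric vector of BC values.
#' @export
betweenness_oracle <- function(net, normalized = FALSE, max_nodes = 64L) {
  stopifnot(inherits(net, "interaction_network"))
  n <- network_nodes_count(net)
  if (n > max_nodes) {
    stop("betweenness_oracle: network exceeds guard of ", max_nodes, " nodes",
         call. = FALSE)
  }
  if (n == 0L) stop("betweenness_oracle: empty network", call. = FALSE)
  if (!igraph::is_connected(net$graph)) {
    stop("betweenness_oracle: network is disconnected", call. = FALSE)
  }
  nodes <- network_nodes(net)
  adj <- lapply(igraph::adjacent_vertices(net$graph, seq_len(n)), as.integer)

  bfs_counts <- function(s) {
    dist <- rep.int(NA_integer_, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[u] + 1L
            nxt <- c(nxt, w)
          }
          if (!is.na(dist[w]) && dist[w] == dist[u] + 1L) {
            sigma[w] <- sigma[w] + sigma[u]
          }
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }

  per_source <- lapply(seq_len(n), bfs_counts)
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) {
    ds <- per_source[[s]]$dist
    ss <- per_source[[s]]$sigma
    for (t in (s + 1L):n) {
      dt <- per_source[[t]]$dist
      st <- per_source[[t]]$sigma
      d <- ds[t]
      total <- ss[t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (!is.na(ds[v]) && !is.na(dt[v]) && ds[v] + dt[v] == d) {
          bc[v] <- bc[v] + ss[v] * st[v] / total
        }
      }
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, nodes)
}
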