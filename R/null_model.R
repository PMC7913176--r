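# Degree-stratified background model: stratify the full interactome into
# contiguous degree intervals, resample random seed sets matching the true
# seed degree profile, rebuild the subnetwork, and accumulate per-gene null
# betweenness statistics.

#' Stratify an interactome by degree
#'
#' Partitions all nodes of the full interactome into contiguous degree
#' intervals \[1..w\], \[w+1..2w\], ... of width `bin_width` (default 3, i.e.
#' each interval spans three degrees). Degree-0 nodes (possible only in
#' degenerate single-node networks) are placed in the first interval.
#'
#' @param ppin The full [interaction_network].
#' @param bin_width Positive integer interval width.
#' @return A `degree_strata`: list with `bin_width`, `labels` (e.g. "1-3"),
#'   `members` (list of gene vectors per interval), `interval_index` (named
#'   integer per gene) and `degree` (named integer per gene).
#' @export
build_strata <- function(ppin, bin_width = 3L) {
  stopifnot(inherits(ppin, "interaction_network"))
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1L) {
    stop("bin_width must be a positive integer", call. = FALSE)
  }
  deg <- network_degrees(ppin)
  idx <- stats::setNames(pmax(1L, as.integer(ceiling(deg / bin_width))),
                         names(deg))
  n_bins <- max(idx)
  labels <- sprintf("%d-%d", (seq_len(n_bins) - 1L) * bin_width + 1L,
                    seq_len(n_bins) * bin_width)
  members <- lapply(seq_len(n_bins), function(i) sort(names(deg)[idx == i]))
  names(members) <- labels
  structure(list(bin_width = bin_width,
                 labels = labels,
                 members = members,
                 interval_index = idx,
                 degree = deg),
            class = "degree_strata")
}

#' @export
print.degree_strata <- function(x, ...) {
  cat(sprintf("<degree_strata: width %d, %d intervals, %d genes>\n",
              x$bin_width, length(x$labels), length(x$interval_index)))
  invisible(x)
}

#' Sample a degree-matched random seed set
#'
#' Draws, without replacement and independently within each degree interval,
#' as many genes as the true seed set has in that interval. The sampling pool
#' of each interval is its entire interactome membership (true seed genes
#' included), which guarantees every quota is feasible. Deterministic given
#' `rng_seed`.
#'
#' @param strata A `degree_strata`.
#' @param per_bin_counts Integer vector of per-interval quotas, as from
#'   [seed_degree_profile()]; shorter vectors are zero-padded.
#' @param rng_seed Integer seed.
#' @return A [seed_list] of the sampled genes.
#' @export
sample_random_seeds <- function(strata, per_bin_counts, rng_seed) {
  stopifnot(inherits(strata, "degree_strata"))
  n_bins <- length(strata$labels)
  counts <- rep.int(0L, n_bins)
  counts[seq_along(per_bin_counts)] <- as.integer(per_bin_counts)
  pop <- lengths(strata$members)
  bad <- which(counts > pop)
  if (length(bad) > 0L) {
    stop(sprintf(
      "requested %d genes from interval %s with only %d members",
      counts[bad[1]], strata$labels[bad[1]], pop[bad[1]]), call. = FALSE)
  }
  set.seed(rng_seed)
  picked <- unlist(lapply(seq_len(n_bins), function(i) {
    if (counts[i] == 0L) return(character(0))
    m <- strata$members[[i]]
    m[sample.int(length(m), counts[i])]
  }))
  seed_list(picked, provenance = sprintf("stratified-random[%d]", rng_seed))
}

# Counter-based per-replicate seed derivation: parallel scheduling can never
# change which stream a replicate uses. Kept below 2^31 (R integer range).
replicate_seed <- function(master_seed, r) {
  as.integer((as.double(master_seed %% 2147483647L) * 69069 +
                as.double(r) * 104729) %% 2147483629)
}

#' Run the degree-stratified null model
#'
#' For each of `R` replicates: derive a replicate seed from
#' (`master_seed`, replicate index); draw a degree-matched random seed set
#' with [sample_random_seeds()]; rebuild a background network with
#' [extract_disease_network()] under the identical construction (induce,
#' prune single-degree non-seed nodes, giant component); compute betweenness.
#' For every gene present in the replicate network its presence count n_g is
#' incremented, its background BC added to a running sum, and its exceedance
#' count r_g incremented when the replicate BC is strictly greater than its
#' disease-network BC (`tie_rule = "weak"` counts ties too, giving more
#' conservative p-values). Genes never seen in the disease network are still
#' tracked (they are reported separately, not prioritized).
#'
#' Results are bit-identical regardless of `workers`: replicates carry their
#' own derived seeds and are accumulated in replicate order.
#'
#' @param ppin Full interactome (giant component) used for sampling pools.
#' @param disease_net The `disease_network` whose BC values define the
#'   observed statistics.
#' @param strata `degree_strata` built from `ppin`.
#' @param R Number of background networks (replicates), >= 1.
#' @param master_seed Integer master seed.
#' @param workers Parallel workers (forked; results identical for any value).
#' @param tie_rule `"strict"` (default; BC must exceed) or `"weak"` (ties
#'   count as exceedance).
#' @param prune_mode Passed to [extract_disease_network()].
#' @param disease_bc Optional precomputed centrality table of
#'   `disease_net$network`; computed if `NULL`.
#' @param sample_fun Test hook: `function(r, strata, per_bin_counts,
#'   rng_seed)` returning a [seed_list]; replaces the stratified sampler.
#' @param keep_values Keep the full per-replicate BC values (needed for the
#'   median background summary); off by default to bound memory.
#' @return A `null_accumulator`: list with `genes` (all interactome genes),
#'   `n_g`, `r_g`, `bc_sum` (aligned named vectors), `replicates`,
#'   `replicate_nodes`/`replicate_edges` (per-replicate network sizes),
#'   `disease_bc`, `degree_ppin`, `degree_disease`, `tie_rule`,
#'   `master_seed`, and optionally `values` (per-replicate named BC vectors).
#' @export
run_null <- function(ppin, disease_net, strata, R, master_seed,
                     workers = 1L,
                     tie_rule = c("strict", "weak"),
                     prune_mode = c("single_pass", "fixpoint"),
                     disease_bc = NULL,
                     sample_fun = NULL,
                     keep_values = FALSE) {
  tie_rule <- match.arg(tie_rule)
  prune_mode <- match.arg(prune_mode)
  stopifnot(inherits(ppin, "interaction_network"),
            inherits(disease_net, "disease_network"),
            inherits(strata, "degree_strata"))
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("R must be >= 1", call. = FALSE)
  if (is.null(disease_bc)) {
    disease_bc <- betweenness_centrality(disease_net$network)
  }
  per_bin <- seed_degree_profile(disease_net, strata)

  one_replicate <- function(r) {
    rs <- replicate_seed(master_seed, r)
    seeds_r <- if (is.null(sample_fun)) {
      sample_random_seeds(strata, per_bin, rs)
    } else {
      sample_fun(r, strata, per_bin, rs)
    }
    dn <- tryCatch(
      extract_disease_network(ppin, seeds_r, prune_mode = prune_mode),
      error = function(e) stop(sprintf("replicate %d failed: %s", r,
                                       conditionMessage(e)), call. = FALSE))
    bc <- betweenness_centrality(dn$network)
    list(genes = names(bc), bc = as.numeric(bc),
         n_nodes = length(bc),
         n_edges = as.integer(network_edges_count(dn$network)))
  }

  reps <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(R), one_replicate, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(R), one_replicate)
  }
  failed <- vapply(reps, inherits, logical(1), "try-error")
  if (any(failed)) {
    stop("null replicate(s) failed: ", which(failed)[1], call. = FALSE)
  }

  all_genes <- network_nodes(ppin)
  n_g <- stats::setNames(integer(length(all_genes)), all_genes)
  r_g <- n_g
  bc_sum <- stats::setNames(numeric(length(all_genes)), all_genes)
  obs <- stats::setNames(rep.int(NA_real_, length(all_genes)), all_genes)
  obs[names(disease_bc)] <- as.numeric(disease_bc)

  for (rep_res in reps) {            # strict replicate order: determinism
    idx <- match(rep_res$genes, all_genes)
    n_g[idx] <- n_g[idx] + 1L
    bc_sum[idx] <- bc_sum[idx] + rep_res$bc
    o <- obs[idx]
    exceeds <- if (tie_rule == "strict") {
      !is.na(o) & rep_res$bc > o
    } else {
      !is.na(o) & rep_res$bc >= o
    }
    r_g[idx] <- r_g[idx] + as.integer(exceeds)
  }

  acc <- list(genes = all_genes, n_g = n_g, r_g = r_g, bc_sum = bc_sum,
              replicates = R,
              replicate_nodes = vapply(reps, `[[`, integer(1), "n_nodes"),
              replicate_edges = vapply(reps, `[[`, integer(1), "n_edges"),
              disease_bc = disease_bc,
              degree_ppin = network_degrees(ppin),
              degree_disease = network_degrees(disease_net$network),
              tie_rule = tie_rule, master_seed = master_seed)
  if (keep_values) {
    acc$values <- lapply(reps, function(x) stats::setNames(x$bc, x$genes))
  }
  structure(acc, class = "null_accumulator")
}

#' @export
print.null_accumulator <- function(x, ...) {
  cat(sprintf(
    "<null_accumulator: %d replicates, %d genes tracked; replicate size %.1f +/- %.1f nodes>\n",
    x$replicates, sum(x$n_g > 0), mean(x$replicate_nodes),
    stats::sd(x$replicate_nodes)))
  invisible(x)
}
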