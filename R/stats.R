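# Empirical p-values, multiple-testing correction, prioritization table and
# cross-network overlap testing.

#' Empirical p-value from null-model counts
#'
#' P = (r + 1) / (n + 1), where n counts the background networks in which the
#' gene appeared and r those where its betweenness strictly exceeded the
#' observed disease-network value. The +1 pseudocount keeps the estimate off
#' zero: with 5000 replicates the floor is 1/5001 (about 2e-4). A gene never
#' observed in any background network (n = 0) gets p = 1.
#'
#' @param r_g,n_g Non-negative integer vectors, elementwise r_g <= n_g.
#' @return Numeric vector of p-values in \[1/(n+1), 1\].
#' @export
empirical_pvalue <- function(r_g, n_g) {
  if (length(r_g) != length(n_g)) {
    stop("r_g and n_g must have equal length", call. = FALSE)
  }
  if (any(is.na(r_g)) || any(is.na(n_g)) || any(r_g < 0) || any(n_g < 0) ||
        any(r_g > n_g)) {
    stop("require 0 <= r_g <= n_g", call. = FALSE)
  }
  (r_g + 1) / (n_g + 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment: sort the m p-values
#' increasingly, multiply the i-th by m/i, enforce monotonicity from the top
#' by running minima, cap at 1. Input order is preserved in the output.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Build the per-gene prioritization table
#'
#' Combines the disease-network centrality table with the null-model
#' accumulator into one row per disease-network gene: degrees in the full
#' interactome and in the disease network, observed BC, background BC summary,
#' relative BC (observed / background), the empirical p-value, its BH
#' adjustment over all disease-network genes (seeds included — they are part
#' of the tested family), and the significance/novelty flags. A gene is
#' *novel* when significant after correction and not a seed.
#'
#' Genes tracked by the accumulator but absent from the disease network are
#' returned in the `"background_only"` attribute, not prioritized.
#'
#' @param disease_bc Centrality table from [betweenness_centrality()] on the
#'   disease network.
#' @param acc `null_accumulator` from [run_null()] on the same network.
#' @param seeds The [seed_list] used to build the disease network.
#' @param alpha Significance level for the adjusted p-values (default 0.05).
#' @param background_summary `"mean"` (default) or `"median"`; the median
#'   requires `run_null(..., keep_values = TRUE)`.
#' @return data.frame with columns gene, degree_ppin, degree_disease,
#'   bc_disease, mean_bc_random, relative_bc, n_g, r_g, p_value, p_adjusted,
#'   is_seed, is_significant, is_novel; sorted by p-value then symbol.
#' @export
summarize_prioritization <- function(disease_bc, acc, seeds, alpha = 0.05,
                                     background_summary = c("mean", "median")) {
  background_summary <- match.arg(background_summary)
  stopifnot(inherits(acc, "null_accumulator"), inherits(seeds, "seed_list"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  genes <- names(disease_bc)
  idx <- match(genes, acc$genes)
  untracked <- sum(is.na(idx))
  if (untracked > 0L) {
    message(untracked, " gene(s) in centrality table missing from ",
            "accumulator; treated as never observed (n_g = 0)")
  }
  n_g <- ifelse(is.na(idx), 0L, acc$n_g[idx])
  r_g <- ifelse(is.na(idx), 0L, acc$r_g[idx])
  bc_sum <- ifelse(is.na(idx), 0, acc$bc_sum[idx])

  if (background_summary == "mean") {
    bg <- ifelse(n_g > 0, bc_sum / n_g, NA_real_)
  } else {
    if (is.null(acc$values)) {
      stop("median background summary needs run_null(keep_values = TRUE)",
           call. = FALSE)
    }
    bg <- vapply(genes, function(g) {
      v <- unlist(lapply(acc$values, function(x) x[g]), use.names = FALSE)
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    }, numeric(1))
  }

  p <- empirical_pvalue(r_g, n_g)
  padj <- bh_adjust(p)
  bc_obs <- as.numeric(disease_bc)
  rel <- ifelse(!is.na(bg) & bg > 0, bc_obs / bg, NA_real_)
  is_seed <- genes %in% seeds$symbols
  is_sig <- padj < alpha
  res <- data.frame(
    gene = genes,
    degree_ppin = as.integer(acc$degree_ppin[genes]),
    degree_disease = as.integer(acc$degree_disease[genes]),
    bc_disease = bc_obs,
    mean_bc_random = bg,
    relative_bc = rel,
    n_g = as.integer(n_g),
    r_g = as.integer(r_g),
    p_value = p,
    p_adjusted = padj,
    is_seed = is_seed,
    is_significant = is_sig,
    is_novel = is_sig & !is_seed,
    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$gene), , drop = FALSE]
  rownames(res) <- NULL

  bg_only <- setdiff(acc$genes[acc$n_g > 0], genes)
  if (length(bg_only) > 0L) {
    attr(res, "background_only") <- data.frame(
      gene = bg_only,
      n_g = as.integer(acc$n_g[bg_only]),
      mean_bc_random = acc$bc_sum[bg_only] / acc$n_g[bg_only],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  attr(res, "alpha") <- alpha
  res
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability of observing at least the seen overlap k when
#' |A| genes are drawn from a universe of N genes of which |B| are successes.
#'
#' @param novel_a,novel_b Character vectors of gene symbols, both subsets of
#'   `universe`.
#' @param universe Character vector; the common gene universe.
#' @return An `overlap_test`: list with `a`, `b`, `k`, `N`, `p_value` and
#'   `overlap` (the shared symbols, sorted).
#' @export
overlap_test <- function(novel_a, novel_b, universe) {
  novel_a <- unique(as.character(novel_a))
  novel_b <- unique(as.character(novel_b))
  universe <- unique(as.character(universe))
  if (!all(novel_a %in% universe) || !all(novel_b %in% universe)) {
    stop("both gene lists must be subsets of the universe", call. = FALSE)
  }
  a <- length(novel_a); b <- length(novel_b); N <- length(universe)
  shared <- sort(intersect(novel_a, novel_b))
  k <- length(shared)
  p <- stats::phyper(k - 1, b, N - b, a, lower.tail = FALSE)
  structure(list(a = a, b = b, k = k, N = N, p_value = p, overlap = shared),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test: |A|=%d, |B|=%d, overlap=%d, universe=%d, p=%.4g>\n",
    x$a, x$b, x$k, x$N, x$p_value))
  invisible(x)
}

#' Write an overlap report
#'
#' TSV with one summary row (a, b, k, N, p) followed by the overlapping
#' symbols, one per line.
#'
#' @param ot An `overlap_test`.
#' @param path Output path.
#' @export
write_overlap <- function(ot, path) {
  stopifnot(inherits(ot, "overlap_test"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("a\tb\tk\tN\tp_value",
               sprintf("%d\t%d\t%d\t%d\t%.10g", ot$a, ot$b, ot$k, ot$N,
                       ot$p_value),
               "overlap_gene",
               ot$overlap), con)
  invisible(path)
}
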