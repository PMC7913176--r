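test_that("build_strata: width-3 intervals over degrees 1..7", {
  # degrees 1..7 on designated nodes (plus one degree-4 helper to make the
  # sequence graphical): D1-D3 land in [1-3], D4-D6 in [4-6], D7 in [7-9]
  g <- igraph::realize_degseq(c(1:7, 4))
  el <- igraph::as_edgelist(g)
  sym <- c(sprintf("D%d", 1:7), "X8")
  net <- interaction_network(sym[el[, 1]], sym[el[, 2]])
  strata <- build_strata(net, 3)
  expect_identical(strata$labels, c("1-3", "4-6", "7-9"))
  expect_equal(unname(strata$interval_index[sprintf("D%d", 1:7)]),
               c(1L, 1L, 1L, 2L, 2L, 2L, 3L))
  expect_equal(unname(lengths(strata$members)), c(3, 4, 1))
  expect_setequal(strata$members[["7-9"]], "D7")
  # every node in exactly one interval
  expect_setequal(unlist(strata$members), network_nodes(net))
})

test_that("build_strata: width 1 gives exact-degree bins; bad width errors", {
  net <- star_net("X", c("A", "B", "C"))
  strata <- build_strata(net, 1)
  expect_identical(strata$labels[1], "1-1")
  expect_setequal(strata$members[["1-1"]], c("A", "B", "C"))
  expect_setequal(strata$members[["3-3"]], "X")
  expect_error(build_strata(net, 0), "positive")
})

test_that("build_strata membership equals an independent histogram partition", {
  net <- generate_ppin(fixture_spec(500, rng_seed = 4))
  strata <- build_strata(net, 3)
  el <- network_edges(net)
  deg <- table(factor(c(el[, 1], el[, 2]), levels = network_nodes(net)))
  for (b in seq_along(strata$labels)) {
    lo <- (b - 1) * 3 + 1
    expected <- sort(names(deg)[deg >= lo & deg <= lo + 2])
    expect_identical(strata$members[[b]], expected)
  }
})

test_that("sample_random_seeds: determinism, forced bins, quotas, errors", {
  net <- generate_ppin(fixture_spec(100, rng_seed = 6))
  strata <- build_strata(net, 3)
  pop <- lengths(strata$members)
  counts <- pmin(pop, c(5, 3, rep(0, length(pop) - 2)))

  s1 <- sample_random_seeds(strata, counts, rng_seed = 42)
  s2 <- sample_random_seeds(strata, counts, rng_seed = 42)
  expect_identical(s1$symbols, s2$symbols)
  expect_false(identical(
    s1$symbols, sample_random_seeds(strata, counts, rng_seed = 43)$symbols))

  # all-zero quota -> empty list
  expect_length(sample_random_seeds(strata, 0 * pop, 1)$symbols, 0)

  # a bin whose population equals its quota is taken whole
  full <- 0 * pop
  b <- which(pop > 0)[length(which(pop > 0))]
  full[b] <- pop[b]
  picked <- sample_random_seeds(strata, full, 7)$symbols
  expect_setequal(picked, strata$members[[b]])

  over <- 0 * pop
  over[b] <- pop[b] + 1
  expect_error(sample_random_seeds(strata, over, 1), "only")

  # sampled quota is honored per bin
  got <- sample_random_seeds(strata, counts, 9)$symbols
  expect_equal(unname(tabulate(strata$interval_index[got],
                               nbins = length(pop))),
               unname(counts))
})

make_run <- function(n = 150, rng_seed = 8, n_seeds = 12) {
  net <- generate_ppin(fixture_spec(n, rng_seed = rng_seed))
  set.seed(rng_seed)
  seeds <- seed_list(sample(network_nodes(net), n_seeds), "fix")
  dn <- extract_disease_network(net, seeds)
  strata <- build_strata(net, 3)
  list(net = net, seeds = seeds, dn = dn, strata = strata,
       bc = betweenness_centrality(dn$network))
}

test_that("forced true seeds give n_g = 1, r_g = 0 (strict ties)", {
  rr <- make_run()
  force_true <- function(r, strata, counts, rng_seed) rr$seeds
  acc <- run_null(rr$net, rr$dn, rr$strata, R = 1, master_seed = 1,
                  sample_fun = force_true, disease_bc = rr$bc)
  present <- names(rr$bc)
  expect_equal(unname(acc$n_g[present]), rep(1L, length(present)))
  expect_equal(unname(acc$r_g[present]), rep(0L, length(present)))
  # weak tie rule counts the tie as exceedance
  acc_w <- run_null(rr$net, rr$dn, rr$strata, R = 1, master_seed = 1,
                    tie_rule = "weak", sample_fun = force_true,
                    disease_bc = rr$bc)
  expect_equal(unname(acc_w$r_g[present]), rep(1L, length(present)))
  # genes absent from the single replicate stay at zero
  absent <- setdiff(acc$genes, present)
  expect_true(all(acc$n_g[absent] == 0) && all(acc$r_g[absent] == 0))
})

test_that("accumulator equals a literal single-threaded re-execution", {
  rr <- make_run(n = 200, rng_seed = 10)
  R <- 50
  acc <- run_null(rr$net, rr$dn, rr$strata, R = R, master_seed = 99,
                  disease_bc = rr$bc)
  # literal loop over the same building blocks, accumulated by hand
  per_bin <- seed_degree_profile(rr$dn, rr$strata)
  genes <- network_nodes(rr$net)
  n_g <- stats::setNames(integer(length(genes)), genes)
  r_g <- n_g
  bc_sum <- stats::setNames(numeric(length(genes)), genes)
  for (r in seq_len(R)) {
    rs <- netprio:::replicate_seed(99, r)
    sl <- sample_random_seeds(rr$strata, per_bin, rs)
    dnr <- extract_disease_network(rr$net, sl)
    bcr <- betweenness_centrality(dnr$network)
    for (g in names(bcr)) {
      n_g[g] <- n_g[g] + 1L
      bc_sum[g] <- bc_sum[g] + bcr[[g]]
      if (g %in% names(rr$bc) && bcr[[g]] > rr$bc[[g]]) {
        r_g[g] <- r_g[g] + 1L
      }
    }
  }
  expect_identical(acc$n_g, n_g)
  expect_identical(acc$r_g, r_g)
  expect_equal(acc$bc_sum, bc_sum, tolerance = 1e-12)
  expect_true(all(acc$r_g <= acc$n_g) && all(acc$n_g <= R))
})

test_that("every replicate matches the true per-bin degree histogram", {
  rr <- make_run(n = 180, rng_seed = 14)
  seen <- new.env()
  seen$hists <- list()
  recorder <- function(r, strata, counts, rng_seed) {
    sl <- sample_random_seeds(strata, counts, rng_seed)
    seen$hists[[r]] <- tabulate(strata$interval_index[sl$symbols],
                                nbins = length(strata$labels))
    sl
  }
  invisible(run_null(rr$net, rr$dn, rr$strata, R = 25, master_seed = 3,
                     sample_fun = recorder, disease_bc = rr$bc))
  truth <- unname(seed_degree_profile(rr$dn, rr$strata))
  for (h in seen$hists) expect_equal(h, truth)
})

test_that("results are bitwise invariant to the number of workers", {
  rr <- make_run(n = 120, rng_seed = 15)
  a1 <- run_null(rr$net, rr$dn, rr$strata, R = 16, master_seed = 5,
                 workers = 1, disease_bc = rr$bc)
  a4 <- run_null(rr$net, rr$dn, rr$strata, R = 16, master_seed = 5,
                 workers = 4, disease_bc = rr$bc)
  for (f in c("n_g", "r_g", "bc_sum", "replicate_nodes", "replicate_edges")) {
    expect_identical(a1[[f]], a4[[f]], info = f)
  }
})

test_that("raising a gene's observed BC can only lower its exceedance count", {
  rr <- make_run(n = 120, rng_seed = 16)
  acc1 <- run_null(rr$net, rr$dn, rr$strata, R = 30, master_seed = 2,
                   disease_bc = rr$bc)
  bumped <- rr$bc
  g <- names(bumped)[which.max(unname(bumped))]
  bumped[g] <- bumped[[g]] + 10
  acc2 <- run_null(rr$net, rr$dn, rr$strata, R = 30, master_seed = 2,
                   disease_bc = bumped)
  expect_lte(acc2$r_g[[g]], acc1$r_g[[g]])
  expect_identical(acc1$n_g, acc2$n_g)
})

test_that("replicate network sizes concentrate near the disease network's", {
  rr <- make_run(n = 200, rng_seed = 17)
  acc <- run_null(rr$net, rr$dn, rr$strata, R = 40, master_seed = 6,
                  disease_bc = rr$bc)
  n_obs <- network_nodes_count(rr$dn$network)
  # loose sanity window, not a hard contract: same order of magnitude
  expect_gt(mean(acc$replicate_nodes), n_obs * 0.3)
  expect_lt(mean(acc$replicate_nodes), n_obs * 3)
})
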