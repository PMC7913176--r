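# netprio

Degree-corrected betweenness prioritization of genes in disease-specific
protein–protein interaction (PPI) subnetworks.

## The problem

Given a curated list of disease *seed* genes and an interactome, which genes
occupy topologically pivotal positions in the disease neighborhood? Raw
betweenness centrality (BC) answers the wrong question: it is driven by
degree, so it re-ranks the same well-studied hubs for every disease.
`netprio` scores each gene's BC in the disease subnetwork against
degree-matched random background networks, so that a **low-degree** gene
that happens to broker the traffic between two disease-relevant subsystems
can outrank the hubs.

For node *v*, with σ<sub>st</sub> the number of unweighted shortest paths
between *s* and *t* and σ<sub>st</sub>(v) those passing through *v*:

&nbsp;&nbsp;&nbsp;&nbsp;BC(v) = Σ<sub>s≠v≠t</sub> σ<sub>st</sub>(v) / σ<sub>st</sub> (unordered pairs, unnormalized)

The pipeline:

1. read and canonicalize the interactome (generic TSV, BioGRID TAB3-style,
   or HPRD flat dialects; symbol-map support), keep its giant component;
2. extract the disease network: seeds + first neighbors (node-induced),
   one pruning pass over degree-1 non-seeds, giant component;
3. stratify the full interactome into degree intervals of width 3; note the
   seed count per interval;
4. build R = 5000 background networks by redrawing, per interval, the same
   number of genes at random and repeating step 2; compute BC each time;
5. per gene, the empirical p-value **P = (r + 1)/(n + 1)**, where *n* counts
   backgrounds containing the gene and *r* those where its background BC
   strictly exceeds its disease-network BC; Benjamini–Hochberg correction
   over all disease-network genes; significant non-seeds are the *novel*
   candidates;
6. optionally, intersect novel sets from two interactomes and test the
   overlap with a hypergeometric tail.

## Worked example

Everything runs on synthetic fixtures — a preferential-attachment
interactome with two seed modules joined only (within their neighborhoods)
by a planted degree-2 connector gene:

```r
library(netprio)
fx <- generate_bridge_fixture(fixture_spec(300, rng_seed = 7003))
paths <- write_fixture(fx$network, fx$seeds, "fixture_dir")
cfg <- run_config(paths["edges"], paths["seeds"], replicates = 200,
                  master_seed = 8003, out_dir = "run_out")
out <- run_single(cfg)
#> network 'edges.tsv': 301 nodes, 511 edges
#> giant component: 301 nodes (100.0%), 511 edges
#> disease network: 164 nodes, 278 edges; 50/50 seeds mapped, 59 pruned
#> null model: 200 replicates, size 182.9 +/- 7.7 nodes
out$results[out$results$gene == fx$bridge,
            c("gene", "degree_ppin", "bc_disease", "relative_bc",
              "n_g", "r_g", "p_value")]
#>       gene degree_ppin bc_disease relative_bc n_g r_g p_value
#> 19 BRX0001           2       4920        7.68  47   0  0.0208
```

Read: the planted connector `BRX0001` has interactome degree 2 (at the
fixture median), yet its disease-network betweenness (4920) is 7.7× its
mean betweenness across the 47 background networks that contained it, and
never exceeded there (r = 0), giving the empirical p-value
(0+1)/(47+1) ≈ 0.021 — it ranks 19th of 164 genes, ahead of far better
connected hubs. A full results table (`run_out/results.tsv`) and a
reproducibility manifest (`run_out/manifest.tsv`) are written per run.

With the published protocol's R = 5000 replicates, a gene present in every
background and never exceeded reaches the floor p = 1/5001 ≈ 0.0002.

Command-line driver (same engine):

```sh
Rscript inst/cli/netprio.R fixtures --out fixture_dir --n-nodes 300
Rscript inst/cli/netprio.R run --network fixture_dir/edges.tsv \
    --seeds fixture_dir/seeds.txt --replicates 200 --out run_out
Rscript inst/cli/netprio.R cross --out-a run_out_a --out-b run_out_b --out overlap.tsv
```

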