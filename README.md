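# rwrboost

Integrated network analysis of miRNA and mRNA signatures. Given a list
of differentially expressed miRNAs (DERs), a list of differentially
expressed genes (DEGs), or both, `rwrboost` looks up the miRNA targets
in one or more target databases, forms **seed genes** (by default the
intersection of the DEG list with the DER targets), and propagates them
over a confidence-filtered protein–protein interaction network with
**Random Walk with Restart**:

    u_new = (1 − p) · A · u_old + p · u0

where `A` is the column-normalised adjacency matrix, `p` the restart
probability (default 0.7) and `u0` the restart distribution, uniform
over the seeds. The fixed point scores every gene's network proximity to
the signature; the **boosted gene set** at level ℓ is the seeds plus the
top ⌈ℓ · (n_nodes − n_seeds)⌉ non-seed genes (defaults 1%, 10%, 20%).
Boosted sets are tested for pathway enrichment with the exact
hypergeometric upper tail (BH-adjusted p reported alongside raw), and
the *number* of enriched pathways is calibrated against a size-matched
permutation null with the add-one empirical p estimator
`(r + 1)/(n_perm + 1)` — floor `1/10001 ≈ 9.999e-5` at 10,000
permutations. Hub/centrality reports and a miRNA–gene overlay network
(GraphML / node-link JSON) round out the results.

It is aimed at anyone with paired (or single) miRNA/mRNA hit lists who
wants network-coherent candidates and pathways beyond the one-hop
neighbourhood of the inputs. All input formats are plain text: one-ID-
per-line lists, TSV target tables (several database export dialects),
STRING-style scored edge lists, GMT collections and a symbol↔Entrez map.
A synthetic-fixture generator produces a complete, planted input bundle
so everything runs offline.

## Worked example

```r
library(rwrboost)

spec   <- fixtureSpec(n_genes = 200, planted_module_size = 16, rng_seed = 7)
bundle <- generateCase(spec, tempfile("case"))   # writes all input files

cfg <- defaultConfig()
cfg$der_list    <- bundle$ders
cfg$deg_list    <- bundle$degs
cfg$target_dbs  <- lapply(bundle$targets, function(p)
  list(path = p, dialect = "generic"))
cfg$ppi         <- bundle$ppi
cfg$gmt         <- bundle$gmt
cfg$id_map      <- bundle$id_map
cfg$mirna_names <- bundle$mirna_names
cfg$out_dir     <- tempfile("out")
cfg$ppi_top_fraction <- 1.0   # the desk-scale fixture is already high-confidence
cfg$n_perm      <- 200
cfg$rng_seed    <- 11

res <- runPipeline(cfg)
```

The run reports each stage:

```
[rwrboost] DERs: 5 raw -> 5 canonical (0 unmapped)
[rwrboost] target databases: 2 combined by intersection -> 182 interactions
[rwrboost] DER targets: 26 genes (0 DER(s) absent from the database)
[rwrboost] DEGs: 20 raw -> 20 Entrez (0 unmapped)
[rwrboost] PPI: 200 nodes, 434 edges read
[rwrboost] seed set: 11 genes (0 dropped, absent from network)
[rwrboost] RWR: p = 0.7, 17 iterations, converged = TRUE
[rwrboost] boost 10pct: 30 genes (19 direct, 0 indirect)
[rwrboost] enrichment 10pct: 3 terms at p < 0.01; permutation p = 0.004975
```

Eleven genes are both DEGs and DER targets on the network — the seeds.
At the 10% boosting level the walk adds the 19 highest-scoring non-seed
genes (all one hop from a seed here). Three pathways are enriched at raw
p < 0.01, and only 0/200 size-matched random gene sets did as well
(empirical p = 1/201 ≈ 0.005). The top hit is the planted module:

```r
head(res$enrichment[["10pct"]], 1)
#>   term_id     description overlap term_size query_size universe_size
#> 1 SET0001 synthetic set 1      16        16         30           200
#>        p_value   p_adjusted
#> 1 8.597128e-16 4.298564e-14
```

All 16 planted-module genes sit in the 30-gene boosted set — including
the 8 that were in neither input list — so its term reaches
p ≈ 8.6e-16. `cfg$out_dir` now holds `seeds.tsv`, `scores.tsv`, one
`boosted_*/enrichment_*/permutation_*.tsv` per level, `dotplot.tsv`,
`hubs.tsv`, `network.graphml`, `network.json`, `manifest.json` and
`run.log`. A thin CLI over the same functions is in
`inst/scripts/rwrboost-cli.R` (subcommands `run`, `simulate`, `enrich`,
`rwr`, `metrics`).

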