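# cellcomm

Directed cell-cell communication networks from sorted-population
transcriptomes.

When a tissue is dissociated and its major cell populations are FACS-sorted
and RNA-sequenced in bulk, the resulting genes × populations FPKM table can
be crossed with a curated ligand-receptor catalogue to ask *who talks to
whom*: a directed interaction (ligand L, receptor R, sender s, receiver r)
is supported whenever L is expressed by population s, R by population r, and
(L, R) is a catalogued pair. `cellcomm` implements that inference for
developmental-biology style designs (the motivating setting is four
populations of the embryonic brain — neural, mural, endothelial and
microglial cells), plus the single-cell arm used to validate the sorting
gates themselves.

## The model

With expression `e(g, t)` (FPKM) for gene `g` in population `t`:

- **Detection filter.** Keep genes with mean expression across populations
  strictly greater than `min_mean` (default 10 FPKM).
- **Expression call.** `g` is expressed in `t` when `e(g, t) >= per_type_min`
  (default 10 FPKM).
- **Network.** For every catalogued pair (L, R) and every ordered population
  pair (s, r) — autocrine `s == r` included — emit an edge when L is called
  in s and R in r. Edge strength defaults to the geometric mean
  `sqrt(e(L, s) * e(R, r))` (min, sum and product are available).
- **Enrichment score.** `E(g, t) = e(g, t) / mean_t' e(g, t')` — a gene's
  expression in one population relative to its mean across all populations.
  The per-gene mean of `E` is 1 by construction; a gene expressed in only
  one of four populations scores 4 there.
- **Top-N ranking.** Keep edges whose ligand is population-specific (maximum
  enrichment ≥ `specificity_min`, default 2, attained in the sender), rank
  by strength, break ties lexicographically.
- **Gate purity.** Filter cells to > `min_transcripts` total transcripts
  (default 1,500), cluster on depth-normalised log counts, assign each
  cluster the cell type whose marker panel scores highest, then report per
  gate the percentage of cells whose cluster identity matches the type the
  gate was designed to capture.

A synthetic-data module plants markers, ligand-receptor sender/receiver
patterns and gate contamination with known truth, so every stage is testable
against ground truth.

## Worked example

Using the miniature tables shipped in `inst/extdata/`:

```r
library(cellcomm)
expr <- system.file("extdata", "example_expression.tsv", package = "cellcomm")
lr   <- system.file("extdata", "example_lr_pairs.tsv", package = "cellcomm")

profile <- read_expression_table(expr)
lrdb    <- read_lr_pairs(lr)
net     <- build_network(profile, lrdb)
net
#> Interaction network: 10 directed edges, 5 unique ligand-receptor pairs, 4 populations
#> Thresholds: per_type_min=10, min_mean=10, strength=geomean, case_insensitive=FALSE
```

Ten directed interactions are supported: the Apoe–Ldlr pair is skipped
(`Ldlr` is absent from the profile) and each remaining pair generates one
edge per (sender, receiver) combination that passes the expression calls.
The per-population-pair count table and the vitronectin enrichment row:

```r
pairwise_count_table(net)
#>              receiver
#> sender        neural mural endothelial microglia
#>   neural           0     0           1         0
#>   mural            1     1           3         1
#>   endothelial      0     0           0         0
#>   microglia        1     1           1         0

enr <- enrichment_scores(filter_expressed_genes(profile))
round(enr$scores["Vtn", ], 3)
#>      neural       mural endothelial   microglia
#>       0.000       3.960       0.026       0.013
```

`Vtn` is almost four-fold enriched in mural cells (near the theoretical
maximum of 4 for a single-population gene). Ranking the strongest
population-specific interactions:

```r
rank_top_interactions(net, enr, n = 5)
#>   ligand receptor    sender    receiver strength rank
#> 1    Vtn      Kdr     mural endothelial 212.1320    1
#> 2    Vtn    Itgb1     mural       mural 168.8194    2
#> 3   Apoe     Lrp1 microglia endothelial 154.9193    3
#> 4   Apoe     Lrp1 microglia      neural 141.4214    4
#> 5  Vegfa      Kdr    neural endothelial 134.1641    5
```

The strongest signal is mural vitronectin onto endothelial KDR; a
receptor-centric slice of the KDR hub (`subnetwork(net, "Kdr", "receptor")`)
keeps exactly the Vegfa and Vtn edges converging on endothelial cells.

The same pipeline runs from the shell via the `inst/cli/cellcomm` script
(`simulate`, `build-network` and `purity` subcommands; `--config file.yaml`
and `--key value` flags are equivalent, and every run writes its effective
config and a log next to its outputs).

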