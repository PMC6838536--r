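---
title: "Inferring cell-cell communication networks from sorted-population transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-cell communication networks from sorted-population transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcomm)
```

## The problem

Developing tissue is sustained by signalling between its resident cell
populations: secreted or membrane-bound ligands produced by one population
engage receptors on another (or on the producing population itself —
autocrine signalling). When the major populations of a tissue can be
FACS-sorted to high purity and bulk RNA-sequenced, crossing their expression
profiles with a curated catalogue of ligand-receptor pairs yields an
in-silico map of which communication channels the tissue can support.
`cellcomm` implements that inference and its two companions: a single-cell
arm that quantifies how pure the sorting gates actually were, and a
simulation arm that plants known communication structure so that the whole
pipeline can be validated against ground truth.

The expression-based inference makes two assumptions worth keeping in
view. First, transcript abundance stands in for protein availability: an
interaction is "detected" when both sides are transcribed above threshold,
which says nothing about secretion, diffusion range or binding. Second, the
catalogue is trusted as-is; a pair missing from the catalogue can never be
detected, and a promiscuous catalogue inflates the network. The package
therefore reports what the data *can support*, a hypothesis set for
experimental follow-up, not a measured signalling map.

## The network model

Let $e(g, t)$ be the FPKM of gene $g$ in population $t$, over $T \ge 2$
populations.

1. **Detection filter.** Genes are kept when their arithmetic mean across
   populations is strictly greater than `min_mean` (default 10 FPKM). The
   inequality is strict: a gene at exactly the threshold is removed.
2. **Expression calls.** Gene $g$ is called expressed in $t$ when
   $e(g, t) \ge$ `per_type_min` (default 10 FPKM). The filter above is a
   documented published criterion; the per-population call threshold is
   implicit in the underlying approach, and the least arbitrary default is
   to reuse the same constant. Both are configurable and echoed into all
   output metadata. With `per_type_min = 0` every entry is called (all
   FPKM are non-negative); this edge case is intentional.
3. **Edges.** For every catalogued pair $(L, R)$ and every ordered
   population pair $(s, r)$, including $s = r$, an edge exists when $L$ is
   called in $s$ and $R$ in $r$. All $T^2$ ordered combinations are
   evaluated. Catalogue genes absent from the (filtered) profile are
   skipped with a summary count — the normal situation for any
   catalogue/assay mismatch — rather than raised as errors.
4. **Strength.** The default edge strength is the geometric mean
   $\sqrt{e(L, s)\, e(R, r)}$: symmetric in the two sides, zero when either
   side is absent, and on the FPKM scale. Because the published notion of
   "ranking absolute expression levels" does not pin down one statistic,
   `min`, `sum` and `product` are offered as alternatives behind the same
   interface.
5. **Counting.** Networks always report both the number of directed edges
   and the number of distinct $(L, R)$ gene pairs with at least one edge.
   Published interaction totals are ambiguous between these two accountings,
   so both are always emitted; the per-(sender, receiver) count table sums
   exactly to the directed-edge total.

The **enrichment score** $E(g, t) = e(g, t) / \overline{e(g, \cdot)}$
measures population specificity; its per-gene mean is 1 by construction and
its maximum is $T$ (a gene expressed in exactly one of $T$ populations).
Genes with zero mean are excluded — their score is undefined — with a
warning.

**Top-N ranking** keeps edges whose ligand is population-specific,
operationalised as: the ligand's maximum enrichment is at least
`specificity_min` (default 2, i.e. twice its cross-population mean) *and*
that maximum is attained in the edge's sender. A ubiquitous ligand
(enrichment 1 everywhere) is excluded no matter how strongly it is
expressed. Edges are then sorted by strength descending with a total
lexicographic tie-break on (ligand, receptor, sender, receiver) so output
order is bit-reproducible.

## The gate-purity arm

Sorting gates are validated by single-cell RNA-seq of the sorted cells:

1. **Cell filter.** Cells with strictly more than `min_transcripts`
   (default 1,500) total transcripts are kept — again a strict inequality,
   matching the "more than" phrasing of the criterion it implements.
2. **Clustering.** The clustering stage is a contract, not an algorithm
   commitment: any function from a cells × features matrix and $k$ to an
   assignment can be plugged in via `method=`. The default is $k$-means
   (20 restarts) on log1p counts after scaling each cell to the median
   total count, over the 100 most variable genes. `k = "auto"` chooses
   $k \in 2..k_{max}$ by maximum mean silhouette width. The original
   workflow used a dedicated single-cell clusterer; the purity computation
   downstream is agnostic to the choice, which is why the contract is kept
   swappable.
3. **Identity.** Each cluster is assigned the cell type whose marker panel
   has the highest mean normalised expression in it — marker-based
   annotation, not a majority vote over gate labels, so that gate labels
   remain held out for the purity estimate. Ties (including degenerate
   all-zero clusters) break to the lexicographically first type with a
   low-confidence warning.
4. **Purity.** For each gate, the percentage of its cells whose cluster
   identity equals the type the gate was designed to capture. A gate with
   no retained cells is reported `NA`, never 0 or 100. Purity is invariant
   under relabelling of clusters.

Per-cluster **top enriched genes** reuse the enrichment definition with
cluster means of normalised expression in place of population FPKM; ties
break by absolute expression, then alphabetically. Whether genes-per-cell
summaries are computed before or after the transcript filter is not fixed
by the published description; the package computes them on whatever matrix
it is given, and the pipeline default is after filtering.

## What the simulator emulates — and what it does not

`generate_bulk()` plants, over a shared gene universe: population-specific
markers, ligand-receptor pairs with designated sender/receiver populations,
near-uniform background genes, and silent decoy pairs (catalogued but never
expressed — they exercise the precision side of recovery). Noise is
multiplicative lognormal, the natural choice for positive, right-skewed
FPKM. Defaults are fixed once as the package's study conditions:

- 4 populations (neural, mural, endothelial, microglia), 200 genes,
  10 markers per population, 10 planted pairs;
- on-target expression `base_fpkm = 200`. The binding detection constraint
  for a gene expressed in a single one of $T$ populations is the mean
  filter, $T \times$ `min_mean` = 40 FPKM at the defaults; 200 places
  planted genes five-fold above that constraint (and twenty-fold above the
  per-population call), so that recovery is a property of the method rather
  than of luck at a boundary;
- off-target expression 0.5 FPKM, far below any call; background at
  20 FPKM, above the mean filter but absent from the catalogue.

`generate_single_cell()` draws each cell's true identity as its gate with
probability $1 -$ contamination, else a uniformly random other type;
counts are negative binomial (common dispersion, default size 2) around
type-specific mean programmes, with lognormal per-cell depth
(mean 3,000, log-sd 0.35) so a realistic fraction of cells falls below the
1,500-transcript filter. `simulate_dropout()` emulates shallow single-cell
detection on a bulk profile by zeroing gene rows with probability
$\exp(-\bar e_g / \text{scale})$ — lowly expressed genes are preferentially
lost, so thinning can only shrink the network.

The simulators deliberately do **not** model library-prep read-level
artefacts, UMI collisions, doublets, batch effects, correlated gene
programmes, or continuous differentiation trajectories. Passing the planted
recovery and purity tests therefore shows the pipeline is correct and
well-calibrated under clean, well-separated population structure; it does
not show robustness to the full messiness of real tissue data.

## Numerical and design choices

- All thresholds use the documented strict/non-strict inequalities
  (mean filter and cell filter strict; expression call inclusive).
- Tie-breaks are total and lexicographic everywhere, so repeated runs are
  bit-identical; all randomised stages take explicit integer seeds and
  restore the caller's RNG state.
- Duplicate gene symbols in input tables are an error by default;
  `duplicate_policy = "collapse"` averages rows, opt-in because silent
  averaging of symbol collisions hides real problems.
- Symbol matching between profile and catalogue is case-sensitive by
  default with an opt-in case-insensitive mode (mouse and human catalogues
  case symbols differently).
- Empty results warn rather than fail (an all-filtered profile, a gate with
  zero cells), but structurally invalid input (negative FPKM, non-numeric
  cells, label/cell mismatches, an empty catalogue) always errors.

## Validation scale

The test-suite and `scripts/acceptance.R` properties run at sizes chosen to
make their statistics meaningful while staying quick on a laptop: 100
random instances (≤ 200 genes, ≤ 50 pairs, ≤ 6 populations) for
brute-force oracle equivalence; 10 seeds of lognormal-noise (sd 0.3)
recovery for precision/recall; 5 seeds × 4 gates × 200 cells for the 5%
contamination purity recovery (±3 percentage points around the planted
95%); and 3 seeds for the dropout detection-depth property. The acceptance
script writes every measured quantity with the problem size it used.

## Known limitations

Expression thresholds on FPKM are assay-dependent; 10 FPKM is a published
convention, not a universal constant. The network carries no statistical
significance — no permutation null is computed, matching the original
procedure; downstream tools should treat edge strength as a ranking
heuristic. The purity estimate inherits any failure of the clustering
stage: populations that are not transcriptionally separable will depress
apparent gate purity even for a perfect sort.
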