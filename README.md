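# phylocap

Toolkit for building and using universal target-enrichment marker sets in
phylogenomics, with fungi-scale defaults. It covers the computational core
of a bait-panel design and analysis workflow:

* **Marker selection** — per-locus k-medoids clustering of aligned
  sequences (uncorrected p-distance) with the convergence criterion that at
  least 95% of a gene's sequences lie within a maximum distance
  (default 0.25) of their medoid, searching the smallest medoid count
  first; genes with aligned exons shorter than 600 bp are discarded.
* **Bait design** — 80 bp baits tiled 2× (40 bp step) over the selected
  representative sequences, with N-run rewriting (runs of 1–10 N → T) and
  filters for GC content (pass only if 25% < GC < 67%, strict
  inequalities), repeat content (> 35% soft-masked fails, in the window or
  in the window ± 80 bp region), residual Ns, and multi-locus hits against
  reference genomes (internal seed-and-extend screen, both strands).
* **Tree toolkit** — neighbor joining with bootstrap supports, normalized
  Robinson–Foulds distances (nRF = RF / RF_max after pruning to shared
  leaves), iterative modified Thompson-tau outlier removal of gene trees,
  2D metric MDS + density clustering to detect alternative topology
  clusters, and gene-tree/species-tree concordance counts per edge.
* **Saturation analysis** — stepwise gene addition (random or
  rate-ordered, using mean pairwise p-distance as the relative-rate
  surrogate) to a concatenated matrix, tracking nRF to a reference
  topology and mean bootstrap support as loci accumulate.
* **Capture QC** — per-sample × gene completeness (fraction of the
  reference length recovered) and the multiple-copy filter: the deepest
  copy is kept when it is at least 10× deeper covered than the next copy;
  in strict mode a failing gene is dropped, otherwise the copy most
  similar to the reference is kept.
* **Multilocus barcoding** — a query is inserted into a prealigned
  per-gene database, alignments are block-filtered and concatenated, the
  20 nearest database sequences (at most 4 per species) are skimmed by a
  blastn-score distance (1 − S/(5·L), S = 5·matches − 4·mismatches), and a
  local NJ + bootstrap tree resolves the query's sister clade. A
  loci-resampling analysis quantifies how intraspecific and interspecific
  distance distributions separate as loci are added.
* **Synthetic data** — Yule trees, JC69 sequence evolution,
  planted-cluster alignments, copy tables with coverage, species-complex
  barcode databases with withheld queries, and soft-masked targets, so
  every component is testable offline.

## Worked example

```r
library(phylocap)

# simulate a 10-locus data set on one species tree
spec <- simulation_spec(n_taxa = 10, gene_count = 10, gene_length = 80,
                        rate_multipliers = 0.08, seed = 1)
sim <- simulate_gene_set(spec)

# saturation: how quickly does the concatenated tree stabilise?
curve <- saturation_analysis(sim$genes, "random", step = 2,
                             reference = sim$tree, replicates = 20, seed = 1)
print(as.data.frame(curve))
#>   n_genes nrf_to_reference mean_support
#> 1       2        0.1428571     86.42857
#> 2       4        0.0000000     92.85714
#> 3       6        0.0000000     94.28571
#> 4       8        0.0000000     98.57143
#> 5      10        0.0000000    100.00000
```

With two short loci the tree still differs from the generating topology
(nRF 0.14, one conflicting split) and bootstrap support is modest; from
four loci on the topology is exact and support climbs to 100 — the
plateau the saturation analysis is designed to locate. `autoplot(curve)`
draws both series.

```r
# strict paralog filtering at a 100:5 coverage contrast
spec2 <- simulation_spec(n_taxa = 6, gene_count = 20, gene_length = 150,
                         seed = 1, fraction_multicopy = 0.31,
                         target_coverage = 100, contaminant_coverage = 5)
ct <- make_copy_table(spec2)
dec <- resolve_copy_table(ct$table, ct$references,
                          filter_config(mode = "strict"))
table(dec$decision)
#>  depth_ratio  single
#>           38      82
```

All 38 multi-copy cells pass the ≥10× depth condition (ratio 20) and the
retained copy is the truth-labeled target in every one.

A command-line front end with the same operations ships in
`inst/cli/phylocap` (subcommands `simulate`, `select-markers`,
`design-baits`, `saturation`, `filter-copies`, `barcode`,
`tree-compare`); every run writes a `manifest.json` so reruns are
reproducible.

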