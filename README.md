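# markerscore

Cell-type annotation of scRNA-seq data leans on marker genes — genes whose
expression is specific to one or a few cell types. Many publications have
run large-scale statistical analyses to find such markers, but each reports
its own endpoints (log fold changes, adjusted p-values, AUROCs, ...) with
its own ranges and significance cutoffs, which makes their results hard to
compare or combine. `markerscore` is for curators and analysts who want to
aggregate such heterogeneous per-study marker statistics into robust,
hierarchy-aware marker calls for mouse and human.

## The method

**Cutoff-anchored score.** Every statistical endpoint of every source is
mapped to a *preliminary score* in [0, 1] by a two-segment piecewise-linear
map anchored at the author-declared significance cutoff *c*: for a
lower-is-more-significant endpoint with declared range [*a*, *b*],

```
s(v) = 0.5 + 0.5 (c − v)/(c − a)   for v ≤ c
s(v) = 0.5 − 0.5 (v − c)/(b − c)   for v > c
```

(mirrored for higher-is-more-significant endpoints; out-of-range values are
clamped). The cutoff always scores exactly 0.5, the most significant bound
1, the least significant 0. Preliminary scores are averaged within a source
per gene–cell type pair, giving one *marker gene score* per
(gene, cell type, source).

**Classification.** Scores are aggregated across sources (each source
contributes one value per pair). Genes observed in fewer than 4 cell types
are *indeterminate*, unless one cell type was examined by ≥ 4 sources
(≥ 2 for rare cell types). For the rest, with X = number of cell types
whose aggregated score is significant (mean ≥ 0.5 by default) and Y = the
number of distinct higher-level groups those cell types map to in a pruned
cell-type tree: X = 0 → *non-marker*; X = 1 → *marker* for that cell type,
propagated up its branch; X ≥ 2 and Y = 1 → *higher-level marker* for the
group (not the subtypes); X ≥ 2 and Y ≥ 2 → *marker* if X ≤ 2 (configurable),
otherwise *non-marker* for lack of specificity. A marker is species-specific
when the mouse/human median scores differ ≥ 3-fold with the larger median
above 0.5.

**Ontology.** Raw cell-type hierarchies (e.g. Cell Ontology `is_a` subsets)
are DAGs with multi-parent terms and cyclic curation artifacts;
`prune_to_tree()` reduces them deterministically to a forest (priority-based
single-parent resolution, lexicographic cycle breaking, collapse of
non-branching intermediates) and records every removal.

## Worked example

```r
library(markerscore)

src <- source_metadata(
  "S1", c("mouse", "human"),
  endpoints = list(
    endpoint_definition("log_fc_enrichment", "lower_more_significant",
                        range_min = -9, range_max = 0,
                        significance_cutoff = -2),
    endpoint_definition("adj_p", "lower_more_significant",
                        range_min = 0, range_max = 1,
                        significance_cutoff = 0.05)))

normalize_statistic(-9, src$endpoints$log_fc_enrichment)
#> [1] 1
normalize_statistic(0.05, src$endpoints$adj_p)
#> [1] 0.5

rec <- tibble::tibble(gene_id = "G1", cell_type_id = "beta_cell",
                      source_id = "S1",
                      endpoint_name = c("log_fc_enrichment", "adj_p"),
                      value = c(-9, 0.05), species = "mouse")
score_source(rec, src)
#> # A tibble: 1 × 6
#>   gene_id cell_type_id source_id species marker_gene_score n_endpoints
#>   <chr>   <chr>        <chr>     <chr>               <dbl>       <int>
#> 1 G1      beta_cell    S1        mouse                0.75           2
```

The log fold change of −9 sits at the most significant end of its range
(score 1), the adjusted p-value of 0.05 sits exactly at its cutoff
(score 0.5), and the pair's marker gene score is their average, 0.75 —
evidence clearly past the source's own significance threshold.

A full synthetic pipeline run, from the shell:

```sh
markerscore simulate --outdir fixtures --seed 1 --n-genes 200
markerscore run --stats fixtures/stats.csv --sources fixtures/sources.json \
    --nodes fixtures/ontology_nodes.csv --edges fixtures/ontology_edges.csv \
    --genes fixtures/genes.csv --outdir results
```

which writes `scores.csv`, `markers.csv` (one classified gene per row),
`summary.json` (gene counts per label and per cell type) and a run
manifest. See `vignette("markerscore-methods")` for the model, parameter
and design details.

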