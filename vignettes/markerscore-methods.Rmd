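---
title: "Scoring and classifying cell-type marker genes across heterogeneous studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying cell-type marker genes across heterogeneous studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerscore)
```

## The problem

Published marker-gene analyses are statistically incommensurable: one study
reports Wilcoxon adjusted p-values, another a log fold change enrichment
score on its own scale, a third AUROCs, and each declares its own
significance threshold. `markerscore` makes these comparable by
re-expressing every statistic on a common [0, 1] scale whose midpoint is
pinned to each study's *own* declared cutoff, then aggregating the
rescaled evidence across studies, species and a cell-type hierarchy into
one of four calls per gene: `marker`, `higher_level_marker`, `non_marker`
or `indeterminate`.

## The cutoff-anchored score

For an endpoint with declared range $[a, b]$, cutoff $c$ and
lower-is-more-significant direction, a raw value $v$ (clamped to $[a, b]$)
is mapped piecewise linearly:

$$ s(v) = \begin{cases} 0.5 + 0.5\,\dfrac{c - v}{c - a} & v \le c \\[4pt]
0.5 - 0.5\,\dfrac{v - c}{b - c} & v > c \end{cases} $$

so $s(a) = 1$, $s(c) = 0.5$, $s(b) = 0$; higher-is-more-significant
endpoints are mirrored. Linear interpolation within each segment is the
minimal choice that reproduces all three anchor points, and it keeps the
map strictly monotone inside the declared range. Two numerical edge cases
are handled deliberately:

* a cutoff equal to a range bound would make one segment degenerate
  (division by zero); such endpoint definitions are rejected as
  configuration errors rather than silently patched;
* observed values outside the declared range (curated tables do contain a
  log fold change of $-10$ against a declared minimum of $-9$) are clamped
  to the nearest bound, keeping the score bounded and monotone instead of
  rejecting the row.

Preliminary scores are averaged per gene–cell type pair *within* a source,
over whichever endpoints that pair was actually reported with — missing
endpoints are omitted from the mean, not scored 0, because several sources
only released their significant rows. Mouse and human records of a
dual-species source are scored separately so species medians remain
available downstream.

## Cross-source aggregation and classification

Each source contributes one value per (gene, cell type) to cross-source
aggregation — the mean of its per-species scores — so a dual-species source
is not counted twice. Per pair the package keeps the cross-source mean,
median, the fraction of sources at or above 0.5, and per-species medians.

Genes observed in fewer than `min_cell_types = 4` cell types are gated as
`indeterminate`: with so few contrasts there is no basis for judging
specificity. The gate has a rescue: a gene whose single cell type was
*examined* by at least `min_sources_common = 4` independent sources
(`min_sources_rare = 2` for rare cell types, which few studies can assay)
proceeds anyway. "Examined" is read as *analyzed*, not *found significant*
— the rescue is about data sufficiency, not about the outcome; the
significance judgment happens afterwards, once, in the classification
proper.

For gated-in genes, a pair is significant when its cross-source mean score
is at least 0.5 (ties at exactly 0.5 count). The alternative rule — at
least two-thirds of sources individually at or above 0.5 — is implemented
as `rule = "two_thirds"`; both readings are defensible and the choice is a
configuration knob with `mean` as default. With $X$ = number of significant
cell types and $Y$ = number of distinct higher-level groups among them:

| condition | call |
|---|---|
| $X = 0$ | `non_marker` |
| $X = 1$ | `marker` for that cell type |
| $X \ge 2$, $Y = 1$ | `higher_level_marker` for the group, **not** the subtypes |
| $X \ge 2$, $Y \ge 2$, $X \le 2$ | `marker` for both cell types (default policy) |
| otherwise | `non_marker` (insufficient specificity) |

The fourth row is the `dual_marker_policy = "allow"` default: a strict
reading of the decision diagram would send every $Y \ge 2$ gene to
`non_marker`, but that leaves no way for a gene to be a marker of exactly
two unrelated cell types, a case that plainly occurs in curated corpora;
`"forbid"` restores the strict reading. Either way a gene never marks more
than `max_marker_types = 2` cell types.

A subtype marker's specificity is propagated up its branch: all strict
ancestors are reported in `propagated_cell_types`, flagged as derived
rather than directly called. Genes whose significant cell types span more
than two higher-level groups are additionally listed in the summary's
`review_genes`: such patterns can be artifacts of branches removed during
pruning and deserve manual curation rather than an automated verdict.

**Species specificity** requires a fold difference of at least 3 between
the mouse and human median scores with the larger median above 0.5; a zero
smaller median counts as an infinite fold difference, and a single observed
species yields `insufficient`. The fold comparison carries a $10^{-12}$
relative slack so that an exactly 3-fold gap (e.g. 0.6 vs 0.2) is not lost
to floating-point division. For a higher-level marker, whose group node
need not itself have been assayed, the group's species medians are taken as
the median over its significant subtypes' per-species medians — a
median-of-medians, chosen over pooling raw records so that each subtype
contributes equally regardless of how many sources assayed it.

## Ontology pruning

Classification needs every cell type to have a single chain of ancestors,
but community ontologies are DAGs. `prune_to_tree()` makes the reduction
deterministic where the original curation was manual:

1. multi-parent nodes keep the parent listed first in a curator-supplied
   priority table, else the lexicographically smallest parent ID — the
   priority file is how a curator's actual choices (microglial cell under
   glial cell rather than macrophage) are reproduced;
2. remaining cycles are broken at the edge whose child has the smallest ID,
   making that node a root;
3. non-branching intermediates that are neither roots, leaves, nor
   explicitly `keep`-flagged are collapsed, repeatedly until fixpoint —
   branching intermediates are retained so future cell types can attach.

Every removed edge and node is returned in a report, and the passes
conserve nodes (input = output + collapsed). The result is a forest:
multiple roots (e.g. separate naïve-cell and somatic-cell branches) are
permitted. `is_higher_level` is an input annotation, not inferred from
depth — the exemplar groups (connective tissue cell, T cell) follow no
depth rule; a branch with no flagged ancestor falls back to its root as the
grouping.

## The synthetic corpus generator

`simulate_corpus()` exists so every stage is testable without any private
curated corpus. It generates fixtures at the *statistics* layer — the layer
this tool actually consumes — rather than simulating reads: each planted
(gene, cell type, source) observation draws a latent preliminary score,
perturbs it with Gaussian noise of `noise_sd`, and writes it to each
endpoint's raw scale through the inverse of the normalization map, so the
noiseless round trip is exact to $10^{-9}$.

Defaults (`n_genes = 500`, `n_sources = 6` alternating mouse/human, a
balanced depth-3 tree with 3 children per node, planted fractions
0.25 marker / 0.10 higher-level / 0.10 species-specific, the remainder
split 80/20 between non-markers and sparsely observed indeterminate genes,
`noise_sd = 0.1`, `missing_rate = 0.05`) describe a corpus in which a
typical gene is assayed in 4 cell types by every source with 1–3 endpoints
each — roughly the density of a well-curated multi-study collection.
Planted significant latent scores are drawn on [0.75, 0.95] and
non-significant ones on [0.05, 0.30]: comfortably separated, as befits
author-reported significant results. Species-specific genes use
[0.90, 1.00] against [0.15, 0.25] in the other species' sources; these
bounds guarantee (at zero noise) both the ≥ 3-fold median gap and a
cross-source mean still above 0.5. A few markers are observed only in the
one rare cell type by exactly two sources, exercising the rare-type
rescue.

What the generator does *not* emulate: correlated endpoints within a
source, systematic inter-study bias, genes near the significance boundary,
ragged cell-type coverage, or disagreement between species beyond the
planted specific class. Passing recovery tests therefore shows the
algorithm decodes its own planted structure — including exact recovery at
zero noise, which holds by construction — not that it is robust to every
pathology of real curated corpora.

At the default noise of 0.1 the label recovery measured over 20 seeds is
about 0.99 (the suite asserts a mean of at least 0.97), and recovery
degrades monotonically as noise grows, which the test suite checks at
noise 0, 0.25 and 0.6.

## Problem sizes in the test suite

The suite checks the classification decision table against an independent
brute-force oracle on an exhaustive single-source sweep of all cell-type
subsets up to size 3 (plus a fixed two-group subset of size 4) over the
score grid {0, 0.25, 0.5, 0.75, 1}, and on 800 randomized multi-source
instances with up to 6 cell types and 5 sources under both significance
rules and both dual-marker policies — about 4,300 instances in all.
Recovery runs use the full default corpus (500 genes, 6 sources) across 20
seeds; ontology properties are checked on dozens of random tangled graphs
of up to 25 nodes. These sizes were chosen to exhaust the small-instance
space where the decision table lives while keeping a full test run to a
few minutes.

## Known limitations

* Gene-identifier unification is a static cross-reference join; no live
  MGI/Entrez/Ensembl queries, no fuzzy symbol matching, and multi-mapping
  orthologs must be pre-resolved into distinct keys by the curator.
* The endpoint range is a declared property of the source, not estimated
  from data; a mis-declared range shifts scores.
* The two species are fixed to mouse and human throughout.
* Corpus-scale results depend entirely on the curated input tables;
  the package validates and accounts for rejected rows but cannot judge
  curation quality.
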