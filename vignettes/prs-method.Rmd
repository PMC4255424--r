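---
title: "The Pathway Regulation Score: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Pathway Regulation Score: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`prsenrich` ranks KEGG pathways by how strongly a case--control expression
contrast perturbs them, combining two signals that plain over-representation
ignores: the *magnitude* of each gene's change and the *position* of changed
genes in the pathway's wiring. This vignette explains the model, the choices
we made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the method's known limitations.

# From KGML to gene graphs

KEGG distributes each pathway as a KGML document built from three object
classes: *entries* (the boxes and circles on the map), *relations* (edges
between protein boxes) and *reactions* (substrate/product conversions
catalysed by enzymes). We classify a pathway as **metabolic** exactly when
it contains at least one reaction element — KGML offers no other structural
discriminator — so a file carrying both relations and reactions is treated
as metabolic.

**Signalling pathways.** Gene-bearing entries become nodes and every
relation whose two endpoints resolve to gene entries contributes one
directed edge. Group entries (protein complexes) are expanded: a relation
touching a group fans out to each gene component, which preserves
connectivity without inventing within-complex edges. Relation subtypes
(activation, inhibition, ...) are deliberately ignored for edge creation:
the score is an overall impact assessment, not a signed propagation model.

**Metabolic pathways.** Enzymes become nodes, and compounds orient the
edges: enzyme E1 points to enzyme E2 whenever a product of a reaction
catalysed by E1 is a substrate of a reaction catalysed by E2. For
reversible reactions the direction of conversion is undefined, so both
compound lists act as substrates and as products; this is the conservative
reading that creates an edge wherever material *could* flow. ECrel
relations between enzyme entries add edges directly. We make no attempt to
model flux — a transcriptional change in a connected enzyme is simply
treated as potentially relevant.

**Redundancy removal.** KEGG descriptions frequently repeat a gene across
several boxes. All nodes sharing any gene are merged transitively; the
merged node inherits the union of in- and out-edges, duplicate edges
collapse, and self-edges arising from the merge are deleted. Merged nodes
are named by their lexicographically smallest gene id (radix order,
locale-independent), which makes the operation idempotent and the output
deterministic. Both the PRS denominator and the z-score counts use these
deduplicated graphs, so a highly redundant description is not rewarded.

# Gene-level statistics

The expression table must already be normalized (RMA or similar); the
package never normalizes. Values are assumed log2-scale by default, so the
fold-change magnitude of a probe is `2^|mean(test) − mean(control)|`; a
flag accepts linear-scale input, where the fold-change is the ratio of
group means. Each probe gets a Welch (unequal-variance) two-sided t-test —
the robust default when replicate variances differ between groups. Probes
collapse to genes by keeping the probe with the smallest p-value, ties
broken by larger absolute log2 fold-change and then by probe id. This rule
is deterministic and auditable; it slightly favours the most responsive
probe of a gene, which is the intended behaviour for an impact score but
does bias per-gene fold-change estimates outward relative to averaging
probes. A gene is significant when its fold-change magnitude meets the
threshold (boundary inclusive, default 1.3) **and** its p-value is strictly
below the p threshold (default 0.05). Probes without a mapping row, and
probes with any missing value, are excluded; the expressed universe `T` is
the set of mapped genes surviving these filters, and `F` its significant
subset.

Degenerate probes (both groups constant and equal) have no defined t
statistic; we report p = 1 with a warning, which keeps them conservatively
non-significant. Constant groups with different means get p = 0, the
limiting value.

# Scoring

A node is significant when any member gene is; its magnitude is the
maximum fold-change over significant members (a node is as impacted as its
most-changed gene). Each significant node is weighted by

> 1 + the number of distinct significant nodes reachable from it along
> directed paths whose intermediate vertices are all significant,

computed by an iterative depth-first search with a visited set, so cycles
are counted once and the search terminates on any digraph. The phrase
"via other significant nodes" is read literally: a non-significant node
blocks propagation. The alternative reading — significant targets
reachable through *any* intermediates — is implemented behind the
`through_nonsignificant` switch, default off; on sparse DEG patterns the
blocking rule is more conservative and keeps the weight a function of the
significant subgraph only.

The pathway score is `PRS = Σ FC_i · w_i / N` over significant nodes, with
`N` the deduplicated node count. Normalizing by `N` (rather than by the
DEG count) measures the *density* of coordinated perturbation, so a large
pathway with a small hot corner does not dominate merely by size.

The comparator z-score standardizes `f`, the number of significant pathway
members, against its hypergeometric expectation given `(n, T, F)`. After
deduplication a gene belongs to exactly one node, so we count at the node
level: `n` is the number of nodes with at least one universe gene and `f`
the number of significant nodes. For the common case of single-gene nodes
this equals the gene-level count; for multi-gene nodes it avoids counting
one box several times. When the variance term vanishes (`F = 0`, `F = T`,
or `n = T`) the z-score is undefined and reported as `NA`; such pathways
keep their PRS and are placed last in the z ranking, flagged.

# Permutation significance

The null hypothesis is that the DEG pattern lands on pathways at random.
We permute the per-gene statistics across gene labels — the
(fold-change, significant) pair travels as a unit, so `T` and `F` are
preserved exactly — and recompute every pathway's PRS per permutation. All
pathways share one permutation stream per run; this is cheaper than
independent streams and preserves the cross-pathway correlation of the
null. The empirical p-value is the fraction of permutations whose score
meets or exceeds the observed one (`p = count/n_perm`), so strong pathways
can report exactly 0; users preferring strictly positive estimates can
switch to `(count+1)/(n_perm+1)`. Benjamini--Hochberg adjustment (via
`stats::p.adjust`) converts p-values to q-values, flagged against the
user's FDR threshold (default 0.05). The default permutation count is
1000; a single integer seed fixes the whole stream, and identical seeds
give byte-identical outputs.

Note that the observed statistics themselves are *not* recomputed inside
permutations (no re-testing per permutation): the permutation randomizes
the mapping of precomputed gene statistics onto pathways, which is the
appropriate null for a score built from those statistics.

# The synthetic-data generator

The generator exists so that the whole pipeline is testable offline, with
known ground truth. It emulates:

* KGML structure — gene entries, PPrel relations, enzyme/reaction chains,
  plus three deliberate stress variants (a duplicated gene entry, a
  3-cycle, a group entry);
* log2-scale normalized intensities: per-gene baselines uniform in
  [4, 12] log2 units (the typical RMA range), i.i.d. Gaussian replicate
  noise with standard deviation 0.5 log2 units — a representative
  inter-replicate variability for well-normalized arrays, and large enough
  that a gene passing p < 0.05 at 5+5 replicates essentially always passes
  fold-change 1.3 too, keeping the null DEG rate near the nominal p
  threshold;
* probe redundancy (1--2 probes per gene) and a fraction of unmapped
  probes;
* planted signal: a chosen pathway has a fraction of its genes (default
  80%) shifted by log2 of the planted fold-change (default 2) in the test
  group.

It does **not** emulate probe-level artefacts (background, saturation,
GC-content effects), correlated noise between genes, realistic KEGG
pathway-size distributions, or genes shared between pathways (each
synthetic pathway has a disjoint gene set). Passing tests on this
generator therefore demonstrates the correctness and calibration of the
*method* — graph construction, weighting, scoring, permutation null — not
robustness to array-specific artefacts, which must be handled upstream by
normalization.

Default study conditions are 30 pathways of 8--12 genes and a 5-vs-5
design; the test suite uses 500 permutations and 20 replicate seeds for
its recovery checks, sizes at which the full pipeline runs in seconds
while leaving the binomial tolerances meaningful.

# Numerical and policy details

* All orderings (node ids, rankings, CSV rows) use radix sorting and
  explicit tie-breaks (score descending, then pathway id), so outputs are
  deterministic and locale-independent.
* Exceedance uses `>=` on doubles; permuted and observed scores come from
  the same arithmetic path, so genuine ties (e.g. a permutation that
  reproduces the observed assignment) count as exceedances, which is the
  conservative side.
* Ranked tables print scores with six decimal places; reading the CSV back
  reproduces the written values exactly.
* Reactions lacking a `type` attribute (older KGML dialects) default to
  irreversible — the conservative choice, creating fewer edges.
* Pathways with no gene entries yield empty graphs, are excluded from
  scoring, and are logged rather than raising.

# Known limitations

* Edge semantics are unsigned: inhibition and activation contribute
  equally, so the score measures perturbation, not direction of effect.
* The blocking rule makes weights sensitive to single non-significant
  nodes on otherwise significant chains; near-threshold genes can toggle
  weights discretely.
* The z-score comparison inherits the usual over-representation caveats
  (independence of genes, a well-defined universe).
* One probe represents each gene after collapsing; evidence from
  concordant secondary probes is not pooled.
* Metabolic graphs connect enzymes through shared compound pools without
  stoichiometry; no flux statement is implied.
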