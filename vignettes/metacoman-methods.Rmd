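---
title: "Methods: comparative metatranscriptome analysis from tabular alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative metatranscriptome analysis from tabular alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

metacoman implements the computational core of a two-condition
metatranscriptomics workflow for microbial communities. It deliberately
starts downstream of read alignment: its inputs are BLAST tabular
(outfmt 6, "m8") hit files — reads against a non-coding-RNA reference and
reads against a reference gene catalogue — together with plain-text maps
(gene to KO/COG/EC, gene to phylum, functional hierarchies, pathway
definitions, BGC definitions) and a two-column sample metadata table with
exactly two condition labels. Running aligners, building reference
databases and annotating reference genomes are out of scope; the package
consumes their tabular outputs.

All comparative analyses are two-condition by design. The reference
condition (the fold-change denominator) is the lexicographically smaller
condition label unless overridden; condition labels are otherwise opaque
strings.

# Non-coding-RNA depletion

Reads derived from rRNA/tRNA and other non-coding RNA would bias
functional profiles and are removed first. A read is flagged when its
*best* hit against the ncRNA reference — minimum e-value, ties broken by
maximum bit score and then lexicographically smallest subject id — has an
e-value strictly below the cutoff (default `1e-5`). The tie rules make
best-hit selection a total order, so results never depend on the row
order of the input file. Strictness matters at the boundary: a best hit
at exactly `1e-5` is retained.

Because a full ncRNA database is highly redundant, a random subset of the
reference can stand in for it. `sample_reference_subset()` draws
`floor(fraction * N)` records without replacement under a mandatory seed
(replicate subsets must be reproducible), and `evaluate_subset()`
quantifies the consequences with two overlap ratios: *relative accuracy*
(reads flagged by both subset and full reference, over all reads flagged
with the subset) and *relative sensitivity* (the same intersection over
all reads flagged with the full reference). Both are defined as 1 when
their denominator is empty, since an empty flag set can neither be wrong
nor miss anything.

# Profiling

`assign_best_gene()` applies the identical best-hit rule to
reads-vs-gene hits at the same default cutoff; each retained read counts
toward exactly one gene. `profile_features()` sums gene counts into
feature counts per annotation system (KO, COG, EC) and divides by the
per-system annotated total of the sample, so every non-degenerate column
of a profile sums to 1.

Two conventions deserve explanation because the field is not uniform on
them:

* **Multi-annotated genes count fully toward each feature** rather than
  being split fractionally. This keeps pre-normalisation counts integral
  and matches the semantics of naive annotation transfer; users comparing
  against split-count pipelines should expect small differences for
  promiscuously annotated genes.
* **The relative-abundance denominator is the per-system annotated
  total**, not the total of mapped reads. Each system's profile is
  therefore self-normalised and systems with very different annotation
  coverage remain comparable internally.

`rollup()` lifts a profile one hierarchy level (KO to KEGG pathway,
pathway to class, COG to category, EC to MetaCyc level). A child with
several parents contributes fully to each, which inflates the column
total, so columns are re-normalised afterwards; on a partition hierarchy
the re-normalisation is exactly a no-op and mass is conserved. Children
with no parent are collected under `"Unclassified"` rather than dropped,
so nothing silently vanishes from the profile.

# Differential expression and ordination

Per feature, the two conditions are compared with a two-sided Wilcoxon
rank-sum test: exact when both groups are small and tie-free, otherwise
the normal approximation with tie correction (the `stats::wilcox.test`
defaults). P-values are Benjamini–Hochberg adjusted across the features
of a system, with a default FDR cutoff of 0.10. Fold changes are
`log2((mean_alt + eps) / (mean_ref + eps))` with the pseudocount `eps`
defaulting to half the smallest nonzero relative abundance in the
profile — scale-adaptive, so zero means never produce infinities while
large abundances are essentially unaffected. Rank tests are used rather
than count models because the inputs are compositional relative
abundances, not library-size-scaled counts.

The "most varied functional groups" drive the downstream taxonomy and
network analyses: all FDR-significant features when any exist, otherwise
the up-to-50 largest positive and up-to-50 most negative log2 fold
changes ("not available" is read as *zero* features passing the cutoff).
Ties on |log2 FC| break by smaller raw p, then feature id, making the
selection deterministic.

Sample ordination uses classical (metric) MDS on Bray–Curtis
dissimilarities of the KO profile — Bray–Curtis being the community
ecology default for compositional data — with Euclidean available by
argument. Axis signs from an eigendecomposition are arbitrary, so each
axis is flipped to make its largest-magnitude coordinate positive; the
embedding is then fully deterministic.

# Pathway inference and enrichment

Mapping each observed function to every pathway containing it inflates
pathway counts. The parsimony alternative is a **minimum set cover**:
the smallest set of pathways whose member functions jointly cover every
observed function. With at most `exact_limit` (default 20) candidate
pathways, the optimum is found by exhaustive search over subsets of
increasing size, bounded by the greedy solution; beyond the limit the
classical greedy heuristic is used and the output labelled `"greedy"`.
Ties among optimal covers are broken by preferring covers whose pathways
individually explain more observed functions, then by lexicographic ids,
so the inference is unique and reproducible. Observed functions that
belong to no definition cannot be covered and are dropped with a
warning rather than silently ignored.

Pathway enrichment asks whether a pathway's members shift *coordinately*
between conditions: a two-sample Welch t test of member versus non-member
log2 fold changes, two-sided, the sign of t giving enrichment versus
depletion, BH-adjusted across tested pathways. Sets with fewer than
`min_set_size` (default 3) members present in the DE table are skipped.
This is the core two-sample-t-on-fold-changes form of gene-set
enrichment; no sample-permutation null is layered on top, and the
`"method"` attribute of the result records that. When member and
non-member fold changes are jointly constant the statistic is defined as
0 with p = 1 (no coordinated shift by construction).

# Taxonomy-resolved analyses

Because a feature's abundance is a sum over gene contributions, it
decomposes exactly by the phylum of the contributing genes. The
**taxonomic contribution** of phylum p to a feature is the
between-condition difference of its phylum-p component means; shares are
absolute deltas normalised to sum to 1 and the top phylum is the largest
share (ties lexicographic). The decomposition is additive and exact — no
model is fitted. Features with zero reads everywhere are dropped with a
warning; features whose deltas all vanish are flagged `no_variation`
instead of receiving undefined shares.

The **taxonomic distribution** reports, per feature and condition, the
fraction of the feature's reads contributed by each phylum.

**Transcription activation** separates regulation from composition: gene
expression divided by the phylum's metagenomic abundance in the same
sample. If expression merely tracks taxon abundance the normalised
values are flat and the Wilcoxon comparison is null; genuine activation
or repression survives the normalisation. Taxa profiles are accepted as
fractions or counts (counts are normalised per sample); a phylum at zero
abundance makes the ratio undefined and the value is set missing with a
warning rather than propagated as infinity.

# Biosynthetic gene clusters

A cluster is called transcriptionally detected when at least 50% of its
*biosynthetic* genes (non-biosynthetic members are excluded first) carry
at least one assigned read. The abundance score of a detected cluster is
the mean gene abundance over all its biosynthetic genes, with uncovered
genes entering as zero. Averaging over all genes, not just covered ones,
penalises partially expressed clusters and keeps the score continuous as
coverage crosses the detection threshold; the covered-only variant is
available via `score_genes = "covered"` for comparison with pipelines
using that convention. "Covered" means at least one best-hit read — a
per-base breadth criterion would need positional coverage that gene-level
tabular hits do not resolve. Scores use per-sample read fractions by
default, matching the profiling convention, so they are comparable across
samples. Type-level abundance is the per-sample sum of detected cluster
scores per BGC type, compared between conditions with Wilcoxon + BH.

# Co-expression networks

Within one condition, pairwise Spearman correlations between the most
varied features define a network with an edge wherever |rho| ≥ 0.7.
Spearman (rank) correlation is invariant to monotone transforms of
either profile, appropriate for relative abundances. The 0.7 default is a
conventional "strong correlation" threshold — no principled universal
value exists, so it is configurable. Edges are weighted by |rho| for both
the random walk and modularity; the sign is retained as an edge
attribute.

Communities are found by Walktrap — agglomerative clustering on short
random-walk distances (walk length 4, the algorithm's conventional
default) — cutting the merge tree at maximum modularity. Isolated nodes
form singletons. All communities with fewer than 3 members are then
merged into one `"residual"` module, keeping small fragments from
cluttering the partition. Hubs are the nodes whose degree falls in the
top 5% (at least one node, ties included); a regular network where every
degree ties is returned whole and flagged degenerate.

More than four samples per condition are required — rank correlations on
four or fewer points are essentially uninformative — and up to eight
samples triggers a warning recommending more, as false-positive edges
drop sharply with sample size.

# The synthetic-data generator

`simulate_dataset()` produces complete, seeded input bundles so every
stage is testable without external databases. The model:

* baseline feature proportions from a symmetric Dirichlet
  (`baseline_alpha = 10`, a moderately uneven community);
* planted differential expression at 4-fold for 10 of 200 features by
  default, **five boosted in condition B and five boosted in condition
  A**. This symmetric planting keeps total transcriptional output
  exchangeable between conditions, so unplanted features are *exactly*
  null in relative-abundance space. One-sided planting would shift every
  unplanted feature through compositional closure and make "false
  positive" ill-defined;
* per-sample biological variation via a Dirichlet with precision
  `dirichlet_concentration = 800`, giving a per-feature coefficient of
  variation near 0.5 at mean abundance — the magnitude of inter-subject
  variation typical of gut metatranscriptomes. `Inf` disables
  overdispersion for pure-multinomial studies;
* 20,000 reads per sample, 30% of them ncRNA-derived, with 9 samples per
  condition — desk-scale sizes that keep the full test suite and the
  acceptance analyses within minutes on one CPU while leaving planted
  effects comfortably detectable;
* every read emits one sub-threshold m8 row against its true subject,
  plus above-threshold decoy rows (5% of reads) so that the e-value
  filters are exercised end to end; decoys can never win best-hit
  selection because their e-values are weaker by construction;
* gene-level structure (two genes per feature, fixed random expression
  weights), round-robin phylum assignment, overlapping block pathway
  definitions, block BGC definitions with two thirds of member genes
  biosynthetic, and a metagenomic taxa profile that is *stable across
  conditions* (so expression shifts are transcriptional, not
  compositional, unless a phylum shift is planted).

Optional planted signals multiply the expression of one phylum's genes or
one BGC type's genes in condition B.

What the generator does **not** emulate: sequence-level errors and
alignment ambiguity (hits are emitted directly, not re-aligned),
correlated feature blocks (features are independent given the Dirichlet
draw), strain-level variation, and uneven library sizes. Passing tests
therefore demonstrate correctness of the statistics and plumbing under a
clean generative model, not robustness to alignment artefacts.

A note on the taxonomic-contribution recovery study used in the tests:
when one phylum's expression is boosted, renormalisation dilutes every
other phylum by a factor that grows with the boosted phylum's mass share.
With two phyla the dilution of the unshifted phylum is as large as the
boost itself and attribution is ambiguous by construction; the recovery
study therefore uses eight phyla, where the planted boost dominates the
dilution roughly in proportion to the number of phyla.

# Numerical and determinism choices

* All writers sort rows ascending on the first column under C collation;
  no output ever depends on hash order or locale.
* All randomness flows through an internal `with_seed()` that saves and
  restores the caller's RNG state; library calls never disturb global
  random state, and identical seeds give byte-identical bundles and
  pipeline output trees.
* Wilcoxon p for two identical constant groups is defined as 1 (the null
  case) before the test is ever called.
* Degenerate guards: empty hit tables flag nothing; samples with no
  annotated reads become all-zero profile columns with a warning;
  all-zero taxa denominators yield missing values; an edgeless network
  has no hubs.

# Limitations

* Two conditions only; no paired designs, no covariates.
* No count-model differential testing (the inputs are relative
  abundances, and rank tests are the deliberate choice).
* Phylum is taken from the best-hit gene's source genome; no LCA-style
  taxonomic reconciliation, and no sub-phylum resolution.
* The enrichment test is the unpermuted two-sample-t form; heavy-tailed
  fold-change distributions can make its p-values approximate.
* MinPath-style inference above `exact_limit` candidates is greedy and
  may exceed the optimum (bounded by the harmonic-number factor
  classical for greedy set cover); the output labels the mode.
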