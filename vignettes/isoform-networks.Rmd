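---
title: "Predicting tissue-specific mRNA isoform functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tissue-specific mRNA isoform functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isonet)
```

## The problem

Most functional genomics resources describe genes, yet a gene with several
alternatively spliced mRNA isoforms can place different isoforms in
different processes and different tissues. `isonet` predicts a *functional
network over mRNA isoforms*: nodes are isoforms, and an edge carries the
probability that the two isoforms participate in the same biological
process or pathway. A leave-one-tissue-out ablation then splits the
predicted network into tissue-specific functional, tissue-specific
non-functional and organism-wide reference pairs.

## The model

### Pair features

Every unordered isoform pair is described by Fisher z-transformed Pearson
correlations:

* **Expression features.** Expression (FPKM) is transformed as
  `log2(FPKM + 1)`. For each tissue, the Pearson correlation of the two
  isoforms' log expression across that tissue's samples gives one feature;
  one more uses all samples together. With the 17 tissues of a typical
  mouse RNA-Seq compendium that is 18 features; generally `n_tissues + 1`.
* **Sequence features.** Nine per-isoform descriptor groups -- mRNA k-mer
  composition for k = 3..6, protein 1-mer and 2-mer composition,
  conjoint-triad descriptors (3-mers over the canonical 7-class
  dipole/side-chain-volume reduction of the amino-acid alphabet,
  7^3 = 343 values), Chou-type pseudo-amino-acid composition
  (20 + lambda values) and Moran autocorrelation (per property scale and
  lag). Each group contributes the correlation between the two isoforms'
  descriptor vectors, giving 9 features. With 17 tissues the row has
  27 features in total.

Each correlation rho is passed through the transform used throughout this
package,

\[ z = \tfrac{1}{2} \log_2 \frac{1-\rho}{1+\rho}, \]

with rho = +1 and -1 replaced by the extreme values -100 and +100 and an
undefined rho (a constant vector) mapped to 0. Note the base-2 logarithm
and the sign inversion relative to the classical Fisher transform: this
orientation is deliberate and is locked in by the extreme-value
replacement rule (larger correlation, more negative z). `fisher_z()`
exposes a `classical` flag for the textbook variant, but every default
path uses the form above, and tissue-specific edge weights inherit its
convention (*lower* weight = *stronger* predicted functional relation).
Values beyond the replacement rule are clipped to [-100, 100]; the clip
only affects |rho| above roughly 0.9999995 and keeps the feature space
bounded.

### Labels

Public annotation databases describe genes, not isoforms, so the gold
standard is built from the cases where the mapping is unambiguous:

* **Positives.** If two *single-isoform* genes are co-annotated to the
  same retained ontology term or pathway, or interact in a retained PPI,
  their (unique) isoform pair is functional. Multi-isoform genes never
  generate positives, which avoids guessing which isoform carries the
  gene's function.
* **Negatives.** An explicit NOT annotation states that a gene is *not*
  involved in a term. After propagation, every isoform of a NOT-annotated
  gene is paired as non-functional with every isoform of each positively
  annotated gene of the same term -- here multi-isoform genes do
  participate on both sides.
* Positive annotations propagate *up* the ontology (the true path rule);
  NOT annotations propagate *down* to all descendants. Ontology
  annotations with evidence codes IEA, NAS or ND are removed before
  propagation. After propagation, terms annotated to fewer than 10 or
  more than 1000 genes are discarded as too specific or too broad. PPI
  records pass source-specific quality filters (APID: at least 2
  experimental evidences; IID: not orthology-only; Mentha: score >= 0.2;
  all sources: both interactors from the target organism).
* A pair found both positive (for one term) and negative (for another)
  is kept positive: the two genes do share at least one process. All
  remaining pairs are *unknown* -- prediction runs over all pairs, not
  only labeled ones.

Design choices where the construction was genuinely open: the term-size
filter is applied once, after propagation, to the same retained term set
used for both positives and negatives, so a term means the same thing on
both sides of the gold standard; term size counts positively annotated
genes (a NOT record is evidence of absence, not an annotation to the
term); pathway memberships are used flat, with no propagation, evidence
or size filtering; and PPI-derived positives bypass the term filter
entirely, since an interaction is evidence of shared function on its own.

### Classifier and ablation

A 100-tree probability random forest (via `ranger`, single-threaded,
seeded) is trained on balanced positive/negative samples; 100 trees is
where the tree-count sweep plateaus. Tissue specificity comes from
retraining the same forest once per tissue with that tissue's expression
feature column removed (the organism-wide feature always stays, and all
models share the training pairs and seed so that prediction flips reflect
feature removal, not sampling noise). For tissue t:

* full-model probability >= 0.6 **and** ablated probability <= 0.4:
  *tissue-specific functional* in t;
* full <= 0.4 and ablated >= 0.6: *tissue-specific non-functional* in t;
* same predicted label under every ablation: *reference*;
* a label flip that misses the confidence bands: *low confidence*,
  excluded from the networks.

A pair may in principle flip under more than one ablation; it is emitted
to each qualifying tissue and flagged `multi_tissue` rather than
discarded, since the flip logic defines no tie-break. The reference set
requires only label stability, not the 0.6/0.4 bands.

Gene-level networks collapse all isoforms of a gene into one node,
dropping intra-gene edges as self-loops and de-duplicating parallel edges
while keeping the minimum contributing weight and a multiplicity count.
Graph statistics (density `2E/(N(N-1))`, components, largest component),
central nodes (intersection of the top 10% by betweenness and by degree,
computed on the largest connected component, ties broken by node id) and
one-sided hypergeometric enrichment with Benjamini-Hochberg control
complete the analysis layer. Betweenness is computed unweighted: the edge
weights are confidences, not distances.

## The synthetic generator

`simulate_study()` generates the full input suite so that every stage of
the pipeline runs and is testable at desk scale:

* a catalog of `n_genes` genes (default 200, 70% single-isoform, up to 3
  isoforms otherwise) with mRNA and protein sequences. Protein sequences
  are generated independently of the mRNA -- the pipeline treats them as
  separate feature sources, so translation consistency would add nothing.
* `planted_module_count` (default 6) co-functional modules of
  `module_size` (default 10) single-isoform genes. Module membership
  drives **both** co-annotation and co-expression, so features and labels
  are genuinely associated. Ten genes per module is the smallest size
  whose term survives the default [10, 1000] term-size filter.
* expression over `tissues` x `samples_per_tissue` (default 4 x 3): a
  gene baseline (log2 scale, mean 4), a gene-by-tissue effect (shared
  within configured `tissue_groups`, so for instance a brain-like trio of
  tissues clusters in the tissue-similarity matrix), and for module
  members a shared latent factor with weight `sqrt(rho)` plus noise with
  SD `noise_sd * sqrt(1 - rho)` (defaults rho = 0.9, noise 0.5). With
  `noise_sd = 0` within-module within-tissue correlations are exactly 1;
  with `noise_sd = 1` they equal rho. FPKM is `max(2^x - 1, 0)`, so the
  log transform exactly inverts the generator on positive values.
* an ontology *forest*: one rooted chain of depth `dag_depth` per module
  plus randomly attached background terms (some with two parents). A
  single shared root is deliberately avoided: at a 200-gene scale an
  upper-level term can never exceed the 1000-gene cap, so propagation
  into a shared root would co-annotate all modules and flood the gold
  standard with cross-module positive pairs that carry no co-expression
  signal. Real ontologies escape this only because their roots are far
  larger than the cap; a multi-root forest reproduces the post-filter
  geometry at desk scale.
* annotations with experimental evidence codes for module genes (plus
  two multi-isoform "extra" genes per term, which matter only for
  negatives), scattered IEA/NAS/ND records that the evidence filter must
  remove, exactly `not_annotation_count` NOT records planted on
  *internal* chain terms so inverse propagation is exercised, pathway
  tables mirroring the first two modules, and PPI tables containing one
  deliberately rejectable record per quality filter.
* `tissue_specific_modules = TRUE` confines each module's latent factor
  to its home tissue (round-robin over the tissue list), and
  `module_sequence_similarity = FALSE` removes the shared sequence
  ancestry; together they build the ablation fixture in which a planted
  pair's signal lives in exactly one tissue feature.

What the generator does *not* emulate: read-level noise and coverage
bias, realistic gene structure or isoform-specific exon usage,
heavy-tailed expression distributions, incomplete or biased annotation
databases, and sex/age covariates. Passing tests therefore show that the
pipeline recovers the statistical structure it assumes -- not that real
annotation databases satisfy those assumptions.

## Numerical and scale choices

* Amino-acid property scales: pseudo-amino-acid composition uses the
  canonical triple (Kyte-Doolittle hydrophobicity, Hopp-Woods
  hydrophilicity, side-chain mass); Moran autocorrelation uses eight
  standard physicochemical scales, standardized over the 20 residues.
  Moran values are invariant to affine rescaling of a property, so the
  standardization is a convention, not a modeling decision.
* Pseudo-AAC defaults lambda = 25, weight = 0.05. Lambda must stay below
  the shortest retained protein (30 residues); 25 leaves the usual
  headroom. Moran uses lags 1..30, with lags exceeding the sequence
  length contributing 0 so 30-residue proteins remain featurizable.
* Correlations within 1e-12 of +/-1 are treated as exact and replaced by
  -/+100; a degenerate (constant) vector yields z = 0.
* The generic classification threshold is 0.5 (the forest-majority
  default); the 0.6/0.4 bands apply only to tissue-specific calls.
* Forest hyperparameters other than tree count stay at `ranger` defaults,
  seeded, one thread.
* Top-decile size for central nodes is `floor(0.1 * n)` with a minimum
  of 1.
* Problem sizes in the test-suite and acceptance fixtures: 200 genes
  (about 290 isoforms after multi-isoform expansion), 4 tissues, 6
  modules, balanced splits of 150 training and 50 test pairs per class,
  20-25 shuffle repetitions, and a scored pair universe of about 4,600
  pairs for the ablation study. The ablation fixture uses 8 samples per
  tissue: with only 3 samples, the per-tissue Pearson correlation of two
  unrelated isoforms is regularly extreme by chance and chance
  correlations would dominate the tissue-specific calls.

## Known limitations

* The gold standard inherits every bias of gene-level databases; the
  single-isoform restriction avoids false positives but under-represents
  multi-isoform genes among positives (they appear only via negatives).
* At genome scale the pair universe (about 2.9 billion pairs for 75,826
  isoforms) must be streamed; `pair_feature_matrix()` computes in
  bounded-memory chunks, but scoring all pairs is outside the scope of
  the test suite.
* The organism-wide feature is not recomputed when a tissue is ablated;
  only the tissue's own feature column is removed, mirroring the ablation
  definition.
* Tissue similarity uses median log-expression profiles; medians are
  computed on the log scale for consistency with every other expression
  computation.
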