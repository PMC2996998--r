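---
title: "Multi-locus eQTL mapping and knowledge-driven benchmarking with eqtlbench"
author: "eqtlbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus eQTL mapping and knowledge-driven benchmarking with eqtlbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlbench)
```

## The problem

Expression quantitative trait locus (eQTL) studies relate binary marker
genotypes of a recombinant inbred (RI) panel — each strain homozygous, coded
1 = BB and 0 = DD — to thousands of quantitative expression traits. Classical
single-marker approaches test one locus at a time and score it by the
significance of its marginal association; gene expression, however, is a
complex trait, often controlled by several loci and by epistatic
interactions, and markers are embedded in strong linkage disequilibrium
(LD). `eqtlbench` implements a family of mapping methods that treat eQTL
mapping as multivariate variable selection, and a battery of benchmarks that
score each method not against simulations alone but against the kind of
independent biological knowledge (gene location, pathway membership,
loss-of-function experiments) that is systematically available for
expression traits.

All methods produce the same currency: a *score profile*, one importance
value per marker for one trait. Benchmarks operate exclusively on the fixed
size top set of each profile, the `k = ceiling(0.01 p)` highest-scoring
markers ("the 99th-percentile set"), with deterministic genome-order
tie-breaking so that sparse profiles with tied (even zero) scores still
yield well-defined sets.

## Mapping methods

**Single-marker regression (HK).** At marker locations, Haley-Knott
regression reduces to the per-marker linear model \(y = \mu + \beta x_m\),
scored by \(\mathrm{LOD}_m = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)\).
`RSS1` is floored at \(10^{-10}\,\mathrm{RSS}_0\), capping the LOD of a
perfect fit at \(5n\); the floor is recorded in the profile metadata.

**Composite interval mapping (CIM), simplified.** Background cofactor
markers are chosen by greedy forward selection on residual sum of squares
(default 3), and each marker is tested against the cofactor background,
excluding cofactors within 10 Mb on the same chromosome and the tested
marker itself. This is a deliberately simplified marker-based
re-implementation: the classical EM interval-mapping machinery adds nothing
at marker positions, which is where all profiles are evaluated, and the
synthetic panels carry physical (bp) rather than genetic (cM) coordinates,
hence a bp exclusion window.

**Lasso and elastic net.** The naive elastic-net problem
\(\min \|y-X\beta\|^2 + \lambda_2\|\beta\|^2 + \lambda_1\|\beta\|_1\) is
solved along an L1 path (glmnet's coordinate descent; the fixed ridge
penalty is imposed through the augmented-data construction
\(X^* = [X; \sqrt{\lambda_2} I]\)). Profiles are \(|\beta|\) at the L1-norm
fraction \(s = \|\beta\|_1 / \max\|\beta\|_1\) selected from the grid
\(\{0.5, 0.55, \ldots, 1\}\) by seeded 10-fold cross-validation; the lower
bound of 0.5 prevents models too sparse to score multiple loci.
\(\lambda_2 = 0\) is the lasso, \(\lambda_2 = 1\) the elastic net.
Predictors are standardized internally and coefficients reported on the
standardized scale. When the (augmented) design has full column rank the
path is anchored at the exact least-squares solution, so \(s = 1\) is the
unpenalized limit.

**Random Forest importances.** Forests of regression trees are grown on
bootstrap samples (default 5,000 trees, `mtry = floor(p/3)`, `nodesize`
5 — a node is split only while its sample count exceeds `nodesize`), using
the reference `randomForest` implementation. Three importance measures are
extracted per marker:

* **RFPI** — unscaled permutation importance: mean over trees of the
  out-of-bag MSE increase when the marker's out-of-bag values are permuted;
* **RFRSS** — summed RSS decrease over all splits on the marker, per tree;
* **RFSF** — selection frequency: the number of internal-node splits using
  the marker, per tree.

### Selection-frequency bias and its correction

Under the null hypothesis of no trait-genotype association, selection
frequency is not flat across markers: when predictors are correlated, trees
preferentially split on markers with *low* correlation to others, so
markers inside LD blocks are systematically under-selected. The correction
estimates this bias directly on the study genotypes: 500 forests of 10
trees each (5,000 trees, the same ensemble size as a study forest) are fit
to independent standard-Gaussian traits; pooled per-marker selection
frequencies give `null_freq`, and each marker's deviation from the mean,
`correction = null_freq - mean(null_freq)`, is subtracted from the observed
selection frequency. Corrected scores may be negative; only ranks matter
downstream.

Two normalization choices are deliberate and recorded in provenance: split
counts are divided by the number of trees (so a marker may exceed 1 when it
is used several times per tree), which makes the 5,000-tree study forest
and the pooled 5,000-tree null commensurate — the subtraction requires a
common scale — and the null forests reuse the study `mtry`/`nodesize`, so
the bias is estimated under the same splitting regime it corrects.

## Simulated trait models

Traits are built on a baseline of 9 plus genetic effects: the single-locus
model adds one marker with coefficient 1; the two-locus epistatic model adds
two markers at 0.25 each plus their logical AND (1 = TRUE) with coefficient
1; the three-locus additive and epistatic models extend the same recipe
(0.25 per marker, three-way AND at 1); an eight-locus model (two strong
loci at 1.0, six weak at 0.25, additive) probes depth-dependent behaviour.
The three- and eight-locus coefficients are the package's own calibration
of the "constructed in a similar fashion" recipe and are configurable;
published weak-locus recovery percentages are therefore treated as
directional only. Gaussian noise is added with standard deviation equal to
2.5–20% (8 levels) of the *noiseless* trait mean — the scale must be fixed
before noise exists. Causal loci are redrawn each replicate, uniformly,
with a 10-marker minimum spacing to avoid unidentifiable overlapping
models (a documented guess; the spacing is recorded in outputs). Per model,
method and noise level, the *worst* (maximum) rank among the causal markers
is recorded; the median over replicates (50 by default) summarizes the
cell, and a cell succeeds when that median fits inside the top-percentile
set.

## Synthetic panels and fixtures

`simulate_ri_genotypes()` draws each strain chromosome as a two-state
Markov chain: first marker Bernoulli(0.5), switch probability
\(\min(1 - e^{-c\,d}, 0.5)\) between markers at distance \(d\) — a
Haldane-style map whose doubled recombination fraction mimics RI map
expansion, capped at free recombination. This reproduces the two features
the methods care about: balanced alleles (about 50/50 everywhere) and LD
decaying with physical distance. It does *not* emulate real-data features
such as segregation distortion, genotyping error, heterozygous residual
regions, or non-uniform marker density, so passing benchmarks demonstrate
correct method behaviour under idealized RI structure, not performance on
any particular organism.

`generate_fixture()` builds a complete input bundle around such a panel:
genes placed uniformly (each within the 5 Mb gene-to-marker window by
construction), cis traits driven by their own gene's nearest marker, trans
traits by planted regulator genes (optionally with AND epistasis between
two regulator loci), pathways constructed so each regulator shares at least
one pathway with its targets, a TF-to-target map of the planted links, and
a mutant table in which deleting a regulator changes its planted targets by
|log2 ratio| = 3 against a N(0, 0.1) background over all other genes — the
shape of a systematic loss-of-function compendium.

## Benchmarks

**cis proportion.** A trait scores a recovered cis-eQTL when any
top-percentile marker lies within a window (500 kb mouse-scale, 50 kb
yeast-scale; strict inequality beyond the bound) of its gene midpoint on
the same chromosome.

**Pathway enrichment.** Pathway genes map to their nearest marker (genes
farther than 5 Mb from every marker are omitted; nearest-marker ties go to
the lower coordinate). For each trait the top-percentile set is tested by
the hypergeometric upper tail for enrichment of markers mapped to by genes
sharing a pathway with the target; with several pathways the minimum P is
kept. The population is all markers in the map — the selected set is drawn
from the full map — and the trait's own gene is excluded from the pathway
marker set by default so cis hits cannot masquerade as pathway hits (an
`include_self` flag restores the alternative). The TF-centric variant tests
instead the union of pathways containing any known transcription factor of
the target.

Min-over-pathways P values deviate from uniform even for random scores, so
observed P values are corrected against an empirical null: per trait (same
pathway context — the per-trait context, not a global pool, so the
correction absorbs exactly the min-rule selection bias), standard-Gaussian
score profiles are drawn, the identical test is run, and observed values
become add-one-smoothed ranks \((1 + \#\{null \le raw\})/(1 + M)\) in the
pooled null. The corrected distribution is summarized by the one-sided
Kolmogorov-Smirnov statistic against uniform, \(D = \sup_x(\hat F(x) - x)\),
with the asymptotic one-sided \(P = e^{-2nD^2}\); exact small-sample KS
P values are unnecessary because only D and orderings drive the
comparisons. The default of one null replicate per trait matches "an
equivalent number" of null traits; it is configurable upward for smoother
nulls on small panels.

**Mutant enrichment.** Each experimentally repressed regulator maps to its
nearest marker (5 Mb rule). Per trait, top-percentile markers that are
mapped markers of repressed regulators contribute the maximum |log2
expression ratio| of those regulators on the trait's gene; values aggregate
over traits. The null randomizes the association between scores and markers
(per-trait score permutation) and the one-sided two-sample KS statistic
\(D = \sup_x(F_{null} - F_{obs})\) asks whether observed values are
stochastically larger.

**Method overlap.** Per trait and method pair,
\(100\,|A \cap B| / ((|A|+|B|)/2)\), averaged over traits. With fixed-size
top sets this mean-size-normalized overlap is monotonically related to the
Jaccard index; the formula is declared in output metadata since published
overlap figures do not state theirs.

**Depth and subsampling harnesses.** `tree_depth_study()` refits forests
over a `nodesize` ladder (5, 15, 29, 57, up to n; `nodesize = n` stops
after the root split), re-bias-corrects RFSF with a matching-nodesize null,
and reports cis and pathway-D improvements against the stump baseline.
`subsample_study()` evaluates nested, seeded strain subsets of decreasing
size.

## Numerical and design choices

* Coordinates are 1-based inclusive internally; BED input is converted at
  ingest. All distance cutoffs are physical (bp).
* Missing or heterozygous genotype calls are imputed at load with the
  per-marker mode, ties toward 1: the matrix must stay binary for tree
  splits and selection-frequency counting, and the handling of residual
  heterozygosity in RI panels is otherwise undocumented; imputation counts
  are surfaced in the load report.
* Trait/gene joins are exact string matches; alias resolution is data
  curation, not method.
* The top-percentile set is a fixed-size top-k, not a quantile threshold,
  so all-tied sparse profiles still yield sets (flagged `all_tied`).
* Cross-validation folds are assigned round-robin after a seeded shuffle;
  one master seed derives all stage- and trait-level seeds by stable
  hashing, so adding a trait never reshuffles the results of others.
* Collinear CIM cofactors are dropped (selection stops early with a
  warning) rather than fitted through a rank-deficient design.
* Constant traits map to all-zero profiles with a warning rather than an
  error: they occur in permutation-based workflows.

## Study scales

Development and validation run at desk scale, with miniatures designed to
preserve the *geometry* of a full RI eQTL study, not just its headline
counts. Three proportions matter and are kept:

* **Top set vs LD block.** The simulation panel is 90 strains and 500
  markers over a 2 Gb, 5-chromosome genome — a mouse-panel genome at
  reduced marker density — so the top-1% set (k = 5) is comparable to the
  span of one LD block (~9 markers at the resulting 4 Mb spacing). A denser
  map at the same k would make the top set smaller than a single peak
  block, a geometry the full-scale study never has, and would punish
  coefficient-spreading methods for an artefact of the miniature.
* **Top set vs causal loci.** The eight-locus depth probe runs on a
  90 x 2000 panel at full marker density (1 Mb spacing), where k = 20
  leaves room for the 8 causal loci, mirroring the full-scale k = 38.
* **Bias contrast.** The flattening check uses a 120-strain, 600-marker
  panel of alternating tight (10 Mb) and loose (100 Mb) chromosomes:
  selection-frequency bias is driven by *differences* in inter-marker
  correlation, so a panel with genuine LD-block contrast is the object the
  correction exists for; a uniform panel has little bias to remove.
* **Depth-sensitive fixture.** The tree-depth study needs traits where
  depth can matter at all: monogenic traits cannot produce it, and a
  strong *annotated* locus saturates its benchmark already at the root
  split (min-over-pathways lets the strongest annotated locus dominate).
  Its fixture therefore gives every trait a strong unannotated trans
  hotspot (`trans_decoy_effect = 1`) with a weak cis effect and two weak
  pathway-annotated regulators underneath (coefficients 0.4, 5% noise, 50
  traits): the benchmark-visible loci are exactly the conditional effects
  that only deep trees reach. The enrichment empirical null in this study
  is seeded per nodesize, not per importance measure, so between-measure
  comparisons are paired and null Monte-Carlo noise cancels.

Forests are 400–500 trees with 20–25 replicates in these studies; 500
random-score traits calibrate the enrichment correction. The full-scale
defaults (5,000 trees, 50 replicates, 500 x 10-tree nulls) remain the
package defaults; reduced scales shrink only compute knobs (trees,
replicates, null forests), never model definitions.

```{r, eval = FALSE}
# a complete miniature study
fx <- generate_fixture(fixture_spec(seed = 1))
dir <- tempfile(); write_fixture(fx, dir)
cfg <- run_config(
  genotype_path = file.path(dir, "genotypes.tsv"),
  expression_path = file.path(dir, "expression.tsv"),
  genes_bed = file.path(dir, "genes.bed"),
  pathways_gmt = file.path(dir, "pathways.gmt"),
  mutant_path = file.path(dir, "mutant.tsv"),
  methods = c("HK", "RFSF"),
  rf = list(n_trees = 500, nodesize = 5, null_forests = 300,
            null_trees = 10),
  mutant_null = 10, seed = 1, out_dir = file.path(dir, "out"))
res <- run_pipeline(cfg)
res$summary
```

## Known limitations

* Sparse partial least squares, a comparator in the original study design,
  is not implemented; external score TSVs can enter the battery through
  `read_score_profile()` with method `EXTERNAL`.
* No interval (pseudo-marker) mapping between markers, and no
  permutation-based significance thresholds: benchmarks compare whole
  score distributions, not per-trait significance calls.
* The asymptotic one-sided KS P values are anti-conservative at very small
  n; summaries with fewer than 5 evaluable traits return NA.
* Mode imputation of heterozygous calls discards real heterozygosity; on
  panels with substantial residual heterozygosity a three-state coding
  would be preferable.
* The simulated panels carry no genotyping error or segregation
  distortion; benchmark levels on real data will differ even when method
  rankings transfer.
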