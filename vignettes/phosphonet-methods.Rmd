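---
title: "phosphonet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosphonet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind `phosphonet`, the
choices made where the method leaves room, and what the synthetic-data
tests do and do not establish. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. Data model

The unit of observation is a quantified phosphopeptide: an MS1 peak
intensity for one peptide sequence in one sample (a cell line, treatment or
organelle fraction). Intensities are non-negative and *compositional in
detection*: a peptide absent from a run carries no information about its
abundance there. The package therefore distinguishes `NA` (not observed)
from 0 everywhere, and every downstream statistic is computed on observed
values only.

**Protein-level summation.** Intensities are summed per protein per sample.
Two complications are handled at this stage:

- *Ambiguity.* A conserved peptide sequence can match several proteins
  (classically the SRC-family kinase activation loop). The exclusive rule
  assigns the peptide to the first candidate protein that is evidenced by a
  *different* peptide in the same sample, otherwise to the first listed
  name. The inclusive rule (used for site-level matrices) instead credits
  every candidate site. Both are provided; exclusive is the default at
  protein level, inclusive at site level.
- *Sign.* Peptides phosphorylated on annotated inhibitory sites contribute
  negatively, so a protein's total distinguishes activation from
  inhibition. For the SRC-family kinases (`SRC`, `FYN`, `LYN`, `YES1`,
  `FRK`), whose C-terminal inhibitory site is a major regulatory switch,
  inhibitory signal is not folded into the protein total but tracked as a
  separate non-positive entity `GENE_i`. The tracked list is an argument,
  so any gene set can opt into `_i` tracking. For non-tracked proteins we
  sum signed contributions within the sample; the alternative (flipping the
  sign after summation) differs only when a protein carries both classes in
  one sample, and the signed sum is the convention that keeps summation
  associative.

Regulatory annotation is accepted as an input column; there is no live
database lookup, for determinism.

**Duplicate runs** of the same experiment are averaged cell-wise, ignoring
missing values (`(10, NA) -> 10`), so a value observed in one run is not
diluted by the other run's non-detection.

## 2. Dissimilarity representations

Samples are first scaled by their standard deviation over observed values
(`n - 1` denominator) *without centering* — centering would destroy the
meaning of zero and of sign, while scaling equalizes the leverage of
samples with different overall signal.

Three representations of the relation between two entity profiles are
computed, each aware of missingness:

- **Euclidean**: for a pair observed jointly in `p` of `P` samples,
  `d = sqrt((P/p) * sum_shared (x - y)^2)`. The `P/p` rescale treats the
  observed coordinates as a representative sample of all coordinates; it is
  the convention built into R's `dist()`, which the implementation uses
  (and which the acceptance suite checks against an independent
  double-loop oracle). A no-rescale variant is available.
- **Spearman**: `1 - |rho|` with ranks over pairwise-complete observations
  and average ranks for ties. The absolute value makes strongly
  anti-correlated profiles *similar*: an inhibitory site moving opposite
  to an activating site is signal, not noise. Constant profiles have
  undefined `rho`; such pairs get dissimilarity 1.
- **SED**: both matrices divided by their maxima and averaged, giving one
  hybrid representation sensitive to both magnitude and rank structure.

**Minimum overlap.** Pairs sharing fewer than `min_overlap` (default 3)
observed samples cannot support a pairwise statistic. They are imputed with
the maximum observed dissimilarity (Euclidean) or 1 (Spearman) rather than
left missing, because the embedding stage requires a complete matrix. Three
shared points is the smallest overlap where a rank correlation is even
defined beyond triviality; the choice is exposed as a parameter.

**Detection filter.** Before embedding, entities quantified in fewer than
`filter_min_frac` (default 0.6) of samples are excluded. Sparse entities
receive mostly fallback distances, which place them as an undifferentiated
shell around the embedding and — under single linkage — absorb the largest
MST edges that the cluster cut relies on. The evaluation stage deliberately
keeps the *unfiltered* entity universe, so random clusters are drawn from
everything the experiment identified, as in the original analysis.

## 3. Embedding and cluster extraction

t-SNE is run directly on the precomputed dissimilarity matrix (never
re-derived from raw data). No t-SNE implementation is available in this
R installation, so the package carries a standard exact implementation:
Gaussian input affinities with per-point bandwidth calibrated by binary
search to the target perplexity, symmetrized joint `P`, Student-t
low-dimensional kernel, gradient descent with early exaggeration (factor
12, 250 iterations), momentum switching (0.5 to 0.8) and delta-bar-delta
gains. At the few-hundred-entity scale of this pipeline the exact
`O(n^2)` iteration is fast and avoids approximation error.

Defaults: 3 embedding dimensions (clusters are read from the embedded
geometry, and a third dimension costs little while easing separation), 1000
iterations, learning rate `max(50, n/12)`, perplexity
`min(30, (n - 1) / 3)` — the conventional 30 capped so that the perplexity
constraint `perplexity < n` holds with margin on small inputs. The seed is
mandatory in pipeline runs; identical seeds reproduce identical
coordinates.

Clusters are extracted by the **minimum-spanning-tree single-linkage
rule**: build the Euclidean MST over the embedded points, delete the
`k - 1` heaviest edges (ties broken lexicographically by edge endpoints),
return the connected components. This is mathematically the same partition
as cutting a single-linkage dendrogram into `k` groups, which the test
suite verifies against `hclust` on 200 random instances. The number of
clusters is a choice the method does not make for you: at full dataset
scale the working convention is 75-80 clusters (the default cut is the
midpoint, 77); for other inputs the default is `ceiling(n / 20)`, and the
pipeline accepts `k` directly. An edge-length-threshold cut would also be
possible; the fixed-`k` cut is the default because it makes runs
comparable across dissimilarity kinds.

## 4. Networks

- **Co-cluster pairs**: entity pairs co-clustered in at least one
  (inclusive) or all (exclusive, the "hard" filter) of the chosen
  embeddings, with multiplicity 1-3 recording in how many embeddings the
  pair co-occurred.
- **CFN**: the merged PPI graph restricted to co-cluster pairs; isolated
  proteins are dropped. PPI sources are unioned with canonical
  (lexicographic) edge orientation; duplicate edges merge with summed
  weight (strength of evidence; max-combine available) and concatenated
  provenance.
- **CCCN**: co-clustered pairs whose Spearman correlation passes
  `|rho| >= 0.5`. The boundary is included (`>=`): the analysis tradition
  writes the threshold as "greater-or-equal", and an open threshold would
  differ only on a measure-zero set of real data. Positive edges carry
  `rho` as weight; negative edges carry `exp(20 * rho)`, a transform that
  maps `(-1, 0)` monotonically into `(0, 1)` so a spring-embedded layout
  pushes anti-correlated nodes apart. Edge thickness is
  `|rho| * multiplicity`. Node attributes record total signed
  phosphorylation (sum over samples, ignoring `NA`) and an
  activating/inhibitory class by its sign.
- **Network statistics**: average local clustering coefficient (isolates
  count 0), diameter and mean shortest path on the largest component, and
  a power-law fit by ordinary least squares of `log(count)` on
  `log(degree)` — reported for all degrees and for degrees above a cutoff
  (default 10), since the low-degree regime often dominates the fit. OLS on
  the log-log histogram is used deliberately (the convention that reports
  an alpha with an R^2), not a maximum-likelihood estimator.

## 5. Cluster evaluation

Each cluster is scored on:

- `pct_na`: percent missing cells of its submatrix;
- `index = (1 - pct_na/100) * sum_i w_i rhobar_i / sum_i w_i`, where
  `rhobar_i` is member `i`'s mean pairwise-complete Spearman correlation
  with the other members and `w_i = sum |signal_i|`. The index rewards
  clusters that are dense in data and conformal in pattern, weighted
  toward the entities carrying signal. The exact formula is fixed here (the
  original description is verbal) and isolated in one function so an
  alternative can be swapped in. Singleton clusters have no pattern: index
  `NA`.
- PPI support: count and summed weight of interaction edges inside the
  cluster.
- GO enrichment: per term, a hypergeometric upper-tail p-value
  (`P[X >= observed]`) against the gene universe; terms kept at `p < 0.01`
  with at least two annotated cluster genes (single-gene terms cannot
  witness enrichment). Reported: enriched-term count, terms per gene, and
  mean observed/expected ratio. No multiple-testing correction is applied
  at this screening step, matching the original practice; a
  Benjamini-Hochberg option exists but defaults off. Annotations are taken
  as given (flat): no propagation to ancestor terms, since whether the
  original analysis propagated is unknown and propagation changes term
  frequencies wholesale. A cluster with annotated genes but no enriched
  term scores ratio 0 (no over-representation); `NA` is reserved for
  clusters with no annotated genes at all.

Real scores are compared with `n_random = 70` non-overlapping random
clusters whose sizes are drawn from the real partition's size distribution
and whose members are drawn without replacement from the full entity
universe. Differences are tested per metric with Welch's two-sample
two-sided t-test (unequal variances, Welch-Satterthwaite degrees of
freedom), implemented in closed form and cross-checked against
`stats::t.test` in the suite. Degenerate inputs (zero variance on both
sides) return `t = 0, p = 1` when the means agree and `p = 0` otherwise.

## 6. Quantitation

Fold changes use the symmetric signed convention `t/c` if `t >= c` else
`-(c/t)`, computed on magnitudes (inhibitory entities are negative by the
sign convention, and their changes are reported as magnitudes under the
`_i` label); `|fold| >= 1` always, equality gives `+1`, zeros yield `NA`
with a warning. The "more than twofold" report filter is strict:
`|fold| > 2` keeps a 2.0001-fold change and drops exactly 2.

Fraction enrichment is `mean(|x|)` over the fraction samples divided by
`mean(|x|)` over the background samples, observed values only, per entity —
samples first, then the ratio, so samples with more observations do not
dominate the background. The arithmetic mean is the default (a median
option exists). The ratio is invariant to global rescaling.

Heat-map export orders rows/columns by descending total absolute signal
("most to least") or by average-linkage hierarchical clustering on the same
NA-aware Euclidean distance used elsewhere; the render spec records the
blue-yellow diverging palette with black for missing cells.

## 7. The synthetic world

`simulate_phospho()` emits exactly the tables the pipeline consumes, plus
ground truth. Its defaults are a statement about what realistic input looks
like, fixed once:

- **400 proteins, 16 samples.** The samples stand for cell lines,
  treatments and fractions treated as states of one system.
- **10 planted co-phosphorylation clusters of 5 proteins** (a 50-protein
  reproducibly quantified core), the rest a sporadically detected tail.
  Data-dependent acquisition produces exactly this shape: a modest core of
  consistently quantified phosphoproteins and a long tail of one-off
  identifications. The 5-member size also keeps the evaluation's 70
  non-overlapping size-matched random clusters drawable from 400 entities
  (70 x 5 = 350), which larger planted clusters would make arithmetically
  impossible.
- **Switch-like activation.** Each cluster is strongly activated
  (2.5 log-units, about 12-fold) in ~25% of samples; activation sets
  overlap by at most one sample between clusters. Signaling pathways are
  on/off across conditions, and this is what makes clusters separable by
  *magnitude* (Euclidean) as well as by *rank* (Spearman). An early purely
  Gaussian latent model matched the target rank correlation but produced
  clusters with no magnitude identity — formally correlated, practically
  inseparable in Euclidean space — which is not the stated world of
  well-separated planted modules.
- **Heteroscedastic noise.** Member profiles add Gaussian log-scale noise
  whose sd is shrunk 0.15x on activated cells: strong MS1 signals are
  measured with small relative error, weak ones with large error. The
  baseline noise sd is calibrated *empirically at generation time* (Monte
  Carlo bisection) so that within-cluster pairwise Spearman hits
  `within_cluster_rho` (default 0.9); the suite verifies the realized
  median across 100 replicate generations stays within [0.8, 0.95].
- **Missingness** is missing-completely-at-random per (protein, sample)
  cell: 20% for core proteins, 80% for the tail (observed in ~3 of 16
  samples — "sporadic"). An intensity-dependent left-censoring mode
  (`missing_mode = "censor"`) is provided, since real MS missingness is
  abundance-biased, but MCAR is the default for analytic transparency.
  The core/tail contrast is what gives data-driven clusters their lower
  percent-`NA` than random gene sets — in real data, too, the proteins
  that cluster are the well-observed ones.
- **Peptides**: 1-4 per protein with Dirichlet-distributed shares fixed
  across samples, 10% emitted as oxidized/non-oxidized pairs splitting one
  signal 70/30, 5% carrying a conserved sequence shared with a second
  protein (the truth table records the true source), 10% of proteins with
  an inhibitory site of proportional share, emitted with
  `regulatory = "inhibitory"`.
- **PPI**: Bernoulli edges, probability 0.3 within planted clusters and
  0.01 elsewhere; weights uniform on [0.2, 1]; two nominal sources.
- **GO**: 3 planted terms per cluster covering ~80% of members with a
  small leak outside, plus a 60-term background pool with 2 random terms
  per gene, so random clusters enrich occasionally (a realistic non-zero
  background) and planted clusters enrich strongly.

Synthetic gene names (`P001`...) never collide with the SRC-family list, so
default simulations contain no `_i` entities; `_i` handling is exercised by
constructed fixtures in the unit tests. This keeps the clustering-recovery
property independent of the ingest module's outlier-generating features.

**What a green test establishes — and does not.** The synthetic world has
planted, well-separated, equally sized modules, MCAR missingness and flat
GO annotation. Green recovery tests show the pipeline's machinery is
correct and its statistics behave as designed under those assumptions. They
do not show that real phosphoproteomic data contain such modules, nor
calibrate how the method degrades under correlated missingness, batch
structure, isoform ambiguity beyond two-way sharing, or annotation bias —
on real data the evaluation-versus-random comparison, not the recovery ARI,
is the operative check.

## 8. Numerical conventions and edge cases

- Zero-variance sample columns abort normalization with the sample named;
  degenerate pairs (insufficient overlap, constant profiles) take the
  maximal dissimilarity rather than propagating `NA`.
- MST cut ties are broken by lexicographic endpoint order; partitions are
  therefore deterministic given coordinates.
- `random_clusters` refuses requests whose sampled sizes exceed the entity
  count (rather than silently truncating).
- All randomness (simulation, t-SNE initialization, random clusters) is
  seeded; per-stage seeds are small fixed offsets of the run seed.
- Provenance is centralized in `run_info.json` (tool version, seed, config
  hash, artifact list) instead of comment headers inside every TSV/GraphML
  file, which would break standard parsers of those formats.
- Pipeline configs are flat `key: value` text (Debian-control style) read
  with `read.dcf`; no YAML parser is required.

## 9. Known limitations

- The exact t-SNE is `O(n^2)` per iteration; beyond a few thousand
  entities a Barnes-Hut implementation would be needed.
- Residue numbering is taken verbatim from the input; no isoform
  re-mapping.
- GO annotations are flat; no ontology graph, no ancestor propagation.
- The power-law fit is a descriptive OLS regression, not a rigorous
  heavy-tail estimator.
- Fold changes are reported per experiment without statistical testing
  (representative-experiment convention).
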