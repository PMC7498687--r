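---
title: "Methods: linking biosynthetic domain diversity to taxonomy"
author: "obulink"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: linking biosynthetic domain diversity to taxonomy}
  %\VignetteEncoding{UTF-8}
---

## The problem

Secondary-metabolite potential in environmental microbiomes is commonly
surveyed with degenerate-primer amplicons of two conserved biosynthetic
domains: the ketosynthase (KS) domain of polyketide synthases and the
adenylation (AD) domain of nonribosomal peptide synthetases. Clustered at
95% identity, these amplicons form *operational biosynthetic units*
(OBUs), the functional analogue of an OTU. Because a biosynthetic gene
cluster sits on the same chromosome as the 16S rRNA gene, an OBU's read
counts should co-occur linearly with the 16S counts of its producer across
samples — which makes it possible to attribute anonymous biosynthetic
diversity to taxa by regression, without any reference database.

`obulink` implements that analysis end to end: domain-amplicon clustering
into OBUs, formula-level diversity statistics, the no-intercept linear
screen attributing OBUs to taxa, cultured-fraction recovery accounting,
and a synthetic community generator with planted ground truth that lets
every stage be validated against known answers.

## OBU clustering

Read pairs are trimmed to fixed lengths (defaults 240 bp forward, 175 bp
reverse, truncating from the 3' end; shorter pairs are discarded and
counted, because the downstream join assumes fixed lengths). Each pair is
joined as `forward + "N" + reverse_complement(reverse)` — a single-N
spacer, giving 416 bp joined reads at the defaults. Clustering is greedy
centroid clustering in two rounds: within each sample at 97% identity,
then the round-1 centroids — weighted by their member read counts — are
pooled and clustered at 95%. Clusters whose total pooled membership is a
single read are discarded. The final 95% clusters are the OBUs; the
feature table counts each sample's reads per OBU.

Determinism: candidates are processed in a total order (abundance weight
descending, ties by sequence and then id), and each candidate joins the
*first* centroid at or above the threshold, so the clustering is invariant
to input order.

**Identity metric.** Identity is computed from a global Needleman–Wunsch
alignment (match +1, mismatch −1, gap −2) as matches over alignment
columns, where any column containing `N` is excluded from both numerator
and denominator — the spacer must not penalise otherwise identical
sequences. Terminal gaps are penalised like internal ones, deliberately:
if end gaps are free *and* end-gap columns are excluded from the
denominator, a short perfect dovetail overlap between two unrelated
sequences scores identity 1.0, and in testing this collapsed planted
clusters into one. Because all joined reads share one fixed length,
penalised end gaps cost nothing on genuine comparisons. The alignment
kernel is implemented in C++ (Rcpp); an optional shared 8-mer prefilter
can skip alignments that provably cannot reach the threshold and is
required by the test suite to leave results bit-identical.

"Singleton" is interpreted as *one member read in total* (not one round-1
centroid); the `min_cluster_reads` argument makes this configurable.
Chimera checking is a pass-through hook (`chimera_hook`), since de novo
chimera detection is typically delegated to external tools. Round-1
member counts are carried into round 2 as abundance weights, so the most
abundant variants found clusters first.

## Diversity statistics

All statistics are implemented at the formula level and are cross-checked
against independent implementations (vegan, `stats::lm`, `cmdscale`) in
the test suite:

* **Chao1** (bias-corrected default): \(S_{obs} + f_1(f_1-1)/(2(f_2+1))\),
  with the classic \(S_{obs} + f_1^2/(2 f_2)\) switchable; standard errors
  from the usual asymptotic variance formulas. The estimator requires raw
  integer counts and refuses normalized data. Whether published
  "Chao1 ± x" values are estimator SEs or SDs across replicates is often
  ambiguous; both are computable here (`chao1_se`, or `sd()` across
  `chao1_table()` rows) and neither is asserted as the convention.
* **Rarefaction**: closed-form
  \(E[S_n] = \sum_i [1 - \binom{N-N_i}{n}/\binom{N}{n}]\) via log-gamma
  arithmetic.
* **Normalization to 100,000 reads**: interpreted as total-sum scaling
  (each column scaled to sum exactly to the target, fractional values
  allowed). Published pipelines are often ambiguous between scaling and
  rarefying; a seeded hypergeometric `rarefy` mode is provided for
  sensitivity analysis.
* **Bray–Curtis**: \(1 - 2\sum_i \min(x_i,y_i)/(\sum x + \sum y)\).
* **PCoA**: Gower double-centering of \(-d^2/2\), symmetric
  eigendecomposition; negative eigenvalues are reported, never corrected;
  eigenvector signs are fixed (largest-magnitude coordinate positive) for
  cross-platform reproducibility.
* **Biplot loadings**: the loading of feature *f* on axis *k* is the
  Pearson correlation of *f*'s abundance with the axis-*k* coordinates,
  scaled by \(sd(\text{axis}_k)/sd(\text{axis}_1)\) so lower-variance axes
  carry proportionally smaller loadings; features whose maximum absolute
  loading exceeds 0.1 are flagged. This is an *unconstrained* stand-in for
  canonical (constrained) ordination loadings and is not claimed to
  reproduce them.
* **PERMANOVA** (one-way, Anderson's partitioning):
  \(SS_T = \sum_{i<j} d_{ij}^2/N\), \(SS_W = \sum_g \sum_{i<j\in g}
  d_{ij}^2/n_g\), \(F = ((SS_T-SS_W)/(a-1))/(SS_W/(N-a))\), with
  \(p = (1+\#\{F_\pi \ge F\})/(1+n_\pi)\) under free label permutation (no
  strata), seeded. Note that sampled permutations occasionally reproduce
  the observed partition, so the attainable minimum p is slightly above
  \(1/(1+n_\pi)\) for small groups, and the test is mildly conservative
  there.
* **ANOVA + Tukey**: `stats::aov`/`TukeyHSD`; the compact letter display
  is a small insert-and-absorb algorithm over the significant pairs, and
  letters collapse to a single group when the overall ANOVA is not
  significant at the chosen level.

## The function-to-taxon screen

For an OBU *i* and species *j* the model is a no-intercept regression

\[ OBU_i = \alpha_{i,j} \, species_j + \varepsilon \]

fitted by the closed forms \(\hat\alpha = \sum xy / \sum x^2\),
\(SE = \sqrt{s^2/\sum x^2}\) with \(s^2 = \sum(y-\hat\alpha x)^2/(n-1)\),
a two-sided t test on \(\hat\alpha\), and the no-intercept
\(r^2 = 1 - RSS/\sum y^2\). Both residual degree-of-freedom conventions
(\(n-1\), the `lm` convention for a one-parameter no-intercept fit; or
\(n\)) are switchable, since software differs.

The screening pipeline applies, in order:

1. **Cleaning**: features present in at most one sample *and* with fewer
   than 10 total reads are removed. The conjunction ("and") is the default
   reading; an `OR` mode is switchable and the removal report states which
   rule fired for each feature.
2. **Collinearity dedup**: species with pairwise \(r^2 = 1\) (within
   \(10^{-12}\)) are grouped by transitive closure; only the
   highest-total-count representative is kept (ties broken
   lexicographically — the rule itself only says "removed"). Zero-variance
   species are removed with reason `"constant"`. Note that with very few
   samples (e.g. 3), *exact* collinearity between unrelated integer count
   vectors is common, so links can legitimately attach to a
   representative rather than the true producer; truth-based evaluations
   in this package therefore score recovery at the OBU level.
3. **Screen**: every OBU × species pair is fitted (vectorized over the
   full cross) and records with \(p < 0.001\) are kept. No
   multiple-testing correction is applied — faithfully mirroring the
   fixed-cutoff screen — but the total number of tests is always reported
   so users can correct on their own.
4. **Genus summary**: per genus, the *union* of linked OBU ids across
   member species (an OBU linked to two congeneric species counts once),
   with mean relative abundance across samples; genera with zero links are
   kept. An OLS regression (with intercept) of linked-OBU count on genus
   abundance quantifies whether abundance predicts biosynthetic potential.

Regressions default to normalized (per-100,000) abundances so slopes are
comparable across samples of unequal depth; a raw-count mode
(`link_scale = "raw"` in `run_config()`) exists for equal-depth designs,
where normalizing each OBU column by its own sample totals would break
exact proportionality.

**A calibration caveat users should know.** The t test's null hypothesis
\(\alpha = 0\) implies mean-zero OBU counts. Against *positive-mean*
background counts the screen is therefore anticonservative: with many
mutually similar samples, a roughly constant OBU regressed on a roughly
constant species yields large t even under independence. In simulation,
with 20 tight replicate samples essentially every positive–positive pair
passes p < 0.001. The screen only discriminates when the residual degrees
of freedom are very small (three replicates give df = 2, where p < 0.001
needs |t| > 31.6, i.e. near-exact proportionality) or when compositional
variation across samples is large. This is a property of the method
itself, not of this implementation; the package's null-calibration tests
are run under the model's proper null (zero slope, mean-zero errors),
where simulated p-values are uniform and the pass rate matches the
threshold.

## Recovery accounting

Environmental (eDNA) and plate-derived (pDNA) OBU tables from a single
pooled clustering run (so ids are comparable — the comparison warns when
id namespaces look disjoint) are compared per pooled group: presence is a
count of at least 1 (configurable) in any sample of the group, recovery is
the percentage of eDNA OBUs also present in the pDNA — making it invariant
to sequencing depth — and pDNA-only OBUs are counted. Replicates are
pooled before comparison; per-replicate analysis is available by
subsetting. Culturability is CFU as a percentage of direct
(microscopy-stained) cell counts.

## The synthetic community generator

`generator_config()` defines the simulated world; defaults were chosen
once as a realistic desk-scale rendering of a coastal amplicon survey:

* Species relative abundances are log-normal (sdlog 1.5 — a typical
  steep rank-abundance curve), shared across replicate samples up to
  per-sample log-normal jitter (sdlog 0.3, emulating replicate-to-replicate
  compositional noise), then multinomially sampled to a fixed depth
  (default 100,000 reads, matching the normalization target).
* Each producer species carries `obus_per_producer` OBUs whose counts are
  negative-binomial around \(\alpha \cdot species\) (dispersion 0.1 by
  default — overdispersion is the norm for amplicon counts). Dispersion 0
  is the exact noise-free limit: OBU counts equal \(\alpha x\), fractional
  for non-integer \(\alpha\) (then flagged as normalized, since Chao1 and
  other integer-only consumers do not apply).
* Slopes are uniform on `alpha_range` (default 1–5). No slope
  distribution is known for real OBU–species pairs; this is an explicit
  placeholder, recorded in the truth object.
* A configurable fraction of producers (default half) is pinned below a
  relative-abundance ceiling (default 0.001, i.e. below 0.1%) — the
  "rare taxa, rich repertoire" scenario.
* Background OBUs are drawn independently of every species around a
  per-OBU integer baseline.
* In sequence mode, per-OBU centroids are random sequences verified to be
  below 90% pairwise identity; reads are the centroid's two ends mutated
  at a per-base rate (default 0.005, keeping within-OBU identity above
  98%), so true cluster memberships are known exactly.
* One RNG substream per logical component (community, OBU counts, reads),
  derived from the master seed, so stages can be regenerated
  independently.

What the generator does *not* emulate: quality-score error profiles,
chimeras, primer degeneracy, phylogenetic correlation between abundance
and biosynthetic repertoire, and compositional (sum-constrained)
covariance beyond the multinomial draw. Passing tests therefore show that
the pipeline's logic and statistics behave correctly under its stated
model — not that the model captures every feature of real surveys.

## Validation design and problem sizes

The test suite validates each statistic against an independent
implementation (vegan, `lm`, `cmdscale`, a pure-R alignment oracle, an
all-pairs clustering reference) at \(10^{-10}\) relative tolerance on
batches of 100 random instances; calibration checks use 25,000 null
regressions and 200 simulated PERMANOVA datasets (199 permutations each);
link recovery uses 20 planted links at 20 samples with NB dispersion 0.1
(where the per-link slope error SD is ~8–9%, so slopes are checked as
"at least 90% within 15%", with exactness asserted separately in the
noise-free limit); the abundance-vs-potential experiment uses 200 species
in 100 genera at the study's own design size of 3 replicates, in the
noise-free limit, where the df = 2 screen is selective by construction.
These sizes keep the whole suite under a minute per file while leaving
each check statistically meaningful.

`demo_synthetic()` runs the entire pipeline (clustering from reads,
diversity, linking, recovery) on a two-niche, three-replicate world in the
noise-free limit with integer slope 2 — so every table stays an integer
count table and every planted link is an exact fit, which is the only
regime in which a df = 2 screen at p < 0.001 retains all planted links.
Its outputs are byte-identical across reruns with the same seed.

## Known limitations

* The screen yields statistical associations, not causal attribution; an
  OBU may be linked to a co-varying neighbour rather than its true host,
  and with few samples the \(r^2 = 1\) dedup can reassign links between
  exactly collinear species.
* The fixed p < 0.001 cutoff is anticonservative against positive-mean
  background under large, homogeneous designs (see above).
* Identity is defined by one specific alignment scoring; other
  clustering tools (different scoring, heuristics, or chimera removal)
  will produce different OBU inventories.
* Ordination loadings are unconstrained correlations, not canonical
  loadings.
* NMDS, constrained ordination, BLAST-based annotation and 16S ASV
  inference are out of scope; taxonomy is an input.
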