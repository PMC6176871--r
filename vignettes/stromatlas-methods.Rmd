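---
title: "Models and methods behind stromatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stromatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stromatlas analyzes single-cell RNA-seq of intestinal mesenchyme along two
parallel tracks — a droplet (10x-style) track built around graph clustering,
and a microfluidic (C1-style) track built around co-expression networks and
NMF consensus clustering — plus cross-species label transfer, trajectory and
cell-cycle inference, and integration diagnostics. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the procedure left genuine freedom. It also describes what the
bundled simulations emulate and, as importantly, what they do not.

## The synthetic data generator

Every stage of the package is exercised on simulated data with known ground
truth, so the test suite runs at desk scale with no downloads.

`simulateDropletExperiment()` draws UMI counts gene-wise from a negative
binomial with variance $\mu + \phi\mu^2$; the dispersion default
$\phi = 0.3$ reflects typical droplet overdispersion. Cells belong to $K$
planted clusters with disjoint marker sets shifted up by a log2 fold change
(default 2, a strong but realistic marker effect). Per-barcode totals form a
two-mode mixture: real cells (log-normal totals around 5,000 UMIs) and
ambient barcodes (around 100 UMIs) drawn from a scaled-down library-wide
mean profile, making them transcriptionally uninformative, as ambient RNA
is. Thirteen mitochondrial genes (prefix `MT-`, configurable to `mt-`)
receive a per-cell beta-distributed share of the library with mean 2%, and
a 5% spike of control cells expresses a dedicated transgene feature — the
analogue of selection-marker-carrying control cells spiked into a
dissociation. Gene-by-batch multiplicative effects are log-normal with SD
0.15 on the log2 scale, a mild but detectable batch effect. A single seed
determines every draw; substream seeds are derived from it, so all outputs
are reproducible byte for byte.

The generator's defaults are the package's reference study conditions:
five clusters of 200 cells, 2,000 genes, 10% markers, 4,000 ambient
barcodes. Scaled-down variants used by specific analyses are stated below.

`simulateTwoSpecies()` links two such datasets by an ortholog table.
Conserved clusters share marker genes through one-to-one pairs at high
identity (85–99%); divergent clusters get species-private markers, and, in
the second species, additionally mimic half the marker set of their nearest
conserved cluster, so that label transfer confuses exactly those two
classes — the planted analogue of cross-species misclassification between
related stromal subsets. The table also carries planted one-to-many /
many-to-one / many-to-many rows and one-to-one identities spanning 60–99%
so the identity filter has real work to do.

`simulateTrajectory()` assigns each cell a latent time $t \in [0,1]$ and
moves a planted fraction of genes along $t$ through linear or sigmoid
programs (two thirds rising, one third falling). Dynamic genes share a
common moderate baseline so that their summed, depth-normalized signal
tracks $t$; without this, a handful of highly abundant falling genes can
cancel the rising ones, which is a property of random abundance draws
rather than of trajectories. An optional branch at $t = 0.5$ splits cells
into two lineages with a lineage-specific late program.

`simulateCellCycle()` plants, per phase (G1, S, G2M), ordered gene pairs
(hi, lo) with a 16-fold mean separation inside the phase and the reverse
outside it, which guarantees the pair inequality holds in at least 90% of
in-phase cells and at most 10% of others at the default noise. The last
cluster is proliferative (60% G2M), supporting G2M-proportion summaries.

What the simulations do **not** emulate: doublets, ambient RNA
contamination inside real cells, gene-length or GC biases, zero inflation
beyond the NB, empirical mean-variance trends of specific chemistries, or
realistic gene-gene correlation outside the planted modules. Passing tests
demonstrate that the algorithms recover structure they are designed for
under controlled conditions — not that any particular biological claim
holds on real tissue.

## Barcode calling and QC

Barcodes below a hard floor of 250 UMIs are discarded. On the remainder a
Gaussian kernel density of log10 totals is estimated on a 512-point grid,
with Silverman's rule-of-thumb bandwidth; the calling threshold is the
first interior grid point whose density is strictly below both neighbors,
scanning from low to high, and accepted only when the density rises to at
least twice the candidate's depth on both sides and at least 5% of the
above-floor barcodes lie above it — a genuine inter-mode valley below a
real cell mode, not a sampling wiggle of a single mode or the gap in front
of a lone outlier barcode (without these conditions, a sample whose ambient
barcodes all fall below the floor can lose almost all its cells to a
spurious high minimum). This is deterministic and
testable; the log10 scale makes the rule scale-free, and the bandwidth
choice matters little because the two modes are far apart (50-fold by
default). If no qualifying valley exists, the floor is used with a warning.
Thresholds are per sample.

Cells with strictly more than 5% mitochondrial UMIs are removed (a cell at
exactly 5.0% is retained). Control-cell clusters are removed automatically:
any initial cluster in which more than half the cells detect the transgene
is excluded entirely — a threshold that replaces manual marker inspection
with a reproducible rule. C1 library QC applies robust lower-tail rules
(median − 3 MAD on log totals and genes detected) plus caps on spike-in and
mitochondrial fractions, since the original metric list comes with no
printed cutoffs.

## Normalization and factor removal

Size factors come from the pooled deconvolution estimator (pool sizes
21–41) with library-size fallback for tiny datasets and for non-positive
estimates; expression is log2(count/factor + 1). On the C1 track a loess
trend (span 0.3, a smooth local fit chosen in the absence of a stated
bandwidth) of per-gene variance against mean identifies technical control
genes as those strictly below their fitted variance; the first left
singular vector of the row-centered control submatrix is the unwanted
factor and is projected out of every gene (one factor by default — the
minimal choice when the true number is unknown; 0 disables the step).
Residuals keep their gene means. Because the factor removal can produce
small negative values, the NMF stage clamps its input at zero.

Variable genes on the droplet track require detection in at least 3 cells,
mean of non-zero log expression strictly between 0.0125 and 4, and SD over
all cells above 0.5 — the thresholds are taken literally, with the non-zero
mean computed exactly as stated and the SD over all cells. The droplet
pipeline additionally excludes mitochondrial genes from the variable set:
their shared per-cell fraction is a QC covariate, and left in, it surfaces
as a principal component along which community detection splits every
cluster into high- and low-mitochondrial halves.

## PCA, jackstraw, graph clustering, t-SNE

PCA centers and unit-scales genes, orders components by variance, and fixes
signs so the largest-magnitude loading is positive. The jackstraw permutes
a small fraction of genes (1% by default) across cells and recomputes the
decomposition per replicate; the permuted genes' squared loadings form the
null and the unpermuted genes' loadings, averaged over the same refits, the
observed statistics, so both sides share the refit geometry. A component is
significant when gene p-values below alpha are enriched beyond uniformity
(one-sided binomial test), and the largest significant prefix is kept. The
test is mildly anti-conservative on small matrices — genes that participate
in almost every fit carry slightly inflated loadings relative to freshly
permuted ones — but is calibrated at the package's reference scale (2,000
genes by 500 cells: structureless data yield no significant components in
at least 9 of 10 seeded runs). All significant components feed clustering.

Clustering builds a k-nearest-neighbor graph (k = 20), weights edges by
the Jaccard overlap of neighbor lists (shared nearest neighbors), prunes
weights below 1/15, and optimizes modularity (Louvain) at resolution 0.8.
Labels are renumbered by decreasing size and are deterministic given the
seed. Modularity on low-dimensional lattice-like graphs tends to
over-partition single Gaussian blobs; on expression-derived PC coordinates
(10+ effective dimensions) the planted five-cluster reference simulation is
recovered with ARI 1.0 across seeds. t-SNE is run from ten random
initializations by default and the run with the lowest final KL divergence
is kept; every run's divergence is retained for inspection.

## Co-expression network and dynamic tree cut

The gene network is signed-hybrid: negative Pearson correlations are set to
zero before raising to the soft power $\beta = 4$, and dissimilarity is
$1 - a$. Edge confidence pruning removes pairs co-detected above a
normalized-count threshold (default 6, the midpoint of the working range
5–8) in fewer than 3 cells (the lower end of "3 or 4"), cutting
connections supported only by sporadic co-detection.

Module detection cuts the average-linkage dendrogram adaptively. An initial
cut just below the top (0.99 of the maximum height) defines coarse
branches; each branch is split recursively at its highest merge whenever
both sub-branches hold at least `min_module_size` genes (default 30) and
the relative height gap of the split exceeds a threshold that shrinks as
`deep_split` grows — `deep_split` 0..4 maps to a scatter cap of
0.64/0.73/0.82/0.91/0.95 whose complement (times 3/4) is the required gap,
so larger settings split more aggressively and yield more, smaller modules,
monotonically. A final branch becomes a module only if its mean internal
dissimilarity stays below the cut height; all other genes are labeled 0.
This is a deliberately transparent variant of adaptive branch cutting: it
reproduces the behavior that matters downstream (planted module recovery at
ARI ≥ 0.9, module-size floors, monotone split sensitivity) without the full
hybrid machinery of partitioning-around-medoids label assignment.

## NMF consensus clustering and rank selection

Cells are clustered by non-negative matrix factorization of the module-gene
expression with the Kullback-Leibler objective and multiplicative updates
(at most 2,000 iterations, relative tolerance 1e-6; the update kernel is
compiled). Per rank, 50 random restarts each assign every cell to its
arg-max basis component; the consensus matrix records co-assignment
frequencies. Per-rank quality metrics: cophenetic correlation between the
consensus dissimilarity and its average-linkage dendrogram; mean silhouette
width of the dendrogram cut at that rank on 1 − consensus (consensus
space, not expression space); dispersion $\mathrm{mean}(4(c - 1/2)^2)$,
which is 1 for a binary consensus and 0 for an all-0.5 one; and the
residual sum of squares of the best-objective fit. The chosen rank is the
smallest simultaneous local maximum of cophenetic, silhouette and
dispersion; failing that, per-metric first maxima tie-broken toward the RSS
inflection (largest absolute second difference); failing that, the smallest
surveyed rank with a warning. The same survey runs on per-gene independently
permuted data as a control — structure-free data whose metrics sit well
below the observed ones at the selected rank. Labels at the chosen rank
come from the average-linkage cut of 1 − consensus, consistent with the
cophenetic computation.

The reference rank-recovery simulation uses 4 clusters of 75 cells, 600
genes with 25% markers, ranks 2–6, 15 restarts and a 200-iteration cap —
sizes at which the survey completes in a few tens of seconds per seed while
still selecting the planted rank in at least 8 of 10 seeds; restarts beyond
~15 and iterations beyond ~200 change the consensus matrices negligibly on
these data.

## Markers, differential expression, enrichment

The marker statistic is the one-vs-rest AUC computed as a rank-sum with
midranks (ties count one half); each gene is tested for the cluster where
its mean is highest, and the top 200 genes per cluster are candidate
markers. Filtered tests require detection in at least 25% of either group
and an absolute log fold change of at least 0.25; in AUC mode, genes are
reported when |AUC − 0.5| ≥ 0.2 (the reporting threshold 0.3 interpreted as
a bound on classifier power — the reading that matches the conventional
ROC-mode semantics). Log fold changes are natural logs of de-logged group
means, the same scale as the detection filters.

The negative binomial GLM fits per gene a log-linear model with a log
size-factor offset and latent covariates (total UMIs, cycle scores, batch).
Dispersion is estimated by method of moments from a Poisson fit and refined
with one Newton step on the pseudo-likelihood equation; each gene gets its
own dispersion (a shared-dispersion variant would shrink estimates but the
per-gene choice is the conservative default when the original choice is
unrecorded). The group coefficient is tested by Wald; p-values are
BH-adjusted; non-converging genes are flagged NA rather than dropped
silently. On 2,000 null genes the empirical type-I error at 0.05 falls in
[0.03, 0.07], and a planted log2 fold change of 1 is recovered with median
in [0.8, 1.2].

Gene-set enrichment is an upper-tail hypergeometric test against the
expressed-gene background with BH correction, both thresholds 0.05; gene
sets are user-supplied GMT files — no ontology database is bundled, which
keeps results independent of database versions. Marker-set overlaps between
two clusterings use a one-sided Fisher exact test per cluster pair
(enrichment direction, since the display is an enrichment screen).

## Cross-species random forests

Ortholog tables are filtered to one-to-one rows; when both directional
identities are present the minimum must reach 75% — the conservative
reading of "identity between pairs". The result is forced to a bijection.
Class balancing down-samples majorities to the median class size and
up-samples minorities by SMOTE (k = 5 neighbors, interpolation
$x + \lambda(x_{nn} - x)$, $\lambda \sim U(0,1)$); SMOTE runs before
feature selection, which follows the original ordering of operations but
lets synthetic points inform the selection — a leakage caveat worth
remembering when quoting cross-validated accuracies. Recursive feature
elimination ranks features by impurity importance (the canonical forest
default), evaluates a descending size schedule by k-fold cross-validation,
and picks the smallest size within one SD of the best. Forests use
ntree = 1000 and mtry = ⌊√p⌋. Confusion matrices are row-normalized;
per-class AUC comes from out-of-forest vote fractions; feature specificity
is the per-gene one-vs-rest AUC, compared across species by Pearson
correlation per cluster.

## Diffusion maps and pseudotime

The kernel is Gaussian on the symmetrized kNN graph (k = 500, clamped to
n − 1 with a warning) with local bandwidths: $\sigma_i$ is the distance to
the ⌈k/100⌉-th neighbor, at least the 5th — a per-cell quantile bandwidth,
the standard realization of a "local" scale. Density normalization with
$\alpha = 1$ removes sampling-density effects, the operator is
row-normalized, and its top non-trivial eigenvectors (10 by default) are
the components. Disconnected graphs are handled by computing the map on the
largest component and flagging the rest with NA coordinates. Pseudotime is
the Euclidean distance from the root cell in components scaled by
$\lambda/(1-\lambda)$, excluding eigenvalue-1 components; the root scores
exactly 0. On the 500-cell linear reference trajectory the Spearman
correlation with the planted time exceeds 0.9.

Cell-cycle scores are the fraction of a phase's marker pairs with strictly
higher hi-gene expression, excluding tied pairs from the denominator — a
rank-based score invariant to monotone per-cell transforms. The original
pair-based method's permutation normalization is omitted: at desk scale
the raw pair fraction with fixed 0.5 cut-offs is deterministic and already
achieves ≥ 0.9 phase accuracy on the reference simulation. Phase calls: G1
if g1 ≥ 0.5 and g2m < 0.5, G2M in the mirror case, S otherwise (including
all-tied cells).

## Integration diagnostics

Batch-mixing entropy samples 100 cell locations per bootstrap (100
bootstraps), takes each location's 100 nearest embedding neighbors — a
fixed-size neighborhood chosen for determinism, since the original
neighborhood extent is unstated — and averages the normalized Shannon
entropy of batch proportions, $-\sum_b p_b \ln p_b / \ln B$; normalizing by
ln B makes the negative control (shuffled labels) comparable across batch
counts, and the positive control replaces batches with cluster labels.
Pseudo-bulk profiles are per-cluster means of normalized log expression
(the comparison target being normalized array intensities, not raw counts).
Reference quantile normalization replaces each column rank-wise by the
reference's sorted values with midrank averaging for ties; it is exact on
marginals and idempotent. Batch adjustment uses parametric empirical-Bayes
location/scale shrinkage (ComBat); the non-parametric variant is out of
scope. Cluster trees over average cells use complete-linkage Euclidean
distance, and each internal node's confidence is the out-of-bag error of a
forest allocating member cells to the node's two branches.

## Numerical and degenerate-input conventions

Zero-variance genes get zero network correlation (with a warning) and are
dropped before PCA. Consensus matrices are validated symmetric with unit
diagonal. Rank selection treats the trailing surveyed rank as a boundary,
not a peak, unless it is the only candidate. The local-minimum scan of the
barcode density requires strict inequality on both sides, so plateaus do
not trigger calls. All stochastic steps (simulations, NMF restarts,
jackstraw, SMOTE, forests, t-SNE, entropy bootstraps) derive their streams
from a single integer seed.

## Known limitations

The dynamic tree cut is a simplified top-down variant (no PAM stage, no
branch re-assignment), adequate for well-separated co-expression blocks but
coarser than the full hybrid algorithm on gradual module boundaries. The
NB GLM uses per-gene moment dispersion with a single refinement rather than
full maximum likelihood, trading a small loss of power for speed and
robustness at desk scale. SMOTE before cross-validation leaks minority
structure into fold estimates, as noted. Batch entropy uses fixed-size
neighborhoods; very unequal batch sizes compress its dynamic range. The
generator's independence assumptions (NB noise, planted blocks) make
recovery easier than on real tissue; results on these simulations bound
what the algorithms can do under their own assumptions, nothing more.
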