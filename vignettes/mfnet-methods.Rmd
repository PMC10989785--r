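---
title: "Methods: linking soil multifunctionality to microbial network properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking soil multifunctionality to microbial network properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mfnet implements the analysis chain used in manipulative climate-change
experiments that ask how a treatment (here, altered precipitation)
reshapes soil ecosystem multifunctionality through the soil microbiome:
its diversity, its assembly regime, and the architecture of its
cross-kingdom co-occurrence network. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices that the
underlying methods leave open.

## The study design and the synthetic generator

The emulated design is a three-level precipitation manipulation — DP
(decreased), Control (ambient), IP (increased) — with six biological
replicates each, i.e. 18 samples. Because such field datasets (paired
16S/ITS OTU tables, 17 soil functions, 10 soil covariates) are rarely
public, `generate_otu_tables()` and `generate_functions()` produce
seeded synthetic data carrying exactly the statistical structure the
downstream stages assume:

* **Latent abundances.** Each OTU has a multivariate-normal
  log-abundance across samples. `n_blocks` correlation blocks (default
  4 blocks of 12 OTUs, latent within-block correlation 0.9) span both
  kingdoms at rate `block_cross_kingdom_fraction` (default 0.25).
  A fraction of block members carries sign-flipped loadings, which
  produces negative pairwise associations; the baseline fraction of
  negative within-block pairs is set by `negative_edge_fraction`
  (0.20 for Control/IP). Counts are fixed-depth multinomial draws
  (10,000 reads per kingdom and sample), so the data are compositional
  like real sequencing output.
* **Richness effects as structural zeros.** A global baseline absent
  set (10% of each pool) is drawn once; treatment effects then remove
  (or, for positive effects, resurrect) OTUs for all samples of a
  treatment. Zeroing rather than down-scaling makes the expected
  richness targets exact. Defaults use the fractional changes such
  manipulations report: DP −7.9% bacterial and −20.9% fungal richness,
  IP +5.3% fungal richness.
* **Competitive-interaction shift.** DP's target negative-pair
  fraction is higher (0.35 vs 0.20). Three structures implement it.
  The mixed blocks carry a sign mixture solved from the high target
  (`2q(1-q) = 0.35`), allocated deterministically per block and
  kingdom so the realized composition does not fluctuate. A
  "mesic" all-positive cross-kingdom block — sized from the target
  ratio — is structurally absent under DP (it is part of DP's richness
  loss), so its positive bacterial-fungal edges dilute the negative
  fraction in Control and IP samples only. And a handful of obligate
  competitive bacterium-fungus pairs (always present, abundant,
  latent anti-correlation 0.995) guarantee that negative
  inter-kingdom edges survive threshold selection in every sample.
  Two compositional subtleties drove this design: anti-correlated
  pairs near the detection floor have their correlations censored
  away (hence mixed-block members carry a +2 log-sd abundance bonus),
  and an abundant block leaving the community inflates every
  remaining relative abundance, planting spurious negative
  associations (hence the mesic block's bonus is only +0.5 log-sd).
  The control is directional and approximately calibrated, not
  exact.
* **Functions.** 17 functions in 4 groups (5 nutrient provisioning,
  5 microbial growth efficiency, 5 labile-organic-matter decomposition,
  2 recalcitrant-organic-matter decomposition) are simulated as
  baseline + treatment-by-group shift + Gaussian noise (`noise_sd`
  0.25 on the standardized scale), then given arbitrary per-function
  affine units (min–max standardization removes them). Field reports
  give only group-level percentage responses, so the standardized
  shifts are free parameters; the defaults (DP: −0.8 for nutrient,
  growth and LOM, +0.8 for ROM; IP: +0.6 for growth) reproduce the
  reported response directions with comfortable signal-to-noise at
  n = 6.

What the generator does **not** emulate: phylogenetic structure,
taxon-specific dynamics, overdispersion beyond the lognormal-multinomial
hierarchy, spatial autocorrelation among replicates, and any coupling
between the OTU tables and the function matrix other than their common
treatment effects. Passing tests therefore certify the pipeline's
statistical machinery, not field-data conclusions.

All stochastic functions take an explicit seed and restore the caller's
RNG state; identical seeds give bit-identical output.

## Multifunctionality indices

All 17 functions are min–max standardized to [0, 1]. A constant
function is mapped to 0.5 with a warning: dropping it would silently
change the denominator of every index. Three indices are computed:

* **averaging** — mean of the 17 standardized functions;
* **group-weighted** — mean of the four group means, so the 2-member
  ROM group counts as much as the 5-member groups;
* **principal-coordinate** — first axis of a Euclidean PCoA of the
  standardized matrix (numerically identical to the first principal
  component of the centered matrix). A PCoA axis has arbitrary sign, so
  it is oriented to correlate nonnegatively (Spearman) with the
  averaging index; further axes are returned for inspection since
  "dimensions of multifunctionality" beyond the first can be of
  interest.

ROM decomposition enters all indices with positive orientation, exactly
as measured; whether it is a desirable function is an interpretation
left to the analyst.

## Diversity and community assembly

Tables are rarefied to the minimum sample depth (without replacement,
seeded) before any diversity computation. Richness is the count of
nonzero OTUs; the combined biodiversity score averages the min–max
standardized bacterial and fungal richness. Levins' niche breadth is
`B = 1 / sum(p^2)` over an OTU's across-sample proportions; the
community summary is the unweighted mean over OTUs occurring at least
twice (the weighting choice is recorded in the output).

**NST.** The normalized stochasticity ratio compares, for each
within-treatment sample pair, the observed incidence-Jaccard
dissimilarity `D` with its expectation `E` under a null model that
fixes each sample's richness and draws taxa with probability
proportional to regional occupancy. Pairwise stochasticity is `D/E`
when `D <= E` and `(1-D)/(1-E)` otherwise; the treatment value is the
mean over pairs, clamped to [0, 1]. The reference method family leaves
the null options open; fixed-richness proportional-occupancy is the
default of that family and is echoed in the result's settings. Two
caveats. Homogenized samples (identical composition while the regional
occupancy support is wider than any one sample) give 0 — deterministic
homogenization is a maximal departure from the null; in the fully
degenerate case where every sample is identical the occupancy support
collapses to exactly those taxa, the plug-in null reproduces the
samples, and the ratio is (consistently) 1. Second, the plug-in
occupancy weights are estimated from the data, which biases the ratio
below 1 for small, sparse sample sets even when the data come from the
null process itself (about 0.80 at 6 sparse samples, about 0.95 at 18
denser ones).
The self-consistency test therefore uses 18 samples, 150 of 250 taxa —
the package states this as its chosen benchmark configuration.

**Sloan's neutral model.** The sampler draws each taxon's per-sample
relative abundance from the stationary beta distribution with shapes
`(N m p, N m (1-p))` and then samples `N` reads multinomially. The
fitter estimates `m` by nonlinear least squares (via minpack.lm) of
occurrence frequencies against the neutral prediction. Its default
detection model is the **sampling-aware** one: detection fails exactly
when the beta-binomial read count is zero, giving
`F(p) = 1 - B(Nmp, Nm(1-p)+N) / B(Nmp, Nm(1-p))`. The classic hard
detection limit `d = 1/N` (`detection = "threshold"`) is also provided;
on read-sampled data it overestimates `m` by roughly 25%, because the
read layer softens detection below the one-read threshold, which is why
it is not the default. R² is computed on untransformed frequencies and
may be negative far from neutrality; near-saturated tables (every OTU
in every sample) are flagged as degenerate fits.

## The co-occurrence network

OTUs present in at least half the samples (9 of 18) are retained and
the kingdoms merged. Pairwise Pearson correlations are computed on
log10 relative abundances with the smallest nonzero relative abundance
added as a pseudo-fraction; the upstream pipelines this follows do not
state their transform, so the setting is recorded and overridable
(`transform = "none"` for raw relative abundances).

The correlation cutoff is chosen by random matrix theory: at each
candidate `s` the matrix restricted to OTUs with at least one
`|r| >= s` entry (weaker entries zeroed) has its eigenvalue spectrum
unfolded — duplicate eigenvalues removed (degeneracies of sparse
matrices flood the spacing distribution with exact zeros and carry no
level-repulsion information), then the cumulative staircase smoothed by
a cubic smoothing spline evaluated on a 51-point grid — and the
nearest-neighbour spacing distribution is tested (chi-squared, 20 bins
on [0, 3], tail folded into the last bin) against the Poisson law
`exp(-d)` and the Gaussian-orthogonal-ensemble Wigner surmise. The
threshold is the smallest `s` whose spacings fit Poisson (p > 0.05)
with GOE rejected; the default grid is 0.30–0.95 in steps of 0.025
(the Poisson window can be narrow, so a coarse 0.05 grid may skip it;
0.01 is supported where runtime allows). Ties break toward the smaller
threshold by construction of the scan.

The network has an edge for every pair at `|r| >=` threshold, signed
by the correlation; isolated nodes are dropped. Clusters come from
agglomerative greedy modularity maximization on `|r|` weights
(signed-modularity variants are out of scope), labelled in decreasing
size order. Link composition reports the negative fraction, the
bacterial–fungal fraction, and the negative fraction **among**
bacterial–fungal edges (the denominator choice; the all-edges variant
is a trivial product of the other two).

## Subnetwork topology and the complexity index

Each sample's subnetwork is the induced subgraph on its present OTUs —
never re-inferred. Seven features are computed: node and edge counts,
average degree `2E/N`, mean local clustering (degree < 2 nodes
contribute 0), average path length over connected pairs only (keeping
its reciprocal finite for disconnected graphs), density, and mean
normalized betweenness (the summary statistic for betweenness is a
choice; the mean is used). For the complexity index the average path
length — a sparsity measure — is replaced by its reciprocal (0 for
edgeless graphs), features are z-scored (constant ones dropped with a
warning), and the first Euclidean-PCoA axis, oriented positively with
average degree, is the score. Z-scoring makes the score invariant to
affine rescaling and ordering of the input features.

Treatment differences per feature use Kruskal–Wallis tests with Dunn
pairwise z-tests (Benjamini–Hochberg corrected) rendered as a compact
letter display; the insert–absorb letter assignment is exact for the
three treatment groups compared here.

## Stability

* **Robustness**: remove `floor(fN)` nodes (uniformly, or hubs first by
  degree), then iteratively delete newly isolated nodes — the
  extinction rule is isolation, abundance-weighted variants are out of
  scope — and report the surviving fraction, averaged over Monte-Carlo
  replicates (default `f = 0.5`, 1000 replicates; both echoed in the
  output since the upstream literature varies).
* **Vulnerability**: `max_i (E - E_i)/E` with `E` the global efficiency
  (mean inverse shortest-path length over ordered pairs, 0 for
  unreachable pairs).
* **Relative modularity**: `(M_obs - mean M_rand)/mean M_rand` against
  node- and edge-count matched Erdős–Rényi graphs.
* **K–S tests** compare node-attribute distributions (degree,
  betweenness, clustering) between two networks.

Per-treatment networks are induced subgraphs of the metacommunity
network on each treatment's majority-present OTUs. Re-inferring
correlations from six replicates at the metacommunity threshold is
noise-dominated (the null spread of Pearson's r at n = 6 exceeds most
thresholds), so a shared edge set is both more honest and more
comparable across treatments.

## Driver attribution

`spearman_screen()` gives rank correlations with BH-adjusted q-values.
`permutation_importance()` fits a regression random forest and defines
importance as the out-of-bag MSE increase under predictor permutation
as a percent of baseline OOB MSE, with significance from refits on
response-permuted data (the importance definition many published
"%IncMSE" figures intend; the forest library's scaled variant divides
by its standard error instead). `partial_correlation()` uses the
precision-matrix formula, defaulting to Pearson inside (a rank-based
variant is exposed because screening is Spearman-based while the
partial-correlation convention is Pearson); `partial_report()` computes
the zero-order and all pairwise-controlled correlations with the
percent change of each — the layout in which a mediator reveals itself
by reducing other factors' correlations more than they reduce its own.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant vectors standardize
to 0.5 with a warning; zero-variance OTUs are excluded from
correlations; empty networks and edgeless subnetworks raise errors or
zero-profiles as documented; singular control sets in partial
correlations raise an error carrying the condition number; NST ratios
with `E = 0, D = 0` are defined as 1.

The shipped tests and the reproduction script run the chain at sizes
chosen to exercise every code path at desk scale: 300 + 150 OTUs at
depth 10,000 for the study emulation; 500 taxa × 30 samples × 20 seeds
for neutral-model recovery; 1000 null randomizations for the NST
benchmark; 10,000 simulations for the Spearman calibration; and 20
seeded end-to-end runs for the direction-reproducibility rate. These
sizes are stated here as the package's benchmark configuration so
results are comparable across machines.

## Known limitations

Co-occurrence edges are not interactions; the RMT threshold selection
is a heuristic whose chi-squared tests are approximate at small spacing
counts; NST's plug-in null biases the ratio downward at small n; the
complexity score is a relative (centered) quantity, comparable only
within a run; and the generator's negative-link control is directional
rather than calibrated. Phylogenetic diversity, compositional
association methods (SparCC and relatives), threshold-count
multifunctionality, and structural equation modeling are deliberately
out of scope.
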