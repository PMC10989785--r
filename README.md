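# mfnet

Soil ecosystems deliver many functions at once — nutrient provisioning,
microbial growth, decomposition of labile and recalcitrant organic
matter — and manipulative climate experiments routinely ask how a
treatment such as altered precipitation reshapes this
**multifunctionality** through the soil microbiome. mfnet is an R
toolkit for that whole analysis chain, written for microbial ecologists
working with paired bacterial (16S) and fungal (ITS) OTU tables, a
function matrix, and soil covariates from a replicated field design:

* **Multifunctionality indices** — each function min–max standardized
  to [0, 1]; the averaging index `MF = mean(f_1..f_K)`, the
  group-weighted index (mean of the four function-group means), and a
  principal-coordinate index (first PCoA axis of the standardized
  matrix).
* **Community assembly** — rarefaction, OTU richness and a combined
  two-kingdom biodiversity score; Levins' niche breadth
  `B = 1 / sum_i p_i^2`; a null-model normalized stochasticity ratio
  (`D/E` vs `(1-D)/(1-E)` on incidence Jaccard under a fixed-richness,
  proportional-occupancy null); and Sloan's neutral community model,
  estimating the migration rate `m` from the occurrence–abundance
  relationship `F(p) = 1 - Beta(N m p, N m (1-p))`-tail.
* **Cross-kingdom co-occurrence network** — occupancy filtering,
  Pearson correlations on log relative abundances, a random-matrix-
  theory threshold (the smallest cutoff whose eigenvalue spacing
  distribution turns Poisson while the Gaussian-orthogonal-ensemble law
  is rejected), greedy-modularity clusters, and link composition (Neg,
  B–F links, Neg in B–F links).
* **Per-sample subnetwork topology** — seven features (nodes, edges,
  average degree, clustering, path length, density, betweenness)
  collapsed into a network-complexity score, with Kruskal–Wallis/Dunn
  treatment comparisons.
* **Stability** — robustness under random or hub-targeted node removal
  with an isolation-extinction cascade, vulnerability
  `max_i (E - E_i)/E` on global efficiency, relative modularity against
  Erdős–Rényi baselines, and K–S tests on node attributes.
* **Driver attribution** — Spearman screening, random-forest
  permutation importance (%IncMSE with response-permutation p-values),
  and zero-order vs controlled partial correlations.

Because such field datasets are rarely public, mfnet ships a seeded
synthetic generator that emulates a 3-treatment × 6-replicate
precipitation manipulation (DP = −50%, Control, IP = +50%) with
two-kingdom OTU tables, planted cross-kingdom correlation blocks and
competitive pairs, 17 functions in 4 groups, and soil covariates — so
every stage is testable end to end.

## Worked example

```r
library(mfnet)
res <- run_pipeline(sim_config(seed = 42), n_null = 200,
                    stability_reps = 200, rf_perms = 50)
print(res)
#> mfnet pipeline run
#>   samples: 18; network: 306 nodes / 1672 edges (|r| >= 0.68)
#>   modularity 0.477 in 23 clusters; neg 0.099, B-F 0.455, neg in B-F 0.097

treatment_effects(res) |> subset(treatment == "DP")
#>               quantity change       type
#>                 mf_avg -58.43    percent
#>  nutrient_provisioning -70.99    percent
#>      growth_efficiency -76.17    percent
#>      LOM_decomposition -66.72    percent
#>      ROM_decomposition 130.65    percent
#>      richness_bacteria  -7.48    percent
#>         richness_fungi -20.15    percent
#>             complexity  -4.93 difference
#>              neg_in_bf   0.16 difference
```

Reading this: the decreased-precipitation treatment suppressed the
averaging multifunctionality index by 58% and bacterial/fungal richness
by 7.5%/20.2% while raising recalcitrant-organic-matter decomposition —
the effect pattern the generator plants, recovered by the full chain
(the richness changes land on the configured −7.9%/−20.9% targets up to
sampling noise). The complexity score (centered, so reported as a
difference) drops under DP, and the negative fraction of
bacterial–fungal links rises by 0.16.

```r
res$assembly$ncm$fungi
#> Sloan NCM fit: m = 0.2533, R^2 = -0.010 (N = 10000, 142 OTUs)
head(res$linkage$importance, 4)
#>  predictor inc_mse_pct      p
#>        SWC         193 0.0196
#>        neg         190 0.0196
#>   bf_links         149 0.0196
#>        SOC         134 0.0196
```

(The near-zero NCM R² is expected here: the generator's communities
are built from treatment effects and correlation blocks, not neutral
dynamics; the fit is diagnostic, and recovers `m` to within a few
percent on data from the neutral sampler itself.)

See `vignettes/mfnet-methods.Rmd` for the models, their assumptions,
and every numerical design choice.

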