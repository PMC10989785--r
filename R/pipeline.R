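#' Run the full multifunctionality-network analysis pipeline
#'
#' End-to-end orchestration: simulate (or accept) a study dataset, then
#' compute multifunctionality indices, diversity and assembly statistics,
#' the RMT-thresholded cross-kingdom metacommunity network with greedy
#' clusters and link composition, per-sample subnetwork topology and the
#' complexity index, per-treatment network stability, and the driver
#' analyses linking everything to multifunctionality.
#'
#' Per-treatment networks reuse the metacommunity RMT threshold: with
#' only a handful of replicates per treatment the spectrum is too small
#' to re-run threshold selection reliably, and a shared threshold keeps
#' the treatment networks comparable.
#'
#' @param cfg A [sim_config()]; its `seed` drives every stochastic step.
#' @param data Optional pre-built list with elements `design`,
#'   `bacteria`, `fungi` ([otu_table]s), `functions`, `groups`, `soil`;
#'   when supplied the generator is skipped.
#' @param min_present Occupancy filter threshold (default half the
#'   samples).
#' @param n_null NST null randomizations (default 1000).
#' @param stability_reps Robustness Monte-Carlo replicates (default
#'   1000).
#' @param rf_perms Response permutations for importance p-values
#'   (default 100).
#' @param run_importance,run_stability,run_nst Logical switches for the
#'   more expensive stages.
#' @return A list of class `mfnet_pipeline` with the per-stage results
#'   (see the elements `design`, `mf`, `diversity`, `assembly`,
#'   `network`, `topology`, `stability`, `linkage`).
#' @export
run_pipeline <- function(cfg = sim_config(), data = NULL,
                         min_present = NULL, n_null = 1000,
                         stability_reps = 1000, rf_perms = 100,
                         run_importance = TRUE, run_stability = TRUE,
                         run_nst = TRUE) {
  if (is.null(data)) {
    design <- generate_design(6)
    tabs <- generate_otu_tables(design, cfg)
    fns <- generate_functions(design, cfg)
    data <- list(design = design, bacteria = tabs$bacteria,
                 fungi = tabs$fungi, functions = fns$functions,
                 groups = fns$groups, soil = fns$soil,
                 blocks = tabs$blocks)
  }
  design <- data$design
  n_s <- nrow(design)
  if (is.null(min_present)) min_present <- ceiling(n_s / 2)
  seed <- cfg$seed

  # rarefy both kingdoms to their own minimum sample depth
  bact <- rarefy(data$bacteria, min(rowSums(data$bacteria$counts)),
                 seed = seed + 11L)
  fung <- rarefy(data$fungi, min(rowSums(data$fungi$counts)),
                 seed = seed + 12L)

  mf <- multifunctionality(data$functions, data$groups)

  rich_b <- richness(bact)
  rich_f <- richness(fung)
  biodiv <- combined_biodiversity(rich_b, rich_f)
  diversity <- data.frame(sample_id = design$sample_id,
                          treatment = design$treatment,
                          richness_bacteria = rich_b,
                          richness_fungi = rich_f,
                          biodiversity = biodiv)

  assembly <- list(
    niche_breadth = list(bacteria = levins_niche_breadth(bact),
                         fungi = levins_niche_breadth(fung)),
    ncm = list(bacteria = sloan_ncm_fit(bact),
               fungi = sloan_ncm_fit(fung)))
  if (run_nst) {
    assembly$nst <- list(
      bacteria = nst(bact, design$treatment, n_null, seed + 21L),
      fungi = nst(fung, design$treatment, n_null, seed + 22L))
  }

  merged <- occupancy_filter(bact, fung, min_present)
  corr <- correlation_matrix(merged)
  # retry on a finer, wider candidate grid before giving up: the Poisson
  # window can fall between coarse grid points
  thr <- tryCatch(rmt_threshold(corr),
                  error = function(e)
                    rmt_threshold(corr, s_min = 0.2, s_max = 0.99,
                                  step = 0.01))
  net <- build_network(corr, thr$threshold, merged)
  clusters <- greedy_modularity_clusters(net)
  links <- link_type_proportions(net)
  cl_rich <- cluster_richness(clusters, merged)

  profiles <- topology_profiles(net, merged)
  cx <- complexity_index(profiles)
  topo_cmp <- compare_topology(profiles, design$treatment)

  # per-sample link composition from the induced subnetworks
  sample_links <- t(vapply(design$sample_id, function(s) {
    present <- colnames(merged$counts)[merged$counts[s, ] > 0]
    sub <- extract_subnetwork(net, present)
    unlist(suppressWarnings(link_type_proportions(sub)))
  }, numeric(3)))

  stability <- NULL
  if (run_stability) {
    # treatment networks: induced subgraphs of the metacommunity network
    # on each treatment's majority-present OTUs. Re-inferring
    # correlations from 6 replicates would be noise-dominated; induced
    # subgraphs keep the treatments comparable on a common edge set.
    trt_nets <- lapply(levels(design$treatment), function(tr) {
      rows <- design$treatment == tr
      occ <- colSums(merged$counts[rows, , drop = FALSE] > 0)
      present <- colnames(merged$counts)[occ >= ceiling(sum(rows) / 2)]
      g <- extract_subnetwork(net, present)
      if (igraph::ecount(g) == 0) NULL else g
    })
    names(trt_nets) <- levels(design$treatment)
    stability <- lapply(trt_nets, function(g) {
      if (is.null(g)) return(NULL)
      list(robustness_random = robustness(g, 0.5, "random",
                                          stability_reps, seed + 31L),
           robustness_targeted = robustness(g, 0.5, "targeted_hub"),
           vulnerability = vulnerability(g),
           relative_modularity = relative_modularity(
             g, max(100, stability_reps), seed + 32L),
           n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
    })
    pairs <- utils::combn(names(trt_nets), 2, simplify = FALSE)
    stability$ks <- lapply(pairs, function(pr) {
      a <- trt_nets[[pr[1]]]; b <- trt_nets[[pr[2]]]
      if (is.null(a) || is.null(b)) return(NULL)
      c(list(pair = paste(pr, collapse = " vs ")),
        degree = list(ks_node_features(a, b, "degree")))
    })
    stability$networks <- trt_nets
  }

  soil <- data$soil
  soil_pc1 <- stats::prcomp(scale(soil))$x[, 1]
  if (stats::cor(soil_pc1, soil$SWC) < 0) soil_pc1 <- -soil_pc1
  predictors <- data.frame(biodiversity = biodiv,
                           complexity = cx$score,
                           neg = sample_links[, "neg"],
                           bf_links = sample_links[, "bf_links"],
                           neg_in_bf = sample_links[, "neg_in_bf"],
                           cluster12_richness =
                             rowSums(cl_rich[, 1:min(2, ncol(cl_rich)),
                                             drop = FALSE]),
                           soil, check.names = FALSE)
  linkage <- list(spearman = spearman_screen(predictors, mf$mf_avg))
  if (run_importance)
    linkage$importance <- permutation_importance(predictors, mf$mf_avg,
                                                 n_perms = rf_perms,
                                                 seed = seed + 41L)
  factor_set <- data.frame(biodiversity = biodiv,
                           complexity = cx$score,
                           neg_in_bf = sample_links[, "neg_in_bf"],
                           bf_links = sample_links[, "bf_links"],
                           cluster12_richness =
                             predictors$cluster12_richness,
                           soil_properties = soil_pc1)
  linkage$partial <- partial_report(factor_set, mf$mf_avg)

  structure(list(design = design, data = data, mf = mf,
                 diversity = diversity, assembly = assembly,
                 network = list(graph = net, threshold = thr,
                                clusters = clusters, links = links,
                                cluster_richness = cl_rich,
                                merged_table = merged),
                 topology = list(profiles = profiles, complexity = cx,
                                 comparison = topo_cmp,
                                 sample_links = sample_links),
                 stability = stability, linkage = linkage),
            class = "mfnet_pipeline")
}

#' Treatment effect summary of a pipeline run
#'
#' Percent change of the key per-sample quantities in each non-control
#' treatment relative to the Control mean: the averaging
#' multifunctionality index, the four function-group scores, bacterial
#' and fungal richness, the complexity score is reported as a mean
#' difference (it is centered at 0, so a ratio is meaningless), and the
#' per-sample negative fraction of bacterial-fungal links likewise as a
#' difference.
#'
#' @param res An `mfnet_pipeline` result.
#' @return Data frame: quantity, treatment, control_mean,
#'   treatment_mean, change (percent for ratio-scale quantities,
#'   difference for centered ones), type.
#' @export
treatment_effects <- function(res) {
  trt <- res$design$treatment
  grab <- function(v) tapply(v, trt, mean)
  ratio_q <- list(mf_avg = res$mf$mf_avg,
                  nutrient_provisioning =
                    res$mf$group_scores[, "nutrient_provisioning"],
                  growth_efficiency =
                    res$mf$group_scores[, "growth_efficiency"],
                  LOM_decomposition =
                    res$mf$group_scores[, "LOM_decomposition"],
                  ROM_decomposition =
                    res$mf$group_scores[, "ROM_decomposition"],
                  richness_bacteria = res$diversity$richness_bacteria,
                  richness_fungi = res$diversity$richness_fungi)
  diff_q <- list(complexity = res$topology$complexity$score,
                 neg_in_bf = res$topology$sample_links[, "neg_in_bf"])
  rows <- list()
  for (nm in names(ratio_q)) {
    m <- grab(ratio_q[[nm]])
    for (tr in setdiff(levels(trt), "Control"))
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = nm, treatment = tr, control_mean = m[["Control"]],
        treatment_mean = m[[tr]],
        change = 100 * (m[[tr]] - m[["Control"]]) / m[["Control"]],
        type = "percent")
  }
  for (nm in names(diff_q)) {
    m <- grab(diff_q[[nm]])
    for (tr in setdiff(levels(trt), "Control"))
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = nm, treatment = tr, control_mean = m[["Control"]],
        treatment_mean = m[[tr]], change = m[[tr]] - m[["Control"]],
        type = "difference")
  }
  do.call(rbind, rows)
}

#' @export
print.mfnet_pipeline <- function(x, ...) {
  cat("mfnet pipeline run\n")
  cat(sprintf("  samples: %d; network: %d nodes / %d edges (|r| >= %.2f)\n",
              nrow(x$design), igraph::vcount(x$network$graph),
              igraph::ecount(x$network$graph),
              x$network$threshold$threshold))
  cat(sprintf("  modularity %.3f in %d clusters; neg %.3f, B-F %.3f, neg in B-F %.3f\n",
              x$network$clusters$modularity,
              length(unique(x$network$clusters$membership)),
              x$network$links$neg, x$network$links$bf_links,
              x$network$links$neg_in_bf))
  invisible(x)
}
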