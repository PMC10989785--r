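#' Extract a per-sample subnetwork
#'
#' Induced subgraph of the metacommunity network on the OTUs present
#' (count > 0) in one sample; edges are inherited, never re-inferred.
#'
#' @param net Metacommunity network from [build_network()].
#' @param present Character vector of OTU ids present in the sample.
#' @return An `igraph` object (possibly with zero vertices).
#' @export
extract_subnetwork <- function(net, present) {
  keep <- intersect(igraph::V(net)$name, present)
  igraph::induced_subgraph(net, keep)
}

#' Topological features of a network
#'
#' Number of nodes and edges, average degree `2E/N`, clustering
#' coefficient (mean local clustering, with degree < 2 nodes contributing
#' 0), average path length (mean shortest-path length over connected
#' pairs only, on the unsigned graph), graph density `2E/(N(N-1))`, and
#' mean normalized betweenness centrality. Edgeless or empty graphs give
#' the zero-connectivity limits (0 everywhere, path length `NA`).
#'
#' @param net An `igraph` object.
#' @return Named numeric vector of the seven features (`avg_path_length`
#'   is `NA` for graphs without a connected pair).
#' @export
topology_features <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  if (n == 0 || e == 0) {
    return(c(n_nodes = n, n_edges = 0, avg_degree = 0,
             clustering_coefficient = 0, avg_path_length = NA_real_,
             graph_density = 0, betweenness_centrality = 0))
  }
  u <- net  # topology on the unsigned, unweighted graph
  if ("weight" %in% igraph::edge_attr_names(u))
    u <- igraph::delete_edge_attr(u, "weight")
  cc <- igraph::transitivity(u, type = "local", isolates = "zero")
  apl <- igraph::mean_distance(u, directed = FALSE, unconnected = TRUE)
  btw <- igraph::betweenness(u, directed = FALSE, normalized = TRUE)
  c(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
    clustering_coefficient = mean(cc),
    avg_path_length = apl,
    graph_density = 2 * e / (n * (n - 1)),
    betweenness_centrality = mean(btw))
}

#' Per-sample topology profiles
#'
#' Runs [extract_subnetwork()] and [topology_features()] for every sample
#' of an OTU table against the metacommunity network.
#'
#' @param net Metacommunity network.
#' @param table [otu_table] or counts matrix over the same OTU ids.
#' @return Matrix samples x 7 features.
#' @export
topology_profiles <- function(net, table) {
  counts <- otu_counts(table)
  t(vapply(rownames(counts), function(s) {
    present <- colnames(counts)[counts[s, ] > 0]
    topology_features(extract_subnetwork(net, present))
  }, numeric(7)))
}

#' Network complexity index
#'
#' Collapses per-sample topology profiles into a single complexity score:
#' the average path length (a sparsity measure) is replaced by its
#' reciprocal (0 for graphs without connected pairs) so that every
#' feature increases with connectivity, features are z-scored (constant
#' features dropped with a warning), and the first axis of a Euclidean
#' PCoA — sign-oriented to correlate nonnegatively with average degree —
#' is the score.
#'
#' @param profiles Matrix samples x features from [topology_profiles()]
#'   (>= 3 samples).
#' @return List of class `complexity_score`: `score` (named per-sample
#'   vector), `features_used`, and `axes` (all PCoA axes).
#' @export
complexity_index <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3)
    stop("complexity_index() needs at least 3 samples")
  x <- profiles
  if ("avg_path_length" %in% colnames(x)) {
    apl <- x[, "avg_path_length"]
    inv <- ifelse(is.na(apl) | apl == 0, 0, 1 / apl)
    x[, "avg_path_length"] <- inv
    colnames(x)[colnames(x) == "avg_path_length"] <- "inv_path_length"
  }
  v <- apply(x, 2, stats::sd)
  if (any(v == 0)) {
    if (all(v == 0)) {
      warning("all features constant: complexity scores are all zero")
      return(structure(list(score = stats::setNames(rep(0, nrow(x)),
                                                    rownames(x)),
                            features_used = character(0), axes = NULL),
                       class = "complexity_score"))
    }
    warning("constant feature(s) dropped: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  z <- scale(x)
  ax <- pcoa_scores(z)
  ref <- if ("avg_degree" %in% colnames(profiles))
    profiles[, "avg_degree"] else rowMeans(z)
  score <- orient_axis(ax[, 1], ref)
  structure(list(score = score, features_used = colnames(x), axes = ax),
            class = "complexity_score")
}

#' Treatment comparison of topology features
#'
#' Kruskal-Wallis test per feature, with pairwise Dunn post-hoc z-tests
#' (Benjamini-Hochberg corrected) summarized as a compact letter display.
#'
#' @param profiles Matrix samples x features.
#' @param treatments Group labels (>= 2 groups, >= 3 samples each).
#' @param alpha Significance level for the letters (default 0.05).
#' @return List of class `topology_comparison`: `kw` (data frame of
#'   feature, chi-squared, p), `letters` (features x groups character
#'   matrix) and `pairwise` (per-feature BH-adjusted Dunn p matrices).
#' @export
compare_topology <- function(profiles, treatments, alpha = 0.05) {
  profiles <- as.matrix(profiles)
  g <- as.factor(treatments)
  if (nlevels(g) < 2 || any(table(g) < 3))
    stop("need >= 2 groups with >= 3 samples each")
  feats <- colnames(profiles)
  kw <- data.frame(feature = feats, chisq = NA_real_, p = NA_real_)
  letter_mat <- matrix("a", length(feats), nlevels(g),
                       dimnames = list(feats, levels(g)))
  pairwise <- vector("list", length(feats))
  names(pairwise) <- feats
  for (j in seq_along(feats)) {
    y <- profiles[, j]
    ok <- !is.na(y)
    if (stats::sd(y[ok]) == 0) {
      kw$p[j] <- 1
      pairwise[j] <- list(NULL)
      next
    }
    kt <- stats::kruskal.test(y[ok], g[ok])
    kw$chisq[j] <- unname(kt$statistic)
    kw$p[j] <- kt$p.value
    dp <- dunn_pairwise(y[ok], g[ok])
    pairwise[[j]] <- dp$p_adj
    letter_mat[j, ] <- cld_letters(dp$p_adj, dp$mean_rank, alpha)
  }
  structure(list(kw = kw, letters = letter_mat, pairwise = pairwise),
            class = "topology_comparison")
}

# Dunn's pairwise rank z-tests with tie correction; BH-adjusted.
dunn_pairwise <- function(y, g) {
  g <- droplevels(as.factor(g))
  r <- rank(y)
  N <- length(y)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ns <- table(g)
  lv <- levels(g)
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pr <- c()
  idx <- utils::combn(length(lv), 2)
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    z <- (mr[i] - mr[j]) / se
    pr[k] <- 2 * stats::pnorm(-abs(z))
  }
  pr <- stats::p.adjust(pr, "BH")
  for (k in seq_len(ncol(idx))) {
    pm[idx[1, k], idx[2, k]] <- pr[k]
    pm[idx[2, k], idx[1, k]] <- pr[k]
  }
  list(p_adj = pm, mean_rank = mr)
}
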