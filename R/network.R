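#' Occupancy filter and kingdom merge
#'
#' Retains OTUs with nonzero counts in at least `min_present` samples
#' (the guard against spurious correlations from rare OTUs) and merges
#' the bacterial and fungal tables into one kingdom-labelled table.
#'
#' @param bacteria,fungi [otu_table]s over the same samples.
#' @param min_present Minimum number of samples an OTU must occupy
#'   (default 9, i.e. half of an 18-sample design).
#' @return A merged, filtered [otu_table].
#' @export
occupancy_filter <- function(bacteria, fungi, min_present = 9) {
  merged <- merge_kingdoms(bacteria, fungi)
  keep <- colSums(merged$counts > 0) >= min_present
  if (!any(keep))
    stop("filter too strict: no OTU present in >= ", min_present,
         " samples")
  otu_subset(merged, keep)
}

#' OTU-OTU Pearson correlation matrix
#'
#' Computes pairwise Pearson correlations between OTUs over samples.
#' Counts are converted to within-sample relative abundances and
#' log10-transformed after adding the smallest nonzero relative abundance
#' as a pseudo-fraction (set `transform = "none"` to correlate raw
#' relative abundances). Zero-variance OTUs are excluded with a warning.
#'
#' @param table An [otu_table] or counts matrix with >= 4 samples.
#' @param transform `"log"` (default) or `"none"`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `"transform"` records the setting.
#' @export
correlation_matrix <- function(table, transform = c("log", "none")) {
  transform <- match.arg(transform)
  counts <- otu_counts(table)
  if (nrow(counts) < 4)
    stop("correlation_matrix() needs at least 4 samples")
  rel <- counts / rowSums(counts)
  x <- if (transform == "log") {
    pseudo <- min(rel[rel > 0])
    log10(rel + pseudo)
  } else rel
  v <- apply(x, 2, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance OTU(s) excluded")
    x <- x[, v > 0, drop = FALSE]
  }
  r <- stats::cor(x)
  diag(r) <- 1
  attr(r, "transform") <- transform
  r
}

# -- random-matrix-theory threshold selection ------------------------------

# Unfold a sorted eigenvalue spectrum: smooth the cumulative staircase
# (cubic smoothing spline through `n_points` grid evaluations) and map
# each eigenvalue through it, giving spacings with unit mean.
# Degenerate (repeated) eigenvalues carry no level-repulsion information
# and would flood the spacing distribution with exact zeros, so only
# distinct eigenvalues are unfolded.
unfold_spectrum <- function(ev, n_points = 51) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  if (length(ev) < 5) return(NULL)
  n <- length(ev)
  grid <- seq(ev[1], ev[n], length.out = n_points)
  stair <- vapply(grid, function(g) sum(ev <= g), numeric(1))
  fit <- tryCatch(stats::smooth.spline(grid, stair),
                  error = function(e) NULL)
  unf <- if (is.null(fit)) stats::approx(grid, stair, xout = ev,
                                         ties = "ordered")$y
         else stats::predict(fit, ev)$y
  sp <- diff(sort(unf))
  ms <- mean(sp)
  if (!is.finite(ms) || ms <= 0) return(NULL)
  sp / ms
}

# chi-squared goodness-of-fit p-value of unfolded spacings against a
# law: "poisson" exp(-d) or "goe" (Wigner surmise pi/2 d exp(-pi d^2/4));
# 20 bins over [0, 3], tail mass folded into the last bin.
nnsd_gof <- function(spacings, law = c("poisson", "goe"), n_bins = 20,
                     upper = 3) {
  law <- match.arg(law)
  br <- seq(0, upper, length.out = n_bins + 1)
  cdf <- switch(law,
                poisson = function(x) 1 - exp(-x),
                goe = function(x) 1 - exp(-pi * x^2 / 4))
  pr <- diff(cdf(br))
  pr[n_bins] <- pr[n_bins] + (1 - cdf(upper))  # open last bin
  idx <- pmin(pmax(findInterval(spacings, br, rightmost.closed = TRUE),
                   1L), n_bins)
  obs <- tabulate(idx, nbins = n_bins)
  n <- length(spacings)
  # merge bins with tiny expectation into neighbours for a usable chi^2
  exp_ct <- pr * n
  stat <- sum((obs - exp_ct)^2 / pmax(exp_ct, 0.5))
  p <- stats::pchisq(stat, df = n_bins - 1, lower.tail = FALSE)
  list(stat = stat, p = p)
}

#' Select a correlation threshold by random matrix theory
#'
#' Scans candidate thresholds `s` over `[s_min, s_max]`. At each `s` the
#' correlation matrix is restricted to OTUs retaining at least one
#' off-diagonal entry with `|r| >= s` (weaker entries zeroed, diagonal
#' kept), its eigenvalue spectrum is unfolded, and the nearest-neighbour
#' spacing distribution (NNSD) is tested against the Poisson law
#' `exp(-d)` (uncorrelated eigenvalues, the signature of real modular
#' structure) and the Gaussian orthogonal ensemble Wigner surmise (the
#' signature of random noise). The selected threshold is the smallest `s`
#' at which the NNSD fits Poisson (chi-squared p > 0.05) while GOE is
#' rejected (p <= 0.05).
#'
#' @param corr Symmetric correlation matrix.
#' @param s_min,s_max,step Candidate grid (defaults 0.30-0.95 by 0.025;
#'   a finer step locates the transition more reliably at extra cost).
#' @param min_nodes Minimum retained matrix size for a candidate to be
#'   testable (default 10).
#' @return List of class `rmt_threshold`: `threshold` and `diagnostics`
#'   (per-candidate data frame of retained size, spacing count and both
#'   p-values).
#' @export
rmt_threshold <- function(corr, s_min = 0.30, s_max = 0.95, step = 0.025,
                          min_nodes = 10) {
  if (!(s_min > 0 && s_min < s_max && s_max <= 1))
    stop("need 0 < s_min < s_max <= 1")
  cand <- seq(s_min, s_max, by = step)
  a <- abs(corr)
  diag(a) <- 0
  diag_rows <- vector("list", length(cand))
  chosen <- NA_real_
  for (k in seq_along(cand)) {
    s <- cand[k]
    keep <- which(apply(a >= s, 1, any))
    row <- data.frame(s = s, n_nodes = length(keep), n_spacings = NA,
                      p_poisson = NA, p_goe = NA)
    if (length(keep) >= min_nodes) {
      m <- corr[keep, keep, drop = FALSE]
      m[abs(m) < s] <- 0
      diag(m) <- 1
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      sp <- unfold_spectrum(ev)
      if (!is.null(sp) && length(sp) >= min_nodes - 1) {
        row$n_spacings <- length(sp)
        row$p_poisson <- nnsd_gof(sp, "poisson")$p
        row$p_goe <- nnsd_gof(sp, "goe")$p
      }
    }
    diag_rows[[k]] <- row
    if (!is.na(row$p_poisson) &&
        row$p_poisson > 0.05 && row$p_goe <= 0.05) {
      chosen <- s
      break  # smallest qualifying s; no need to scan further
    }
  }
  diagnostics <- do.call(rbind, diag_rows[!vapply(diag_rows, is.null,
                                                  logical(1))])
  if (is.na(chosen))
    stop("threshold not found: no candidate in [", s_min, ", ", s_max,
         "] shows a Poisson NNSD with GOE rejected; widen the range ",
         "or inspect the diagnostics")
  structure(list(threshold = chosen, diagnostics = diagnostics),
            class = "rmt_threshold")
}

#' Build the signed co-occurrence network
#'
#' Creates an undirected igraph with an edge for every OTU pair with
#' `|r| >= threshold`, edge attributes `r` (signed correlation), `weight`
#' (`|r|`) and `sign`; node attributes `kingdom` and `rel_abundance`
#' (mean relative abundance) when a table is supplied. Isolated nodes are
#' dropped.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param threshold Cutoff from [rmt_threshold()] or a user override.
#' @param table Optional [otu_table] supplying node annotations.
#' @return An `igraph` object.
#' @export
build_network <- function(corr, threshold, table = NULL) {
  a <- corr
  diag(a) <- 0
  a[abs(a) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(abs(a) > 0, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) stop("empty network: no pair reaches the threshold")
  r <- a[cbind(el[, 1], el[, 2])]
  igraph::E(g)$r <- r
  igraph::E(g)$weight <- abs(r)
  igraph::E(g)$sign <- ifelse(r > 0, "positive", "negative")
  if (!is.null(table)) {
    counts <- otu_counts(table)
    rel <- colMeans(counts / rowSums(counts))
    ids <- igraph::V(g)$name
    if (inherits(table, "otu_table"))
      igraph::V(g)$kingdom <- unname(table$kingdom[ids])
    igraph::V(g)$rel_abundance <- unname(rel[ids])
  }
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  attr(g, "threshold") <- threshold
  g
}

#' Greedy modularity clusters
#'
#' Agglomerative greedy modularity optimization on the unsigned graph
#' (`|r|` as edge weight). Clusters are relabelled in decreasing size
#' order (cluster 1 is the largest).
#'
#' @param net Network from [build_network()].
#' @return List of class `cluster_assignment`: `membership` (named
#'   integer vector) and `modularity`.
#' @export
greedy_modularity_clusters <- function(net) {
  if (igraph::vcount(net) == 0) stop("network is empty")
  cl <- igraph::cluster_fast_greedy(net,
                                    weights = igraph::E(net)$weight)
  memb <- igraph::membership(cl)
  # guard: the returned partition must be at least as good as the
  # trivial one-cluster partition (igraph can leave singletons on
  # degenerate graphs)
  q <- igraph::modularity(net, memb, weights = igraph::E(net)$weight)
  if (q < 0) {
    memb <- stats::setNames(rep(1L, igraph::vcount(net)),
                            igraph::V(net)$name)
  }
  sizes <- table(memb)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  memb2 <- relabel[as.character(memb)]
  names(memb2) <- igraph::V(net)$name
  structure(list(membership = memb2,
                 modularity = igraph::modularity(
                   net, memb, weights = igraph::E(net)$weight)),
            class = "cluster_assignment")
}

#' Link-type proportions
#'
#' @param net Network from [build_network()] with kingdom node labels.
#' @return List: `neg` (negative edges / all edges), `bf_links`
#'   (bacterial-fungal edges / all edges) and `neg_in_bf` (negative
#'   bacterial-fungal edges / bacterial-fungal edges; 0 with a warning
#'   when there are no inter-kingdom edges).
#' @export
link_type_proportions <- function(net) {
  ne <- igraph::ecount(net)
  if (ne == 0) return(list(neg = 0, bf_links = 0, neg_in_bf = 0))
  negative <- igraph::E(net)$sign == "negative"
  kd <- igraph::V(net)$kingdom
  if (is.null(kd)) stop("network nodes carry no kingdom labels")
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  bf <- kd[ends[, 1]] != kd[ends[, 2]]
  neg_in_bf <- if (!any(bf)) {
    warning("no inter-kingdom edges; neg_in_bf set to 0")
    0
  } else mean(negative[bf])
  list(neg = mean(negative), bf_links = mean(bf), neg_in_bf = neg_in_bf)
}

#' Per-sample richness within network clusters
#'
#' @param assignment A `cluster_assignment` from
#'   [greedy_modularity_clusters()].
#' @param table The [otu_table] the network was built from.
#' @return Matrix samples x clusters: number of that cluster's OTUs with
#'   nonzero abundance in the sample.
#' @export
cluster_richness <- function(assignment, table) {
  counts <- otu_counts(table)
  memb <- assignment$membership
  ids <- intersect(names(memb), colnames(counts))
  cl <- sort(unique(memb))
  out <- sapply(cl, function(k) {
    members <- ids[memb[ids] == k]
    rowSums(counts[, members, drop = FALSE] > 0)
  })
  colnames(out) <- paste0("cluster", cl)
  out
}
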