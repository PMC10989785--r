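#' Network robustness under node removal
#'
#' Removes `floor(f * N)` nodes — uniformly at random or by descending
#' degree (`targeted_hub`) — then iteratively deletes nodes left without
#' any edge (the extinction cascade: an OTU losing all its associations
#' is assumed lost). Robustness is the surviving fraction of the initial
#' nodes, averaged over `reps` Monte-Carlo replicates for random removal
#' (targeted removal is deterministic and run once).
#'
#' @param net An `igraph` network.
#' @param f Fraction of nodes to remove, in (0, 1).
#' @param mode `"random"` or `"targeted_hub"`.
#' @param reps Monte-Carlo replicates (>= 100 for random mode).
#' @param seed Integer seed.
#' @return List: `robustness` (mean surviving fraction), `sd`
#'   (Monte-Carlo SD; 0 for targeted), `f`, `mode`, `reps`.
#' @export
robustness <- function(net, f = 0.5, mode = c("random", "targeted_hub"),
                       reps = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (f <= 0 || f >= 1) stop("f must lie in (0, 1)")
  n <- igraph::vcount(net)
  n_rm <- floor(f * n)
  if (n_rm < 1) {
    warning("f * N < 1: nothing removed")
    return(list(robustness = 1, sd = 0, f = f, mode = mode, reps = 0))
  }
  if (mode == "random" && reps < 100)
    stop("random mode needs reps >= 100")
  surviving <- function(remove_idx) {
    g <- igraph::delete_vertices(net, remove_idx)
    repeat {
      iso <- which(igraph::degree(g) == 0)
      if (length(iso) == 0) break
      g <- igraph::delete_vertices(g, iso)
    }
    igraph::vcount(g) / n
  }
  if (mode == "targeted_hub") {
    ord <- order(igraph::degree(net), decreasing = TRUE)
    val <- surviving(ord[seq_len(n_rm)])
    list(robustness = val, sd = 0, f = f, mode = mode, reps = 1)
  } else {
    vals <- with_seed(seed, vapply(seq_len(reps), function(i)
      surviving(sample.int(n, n_rm)), numeric(1)))
    list(robustness = mean(vals), sd = stats::sd(vals), f = f,
         mode = mode, reps = reps)
  }
}

# global efficiency: mean over ordered pairs of 1/d_ij, 0 for
# unreachable pairs; in [0, 1], equal to 1 iff the graph is complete.
global_efficiency <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) return(0)
  d <- igraph::distances(net, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' `V = max_i (E - E_i) / E`, where `E` is the global efficiency (mean
#' inverse shortest-path length over ordered pairs, unreachable pairs
#' contributing 0) and `E_i` the efficiency after deleting node `i`: the
#' worst-case relative efficiency loss from a single extinction.
#'
#' @param net An `igraph` network.
#' @return Scalar in `[0, 1]` (0 with a warning for graphs with < 2
#'   nodes).
#' @export
vulnerability <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) {
    warning("vulnerability of a single-node graph is 0")
    return(0)
  }
  E <- global_efficiency(net)
  if (E == 0) return(0)
  drops <- vapply(seq_len(n), function(i)
    (E - global_efficiency(igraph::delete_vertices(net, i))) / E,
    numeric(1))
  max(drops)
}

#' Relative modularity
#'
#' `(M_obs - mean(M_rand)) / mean(M_rand)`, where `M_obs` is the greedy
#' modularity of the observed network and `M_rand` the greedy modularity
#' of Erdos-Renyi graphs with identical node and edge counts: how much
#' more modular the network is than a size-matched random graph.
#'
#' @param net An `igraph` network.
#' @param n_random Size of the random ensemble (>= 100).
#' @param seed Integer seed.
#' @return List: `relative_modularity`, `m_obs`, `m_rand_mean`,
#'   `m_rand_sd`, `n_random`, and `degenerate` (TRUE when the random
#'   baseline is ~0 and the ratio is unreliable).
#' @export
relative_modularity <- function(net, n_random = 100, seed = 1) {
  if (n_random < 100) stop("n_random must be at least 100")
  m_obs <- greedy_modularity_clusters(net)$modularity
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  m_rand <- with_seed(seed, vapply(seq_len(n_random), function(i) {
    g <- igraph::sample_gnm(n, e)
    igraph::modularity(igraph::cluster_fast_greedy(g))
  }, numeric(1)))
  mu <- mean(m_rand)
  degenerate <- abs(mu) < 1e-6
  list(relative_modularity = if (degenerate) NA_real_
       else (m_obs - mu) / mu,
       m_obs = m_obs, m_rand_mean = mu, m_rand_sd = stats::sd(m_rand),
       n_random = n_random, degenerate = degenerate)
}

#' Kolmogorov-Smirnov comparison of node attributes
#'
#' Two-sample K-S test between the node-attribute distributions (degree,
#' normalized betweenness, or local clustering) of two networks.
#'
#' @param net_a,net_b Nonempty `igraph` networks.
#' @param attribute One of `"degree"`, `"betweenness"`, `"clustering"`.
#' @return List: `D`, `p`, `attribute`.
#' @export
ks_node_features <- function(net_a, net_b,
                             attribute = c("degree", "betweenness",
                                           "clustering")) {
  attribute <- match.arg(attribute)
  if (igraph::vcount(net_a) == 0 || igraph::vcount(net_b) == 0)
    stop("both networks must be nonempty")
  grab <- function(g) switch(attribute,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE,
                                      normalized = TRUE, weights = NA),
    clustering = igraph::transitivity(g, type = "local",
                                      isolates = "zero"))
  a <- grab(net_a); b <- grab(net_b)
  if (length(unique(c(a, b))) == 1L)
    return(list(D = 0, p = 1, attribute = attribute))
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value, attribute = attribute)
}
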