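test_that("occupancy filter keeps OTUs present in enough samples", {
  tt <- toy_tables()
  # prevalences are 18, 10, 9 (bacteria) and 8, 1 (fungi)
  merged <- occupancy_filter(tt$bacteria, tt$fungi, min_present = 9)
  expect_equal(sort(colnames(merged$counts)), c("B1", "B2", "B3"))
  all_kept <- occupancy_filter(tt$bacteria, tt$fungi, min_present = 0)
  expect_equal(ncol(all_kept$counts), 5)
  expect_error(occupancy_filter(tt$bacteria, tt$fungi, min_present = 19),
               "filter too strict")
})

test_that("correlation matrix reproduces exact correlations", {
  # equal row totals so relative abundances are proportional to counts
  x <- c(1, 5, 3, 8, 2, 6, 4, 7)
  counts <- cbind(A = x, B = x, C = 10 - x, D = rep(3, 8))
  counts <- cbind(counts, E = 40 - rowSums(counts))  # pad to equal totals
  rownames(counts) <- paste0("S", 1:8)
  expect_warning(r <- correlation_matrix(counts, transform = "none"),
                 "zero-variance")
  expect_equal(unname(r["A", "B"]), 1)
  expect_equal(unname(r["A", "C"]), -1)
  expect_false("D" %in% rownames(r))
  expect_equal(unname(diag(r)), rep(1, nrow(r)))
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_error(correlation_matrix(counts[1:3, ]), "at least 4")
})

test_that("null-data correlations follow the Pearson null law", {
  set.seed(5)
  n <- 18
  # near-constant baseline + small noise: compositional closure negligible
  counts <- matrix(1e6 + round(1000 * stats::rnorm(n * 40)), n, 40)
  colnames(counts) <- paste0("O", 1:40)
  rownames(counts) <- paste0("S", 1:n)
  r <- correlation_matrix(counts, transform = "none")
  rv <- abs(r[upper.tri(r)])
  null_cdf <- function(x) stats::pbeta(x^2, 0.5, (n - 2) / 2)
  ks <- suppressWarnings(stats::ks.test(rv, null_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("RMT threshold separates planted blocks from noise", {
  # block-diagonal: within-block ~0.9, between 0 -> a threshold below 0.9
  # is selected and the graph's components are exactly the blocks (the
  # jitter keeps the eigenvalues distinct so spacings exist)
  set.seed(14)
  blocks <- rep(1:3, each = 8)
  r <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0))
  jit <- matrix(stats::runif(24 * 24, -0.04, 0.04), 24, 24)
  r <- r + (jit + t(jit)) / 2 * (r > 0)
  diag(r) <- 1
  dimnames(r) <- list(paste0("O", 1:24), paste0("O", 1:24))
  thr <- rmt_threshold(r, s_min = 0.3, s_max = 0.95, step = 0.05)
  expect_lt(thr$threshold, 0.9)
  g <- build_network(r, thr$threshold)
  comp <- igraph::components(g)$membership
  expect_equal(ari(comp, blocks[match(names(comp), paste0("O", 1:24))]), 1)

  # candidate grid arithmetic
  expect_equal(length(seq(0.30, 0.95, by = 0.05)), 14)

  # pure noise: a transition threshold exists (property, not a value)
  set.seed(21)
  noise <- matrix(stats::rnorm(18 * 150), 18, 150,
                  dimnames = list(paste0("S", 1:18), paste0("O", 1:150)))
  rn <- stats::cor(noise)
  thr2 <- rmt_threshold(rn)
  expect_true(thr2$threshold > 0.3 && thr2$threshold <= 0.95)
  expect_true(is.data.frame(thr2$diagnostics))
  expect_error(rmt_threshold(rn, s_min = 0.5, s_max = 0.4), "s_min")
})

test_that("network building respects the threshold and nests monotonically", {
  expect_error(build_network(diag(5), 0.5), "empty network")
  set.seed(8)
  x <- matrix(stats::rnorm(10 * 30), 10, 30,
              dimnames = list(NULL, paste0("O", 1:30)))
  r <- stats::cor(x)
  g_all <- build_network(r, 1e-9)
  expect_equal(igraph::ecount(g_all), choose(30, 2))  # complete graph
  edges_at <- function(s) {
    g <- tryCatch(build_network(r, s), error = function(e) NULL)
    if (is.null(g)) character(0) else
      apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
  }
  e1 <- edges_at(0.3); e2 <- edges_at(0.5); e3 <- edges_at(0.7)
  expect_true(all(e2 %in% e1))
  expect_true(all(e3 %in% e2))
  # every retained edge honors |r| >= threshold
  g <- build_network(r, 0.5)
  expect_true(all(abs(igraph::E(g)$r) >= 0.5))
})

test_that("greedy clusters recover obvious structure", {
  cl <- greedy_modularity_clusters(g_two_cliques)
  expect_equal(length(unique(cl$membership)), 2)
  expect_equal(unname(cl$membership[1:5]), rep(cl$membership[[1]], 5))
  # cluster 1 is the larger clique
  expect_equal(sum(cl$membership == 1), 6)

  single <- igraph::make_graph(~ a - b)
  cs <- greedy_modularity_clusters(single)
  expect_equal(length(unique(cs$membership)), 1)
  expect_equal(cs$modularity, 0)

  # partition must beat the trivial single-cluster partition
  expect_gte(cl$modularity,
             igraph::modularity(g_two_cliques,
                                rep(1, igraph::vcount(g_two_cliques))))
})

test_that("link proportions count signs and kingdoms correctly", {
  g <- igraph::make_graph(~ b1 - f1, b1 - b2, b2 - f2, f1 - f2)
  igraph::V(g)$kingdom <- c("bacteria", "fungi", "bacteria", "fungi")
  igraph::E(g)$sign <- c("negative", "positive", "positive", "positive")
  # edges: b1-f1 (BF, neg), b1-b2 (BB, pos), b2-f2 (BF, pos), f1-f2 (FF, pos)
  lp <- link_type_proportions(g)
  expect_equal(lp$neg, 0.25)
  expect_equal(lp$bf_links, 0.5)
  expect_equal(lp$neg_in_bf, 0.5)

  # flipping every sign maps neg -> 1 - neg
  g2 <- g
  igraph::E(g2)$sign <- ifelse(igraph::E(g)$sign == "negative",
                               "positive", "negative")
  expect_equal(link_type_proportions(g2)$neg, 0.75)

  # single-kingdom all-positive network
  g3 <- igraph::make_graph(~ a - b, b - c)
  igraph::V(g3)$kingdom <- "bacteria"
  igraph::E(g3)$sign <- "positive"
  expect_warning(lp3 <- link_type_proportions(g3), "no inter-kingdom")
  expect_equal(unlist(lp3), c(neg = 0, bf_links = 0, neg_in_bf = 0))
})

test_that("cluster richness counts cluster members present per sample", {
  counts <- rbind(S1 = c(A = 1L, B = 2L, C = 0L, D = 1L),
                  S2 = c(A = 0L, B = 0L, C = 0L, D = 5L),
                  S3 = c(A = 1L, B = 1L, C = 1L, D = 1L))
  assign <- structure(list(membership = c(A = 1, B = 1, C = 2, D = 2),
                           modularity = 0.1), class = "cluster_assignment")
  cr <- cluster_richness(assign, counts)
  expect_equal(unname(cr["S1", ]), c(2, 1))
  expect_equal(unname(cr["S2", ]), c(0, 1))
  # row sums never exceed sample richness over networked OTUs
  expect_true(all(rowSums(cr) <= richness(counts)))
})

test_that("the full chain recovers planted blocks across kingdoms", {
  d <- generate_design(6)
  aris <- vapply(1:5, function(sd) {
    cfg <- sim_config(seed = sd, richness_effects = null_richness_effects,
                      n_competitive_pairs = 0)
    tabs <- generate_otu_tables(d, cfg)
    merged <- occupancy_filter(tabs$bacteria, tabs$fungi, 9)
    corr <- correlation_matrix(merged)
    thr <- rmt_threshold(corr)
    net <- build_network(corr, thr$threshold, merged)
    cl <- greedy_modularity_clusters(net)
    bl <- tabs$blocks
    common <- intersect(names(cl$membership), names(bl)[bl > 0])
    ari(cl$membership[common], bl[common])
  }, numeric(1))
  expect_true(all(aris > 0.9))
})
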