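# Shared fixtures and small independent oracles used across test files.

# adjusted Rand index between two labelings (independent of igraph)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

null_richness_effects <- list(DP = c(bacteria = 0, fungi = 0),
                              Control = c(bacteria = 0, fungi = 0),
                              IP = c(bacteria = 0, fungi = 0))

null_function_effects <- local({
  z <- c(nutrient_provisioning = 0, growth_efficiency = 0,
         LOM_decomposition = 0, ROM_decomposition = 0)
  list(DP = z, Control = z, IP = z)
})

# small test graphs
g_triangle <- igraph::make_full_graph(3)
g_path3 <- igraph::make_graph(~ a - b, b - c)
g_star5 <- igraph::make_star(6, mode = "undirected")  # 5 leaves + center
g_k20 <- igraph::make_full_graph(20)
g_two_cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                        igraph::make_full_graph(6))

# a small otu_table pair with known prevalence pattern
toy_tables <- function() {
  counts_b <- matrix(0L, 18, 3,
                     dimnames = list(paste0("S", 1:18),
                                     c("B1", "B2", "B3")))
  counts_b[1:18, 1] <- 5L       # prevalence 18
  counts_b[1:10, 2] <- 3L       # prevalence 10
  counts_b[1:9, 3] <- 2L        # prevalence 9
  counts_f <- matrix(0L, 18, 2,
                     dimnames = list(paste0("S", 1:18), c("F1", "F2")))
  counts_f[1:8, 1] <- 4L        # prevalence 8
  counts_f[1, 2] <- 1L          # prevalence 1
  list(bacteria = otu_table(counts_b, "bacteria"),
       fungi = otu_table(counts_f, "fungi"))
}
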