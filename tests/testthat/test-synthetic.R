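test_that("study design is balanced, deterministic, and validated", {
  d <- generate_design(6)
  expect_equal(nrow(d), 18)
  expect_equal(as.vector(table(d$treatment)), rep(6L, 3))
  expect_equal(anyDuplicated(d$sample_id), 0L)
  expect_equal(generate_design(6), d)  # no RNG involved
  expect_equal(nrow(generate_design(2)), 6)
  expect_error(generate_design(1), "invalid design")
})

test_that("identical seeds give bit-identical tables; global RNG untouched", {
  d <- generate_design(3)
  cfg <- sim_config(n_bacteria = 60, n_fungi = 30, depth = 2000, seed = 5)
  set.seed(123)
  before <- .Random.seed
  t1 <- generate_otu_tables(d, cfg)
  expect_identical(.Random.seed, before)
  t2 <- generate_otu_tables(d, cfg)
  expect_identical(t1$bacteria$counts, t2$bacteria$counts)
  expect_identical(t1$fungi$counts, t2$fungi$counts)
  t3 <- generate_otu_tables(d, sim_config(n_bacteria = 60, n_fungi = 30,
                                          depth = 2000, seed = 6))
  expect_false(identical(t1$bacteria$counts, t3$bacteria$counts))
})

test_that("count tables are nonnegative integers with fixed row sums", {
  d <- generate_design(6)
  tabs <- generate_otu_tables(d, sim_config(seed = 2))
  for (tab in list(tabs$bacteria, tabs$fungi)) {
    expect_true(all(tab$counts >= 0))
    expect_true(all(tab$counts == round(tab$counts)))
    expect_equal(unname(rowSums(tab$counts)), rep(10000, 18))
  }
})

test_that("null richness effects leave no systematic treatment differences", {
  d <- generate_design(6)
  pvals <- sapply(1:40, function(sd) {
    tabs <- generate_otu_tables(d, sim_config(
      n_bacteria = 120, n_fungi = 60, depth = 4000,
      richness_effects = null_richness_effects, seed = sd))
    c(stats::kruskal.test(richness(tabs$bacteria), d$treatment)$p.value,
      stats::kruskal.test(richness(tabs$fungi), d$treatment)$p.value)
  })
  # type-I error near nominal: a few rejections are expected, not many
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("planted richness effects hit their targets", {
  d <- generate_design(6)
  ratios <- sapply(1:20, function(sd) {
    tabs <- generate_otu_tables(d, sim_config(
      richness_effects = list(DP = c(bacteria = -0.08, fungi = -0.21),
                              Control = c(bacteria = 0, fungi = 0),
                              IP = c(bacteria = 0, fungi = 0)),
      seed = sd))
    rb <- tapply(richness(tabs$bacteria), d$treatment, mean)
    rf <- tapply(richness(tabs$fungi), d$treatment, mean)
    c(rb[["DP"]] / rb[["Control"]], rf[["DP"]] / rf[["Control"]])
  })
  expect_lt(abs(mean(ratios[1, ]) - 0.92), 0.05)
  expect_lt(abs(mean(ratios[2, ]) - 0.79), 0.05)
})

test_that("latent abundances carry the planted correlation blocks", {
  d <- generate_design(6)
  tabs <- generate_otu_tables(d, sim_config(
    n_blocks = 4, richness_effects = null_richness_effects, seed = 9))
  lat <- tabs$latent
  bl <- tabs$blocks
  members <- names(bl)[bl > 0]
  cmat <- abs(stats::cor(lat[, members]))
  same <- outer(bl[members], bl[members], `==`)
  diag(same) <- NA
  within <- cmat[same & upper.tri(cmat)]
  between <- cmat[!same & upper.tri(cmat)]
  expect_gt(stats::median(within) - stats::median(between), 0.3)
})

test_that("excessive richness effects raise a degenerate-simulation error", {
  d <- generate_design(3)
  expect_error(
    generate_otu_tables(d, sim_config(
      n_bacteria = 20, n_fungi = 20, n_blocks = 1, block_size = 4,
      richness_effects = list(DP = c(bacteria = -0.95, fungi = 0),
                              Control = c(bacteria = 0, fungi = 0),
                              IP = c(bacteria = 0, fungi = 0)),
      seed = 1)),
    "degenerate")
})

test_that("function matrix has 17 functions in 4 groups with planted effects", {
  d <- generate_design(6)
  fns <- generate_functions(d, sim_config(seed = 3))
  expect_equal(ncol(fns$functions), 17)
  expect_equal(length(unique(fns$groups)), 4)
  expect_equal(as.vector(table(fns$groups)[c("nutrient_provisioning",
                                             "growth_efficiency",
                                             "LOM_decomposition",
                                             "ROM_decomposition")]),
               c(5L, 5L, 5L, 2L))
  expect_equal(nrow(fns$soil), 18)

  # +0.39 sd ROM effect under DP shows up in nearly every seed at noise 0.2
  eff <- list(DP = c(nutrient_provisioning = 0, growth_efficiency = 0,
                     LOM_decomposition = 0, ROM_decomposition = 0.39),
              Control = null_function_effects$Control,
              IP = null_function_effects$IP)
  hits <- sapply(1:100, function(sd) {
    f <- generate_functions(d, sim_config(function_effects = eff,
                                          noise_sd = 0.2, seed = sd))
    std <- apply(f$functions, 2, minmax_standardize)
    rom <- rowMeans(std[, f$groups == "ROM_decomposition"])
    mean(rom[d$treatment == "DP"]) > mean(rom[d$treatment == "Control"])
  })
  expect_gte(mean(hits), 0.95)

  # null effects: no group shows a systematic treatment shift
  pv <- sapply(1:30, function(sd) {
    f <- generate_functions(d, sim_config(
      function_effects = null_function_effects, seed = sd))
    std <- apply(f$functions, 2, minmax_standardize)
    stats::kruskal.test(rowMeans(std), d$treatment)$p.value
  })
  expect_lt(mean(pv < 0.05), 0.2)
})

test_that("neutral sampler matches the Sloan occurrence prediction", {
  expect_error(sample_neutral_community(c(0.5, 0.5), 100, m = 0, 5),
               "parameter error")
  expect_error(sample_neutral_community(c(0.5, 0.5), 100, m = 1.2, 5),
               "parameter error")
  expect_error(sample_neutral_community(c(0.5, 0.6), 100, 0.5, 5),
               "sum to 1")

  # zero metacommunity abundance: taxon absent everywhere
  tab <- sample_neutral_community(c(0.7, 0.3, 0), 500, 0.5, 20, seed = 1)
  expect_equal(sum(tab$counts[, 3]), 0)

  # m = 1, p = 0.5: occurrence ~ 1 - pbeta(1/N, N p, N (1-p))
  N <- 10000
  p <- c(0.5, 0.5)
  tab <- sample_neutral_community(p, N, 1, 400, seed = 2)
  obs <- mean(tab$counts[, 1] > 0)
  pred <- 1 - stats::pbeta(1 / N, N * 0.5, N * 0.5)
  se <- sqrt(pred * (1 - pred) / 400) + 1e-3
  expect_lt(abs(obs - pred), 4 * se)
})

test_that("OTU tables round-trip through TSV", {
  d <- generate_design(2)
  tabs <- generate_otu_tables(d, sim_config(n_bacteria = 25, n_fungi = 10,
                                            depth = 500, n_blocks = 1,
                                            block_size = 6, seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tabs$bacteria, path)
  back <- read_otu_table(path)
  expect_equal(back$counts, tabs$bacteria$counts)
  expect_equal(back$kingdom, tabs$bacteria$kingdom)
})
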