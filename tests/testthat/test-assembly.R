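test_that("rarefaction preserves support and matches expectations", {
  m <- matrix(c(10L, 0L, 5L, 20L, 0L, 30L), 2, 3, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  # full-depth draw leaves the sample unchanged
  r <- suppressWarnings(rarefy(m, 15, seed = 1))
  expect_equal(r[1, ], m[1, ])
  # single-OTU sample keeps all reads in that OTU
  one <- matrix(c(50L, 0L), 1, 2, dimnames = list("S1", c("A", "B")))
  expect_equal(unname(suppressWarnings(rarefy(one, 10, seed = 2))[1, ]),
               c(10L, 0L))
  expect_error(rarefy(m, 100), "depth error")

  # hypergeometric expectation: [5,5] rarefied to 2 -> mean A-count 1
  pair <- matrix(c(5L, 5L), 1, 2, dimnames = list("S", c("A", "B")))
  draws <- suppressWarnings(  # vegan flags the toy's count scale
    vapply(1:10000, function(sd) rarefy(pair, 2, seed = sd)[1, 1],
           numeric(1)))
  se <- sqrt(stats::var(draws) / length(draws))
  expect_lt(abs(mean(draws) - 1), 3 * se + 1e-3)
})

test_that("richness counts nonzero OTUs per sample", {
  m <- rbind(S1 = c(0L, 0L, 0L), S2 = c(1L, 0L, 2L), S3 = c(1L, 1L, 1L))
  colnames(m) <- c("A", "B", "C")
  expect_equal(unname(richness(m)), c(0, 2, 3))
  # identity-like table: one private OTU per sample
  expect_equal(unname(richness(diag(5L))), rep(1, 5))
})

test_that("combined biodiversity averages standardized kingdom richness", {
  b <- c(10, 20, 30)
  f <- c(300, 200, 100)
  out <- combined_biodiversity(b, f)
  expect_equal(out, c(0.5, 0.5, 0.5))  # opposite extremes cancel
  expect_equal(combined_biodiversity(b, b), c(0, 0.5, 1))
  # permutation equivariance
  perm <- c(3, 1, 2)
  expect_equal(combined_biodiversity(b[perm], f[perm]), out[perm])
  expect_error(combined_biodiversity(b, f[1:2]), "same samples")
})

test_that("Levins' niche breadth matches closed forms and is scale-free", {
  m <- matrix(0L, 18, 3, dimnames = list(paste0("S", 1:18),
                                         c("U", "S1", "H")))
  m[, "U"] <- 4L                 # uniform over 18 samples
  m[3, "S1"] <- 7L               # present in exactly one sample
  m[1:2, "H"] <- c(5L, 5L)       # proportions (0.5, 0.5, 0, ...)
  nb <- levins_niche_breadth(m, min_occurrence = 1)
  expect_equal(unname(nb$B["U"]), 18)
  expect_equal(unname(nb$B["S1"]), 1)
  expect_equal(unname(nb$B["H"]), 2)
  expect_true(all(nb$B >= 1 & nb$B <= 18))

  m2 <- m
  m2[, "H"] <- m2[, "H"] * 13L
  nb2 <- levins_niche_breadth(m2, min_occurrence = 1)
  expect_equal(nb2$B["H"], nb$B["H"])

  m3 <- cbind(m, Z = 0L)
  expect_warning(nb3 <- levins_niche_breadth(m3, 1), "zero total")
  expect_equal(sort(names(nb3$B)), sort(names(nb$B)))
})

test_that("NST is 0 for homogenized samples, 1 under its own null, in [0,1]", {
  # three identical samples plus one divergent one: the regional pool is
  # wider than any sample, so the null has room to vary (E > 0) and the
  # identical pairs' D = 0 is a maximal deterministic departure
  inc <- matrix(0L, 4, 50, dimnames = list(paste0("S", 1:4), NULL))
  inc[1:3, 1:20] <- 1L
  inc[4, 31:50] <- 1L
  r <- nst(inc, rep("g", 4), n_null = 100, seed = 1)
  pw <- r$pairwise$g
  expect_true(all(pw$E > 0))
  expect_equal(pw$stochasticity[pw$D == 0], rep(0, 3))

  # data generated by the null process itself: NST near 1
  tab <- sample_filtered_community(w = 0, n_taxa = 250, richness = 150,
                                   n_samples = 18, seed = 3)
  r2 <- nst(tab, rep("g", 18), n_null = 500, seed = 4)
  expect_lt(abs(r2$nst[["g"]] - 1), 0.12)
  expect_true(all(r2$nst >= 0 & r2$nst <= 1))

  expect_error(nst(inc, rep(c("a", "b"), 2), 100), "insufficient")
  expect_error(nst(inc, rep("g", 4), n_null = 10), "at least 100")
})

test_that("NST falls monotonically along a filtering gradient", {
  vals <- sapply(c(0, 0.35, 0.7, 0.95), function(w) {
    tab <- sample_filtered_community(w, n_taxa = 250, richness = 150,
                                     n_samples = 12, seed = 11)
    nst(tab, rep("g", 12), n_null = 300, seed = 5)$nst[["g"]]
  })
  expect_true(all(diff(vals) < 0.02))   # non-increasing up to MC noise
  expect_lt(vals[4], 0.5)               # strong filtering
  expect_gt(vals[1], 0.85)              # w = 0: the null itself

  # fully deterministic identical samples collapse the occupancy support,
  # so the plug-in null reproduces them and the ratio returns 1
  tab1 <- sample_filtered_community(1, 250, 150, 6, seed = 2)
  expect_equal(nst(tab1, rep("g", 6), 100, 3)$nst[["g"]], 1)
})

test_that("Sloan NCM fit recovers the migration rate of neutral data", {
  set.seed(99)
  lp <- exp(stats::rnorm(300, 0, 1.5))
  p <- lp / sum(lp)
  for (m_true in c(0.05, 0.3)) {
    errs <- vapply(1:6, function(sd) {
      fit <- sloan_ncm_fit(sample_neutral_community(p, 5000, m_true, 25,
                                                    seed = sd))
      abs(fit$m - m_true) / m_true
    }, numeric(1))
    expect_lt(stats::median(errs), 0.2)
  }
  # doubling depth: recovered m stable
  f1 <- sloan_ncm_fit(sample_neutral_community(p, 5000, 0.1, 25, seed = 1))
  f2 <- sloan_ncm_fit(sample_neutral_community(p, 10000, 0.1, 25, seed = 1))
  expect_lt(abs(f1$m - f2$m) / f1$m, 0.3)
  expect_equal(f2$N, 10000)
  expect_equal(f2$detection_limit, 1e-4)
})

test_that("saturated tables are flagged and errors are informative", {
  m <- matrix(100L, 6, 12,
              dimnames = list(paste0("S", 1:6), paste0("O", 1:12)))
  m <- m + matrix(sample(0:3, 72, TRUE), 6, 12)
  fit <- sloan_ncm_fit(m)
  expect_true(fit$saturated)
  expect_error(sloan_ncm_fit(m[, 1:3]), ">= 10 OTUs")
})
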