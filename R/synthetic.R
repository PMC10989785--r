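#' Balanced precipitation-manipulation study design
#'
#' Builds the sample metadata for a three-treatment precipitation
#' manipulation (DP = 50% decrease, Control = ambient, IP = 50% increase)
#' with `n_reps` biological replicates per treatment.
#'
#' @param n_reps Replicates per treatment (>= 2; the field design used 6,
#'   giving 18 samples).
#' @return A data.frame with columns `sample_id`, `treatment` (factor with
#'   levels DP, Control, IP) and `replicate`.
#' @examples
#' generate_design(6)
#' @export
generate_design <- function(n_reps = 6) {
  if (!is.numeric(n_reps) || n_reps < 2)
    stop("invalid design: at least 2 replicates per treatment are required")
  n_reps <- as.integer(n_reps)
  trt <- factor(rep(c("DP", "Control", "IP"), each = n_reps),
                levels = c("DP", "Control", "IP"))
  rep_id <- rep(seq_len(n_reps), times = 3)
  data.frame(sample_id = paste0(as.character(trt), rep_id),
             treatment = trt, replicate = rep_id,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic community generator
#'
#' Bundles every tunable of [generate_otu_tables()] and
#' [generate_functions()]. Defaults encode the study conditions the
#' generator emulates: two-kingdom OTU tables for 18 samples with
#' richness shifts of -7.9% (bacteria) and -20.9% (fungi) under DP and
#' +5.3% (fungi) under IP; four planted cross-kingdom correlation blocks;
#' a higher fraction of negatively associated pairs under DP; and 17 soil
#' functions in four groups with DP suppressing nutrient provisioning,
#' growth efficiency and LOM decomposition while elevating ROM
#' decomposition, and IP elevating growth efficiency only.
#'
#' @param n_bacteria,n_fungi OTU pool sizes per kingdom.
#' @param depth Target reads per sample and kingdom (fixed-depth
#'   multinomial sampling: row sums equal `depth` exactly).
#' @param base_presence Fraction of the OTU pool present (non-structural
#'   zero) under Control.
#' @param richness_effects Named list `treatment -> c(bacteria=, fungi=)`
#'   of fractional richness changes relative to Control.
#' @param function_effects Named list `treatment -> c(group = effect)` of
#'   standardized (per-noise-sd-free) mean shifts for the four function
#'   groups.
#' @param n_blocks Number of planted correlation blocks.
#' @param block_size OTUs per block.
#' @param block_cross_kingdom_fraction Fraction of each block's members
#'   drawn from the fungal pool.
#' @param block_rho Latent within-block correlation (absolute value).
#' @param n_competitive_pairs Number of obligate competitive
#'   bacterium-fungus pairs: always-present, abundant pairs with a
#'   strongly anti-correlated latent (0.995), guaranteeing negative
#'   inter-kingdom edges in every sample's subnetwork.
#' @param negative_edge_fraction Named vector `treatment -> target
#'   fraction` of negatively associated within-block pairs. The largest
#'   value fixes the mixed blocks' loading-sign mixture; when targets
#'   differ across treatments, an extra all-positive "mesic"
#'   (drought-sensitive) cross-kingdom block is planted whose members
#'   are structurally absent under the high-target treatments, so its
#'   positive bacterial-fungal edges dilute the negative fraction only
#'   where it is present. A directional, approximately calibrated
#'   control of the planted edge composition.
#' @param noise_sd Residual standard deviation of the function
#'   measurements, on the standardized scale.
#' @param log_sd Standard deviation of baseline log abundances.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_bacteria = 300, n_fungi = 150, depth = 10000,
                       base_presence = 0.9,
                       richness_effects = list(
                         DP = c(bacteria = -0.079, fungi = -0.209),
                         Control = c(bacteria = 0, fungi = 0),
                         IP = c(bacteria = 0, fungi = 0.053)),
                       function_effects = list(
                         DP = c(nutrient_provisioning = -0.8,
                                growth_efficiency = -0.8,
                                LOM_decomposition = -0.8,
                                ROM_decomposition = 0.8),
                         Control = c(nutrient_provisioning = 0,
                                     growth_efficiency = 0,
                                     LOM_decomposition = 0,
                                     ROM_decomposition = 0),
                         IP = c(nutrient_provisioning = 0,
                                growth_efficiency = 0.6,
                                LOM_decomposition = 0,
                                ROM_decomposition = 0)),
                       n_blocks = 4, block_size = 12,
                       block_cross_kingdom_fraction = 0.25,
                       block_rho = 0.9, n_competitive_pairs = 6,
                       negative_edge_fraction = c(DP = 0.35, Control = 0.2,
                                                  IP = 0.2),
                       noise_sd = 0.25, log_sd = 1, seed = 1) {
  cfg <- list(n_bacteria = n_bacteria, n_fungi = n_fungi, depth = depth,
              base_presence = base_presence,
              richness_effects = richness_effects,
              function_effects = function_effects,
              n_blocks = n_blocks, block_size = block_size,
              block_cross_kingdom_fraction = block_cross_kingdom_fraction,
              block_rho = block_rho,
              n_competitive_pairs = n_competitive_pairs,
              negative_edge_fraction = negative_edge_fraction,
              noise_sd = noise_sd, log_sd = log_sd, seed = seed)
  stopifnot(depth > 0, n_bacteria > 0, n_fungi > 0,
            base_presence > 0, base_presence <= 1,
            block_cross_kingdom_fraction >= 0,
            block_cross_kingdom_fraction <= 1,
            block_rho > 0, block_rho < 1,
            all(negative_edge_fraction >= 0),
            all(negative_edge_fraction <= 0.5))
  class(cfg) <- "sim_config"
  cfg
}

#' The 17 soil ecosystem functions and their four groups
#'
#' Nutrient provisioning (dissolved organic C and N, available P, ammonium
#' and nitrate N), microbial growth efficiency (microbial biomass C/N/P,
#' carbon use efficiency, biomass turnover), labile organic matter
#' decomposition (five hydrolytic enzyme activities) and recalcitrant
#' organic matter decomposition (two oxidative enzyme activities).
#'
#' @return Named character vector: function name -> group.
#' @export
function_groups <- function() {
  c(DOC = "nutrient_provisioning", DON = "nutrient_provisioning",
    AP = "nutrient_provisioning", NH4_N = "nutrient_provisioning",
    NO3_N = "nutrient_provisioning",
    MBC = "growth_efficiency", MBN = "growth_efficiency",
    MBP = "growth_efficiency", CUE = "growth_efficiency",
    turnover = "growth_efficiency",
    BG = "LOM_decomposition", CBH = "LOM_decomposition",
    NAG = "LOM_decomposition", LAP = "LOM_decomposition",
    ALP = "LOM_decomposition",
    PER = "ROM_decomposition", PPO = "ROM_decomposition")
}

# internal: block membership and signed loadings over the combined pool.
# Mixed blocks (1..n_blocks) carry the sign mixture that produces the
# maximal treatment's negative-pair fraction. When the per-treatment
# targets differ, one extra all-positive "mesic" (drought-sensitive)
# cross-kingdom block is planted; it is structurally absent under
# high-target treatments, so its positive bacterial-fungal edges dilute
# the negative fraction only where it is present. Its size is solved so
# the planted edge composition matches the lower target.
# Returns list(block, sign, mesic = id of the mesic block or 0).
plant_blocks <- function(cfg) {
  n_tot <- cfg$n_bacteria + cfg$n_fungi
  block <- integer(n_tot)
  bcf <- cfg$block_cross_kingdom_fraction
  n_f_per_block <- round(cfg$block_size * bcf)
  n_b_per_block <- cfg$block_size - n_f_per_block
  t_max <- max(cfg$negative_edge_fraction)
  t_min <- min(cfg$negative_edge_fraction)

  # mesic block dimensions from the target ratio
  m_b <- 0L
  m_f <- 0L
  if (t_max > t_min + 1e-9 && bcf > 0) {
    bf_mix <- cfg$n_blocks * n_b_per_block * n_f_per_block
    bf_mesic <- bf_mix * (t_max - t_min) / max(t_min, 0.05)
    m_b <- max(2L, round(sqrt(bf_mesic * (1 - bcf) / bcf)))
    m_f <- max(2L, round(bf_mesic / m_b))
    # the mesic members must fit inside the high-target treatment's
    # structural-zero quota (they are part of its richness loss)
    for (tr in names(cfg$negative_edge_fraction)) {
      if (cfg$negative_edge_fraction[[tr]] <= t_min + 1e-9) next
      eff <- cfg$richness_effects[[tr]]
      if (is.null(eff)) eff <- c(bacteria = 0, fungi = 0)
      quota_b <- round(cfg$base_presence * cfg$n_bacteria) -
        round(cfg$base_presence * cfg$n_bacteria * (1 + eff[["bacteria"]]))
      quota_f <- round(cfg$base_presence * cfg$n_fungi) -
        round(cfg$base_presence * cfg$n_fungi * (1 + eff[["fungi"]]))
      m_b <- min(m_b, max(0L, quota_b))
      m_f <- min(m_f, max(0L, quota_f))
    }
    if (m_b < 2 || m_f < 2) {
      m_b <- 0L
      m_f <- 0L
    }
  }

  need_b <- cfg$n_blocks * n_b_per_block + m_b
  need_f <- cfg$n_blocks * n_f_per_block + m_f
  if (need_b > cfg$n_bacteria || need_f > cfg$n_fungi)
    stop("degenerate simulation: OTU pools too small for the planted blocks")
  b_members <- sample.int(cfg$n_bacteria, need_b)
  f_members <- cfg$n_bacteria + sample.int(cfg$n_fungi, need_f)
  for (b in seq_len(cfg$n_blocks)) {
    block[b_members[(b - 1) * n_b_per_block + seq_len(n_b_per_block)]] <- b
    block[f_members[(b - 1) * n_f_per_block + seq_len(n_f_per_block)]] <- b
  }
  mesic <- 0L
  if (m_b > 0) {
    mesic <- cfg$n_blocks + 1L
    block[b_members[cfg$n_blocks * n_b_per_block + seq_len(m_b)]] <- mesic
    block[f_members[cfg$n_blocks * n_f_per_block + seq_len(m_f)]] <- mesic
  }

  # obligate competitive bacterium-fungus pairs
  n_cp <- cfg$n_competitive_pairs
  comp <- integer(0)
  if (n_cp > 0) {
    free_b <- setdiff(seq_len(cfg$n_bacteria), which(block > 0))
    free_f <- setdiff(cfg$n_bacteria + seq_len(cfg$n_fungi),
                      which(block > 0))
    if (length(free_b) < n_cp || length(free_f) < n_cp)
      stop("degenerate simulation: OTU pools too small for the planted blocks")
    cp_b <- free_b[sample.int(length(free_b), n_cp)]
    cp_f <- free_f[sample.int(length(free_f), n_cp)]
    base_id <- cfg$n_blocks + 2L
    for (k in seq_len(n_cp)) {
      block[cp_b[k]] <- base_id + k - 1L
      block[cp_f[k]] <- base_id + k - 1L
    }
    comp <- base_id + seq_len(n_cp) - 1L
  }

  # sign mixture of the mixed blocks from the maximal target t:
  # fraction of negative within-block pairs = 2q(1-q) => q. Allocated
  # deterministically (exactly round(q * members) per block and kingdom)
  # so the realized edge composition does not fluctuate across seeds.
  q <- (1 - sqrt(max(0, 1 - 2 * t_max))) / 2
  sgn <- rep(1L, n_tot)
  for (b in seq_len(cfg$n_blocks)) {
    for (kd_first in c(TRUE, FALSE)) {
      members <- which(block == b &
                         (seq_len(n_tot) <= cfg$n_bacteria) == kd_first)
      n_neg <- round(q * length(members))
      if (n_neg > 0)
        sgn[members[sample.int(length(members), n_neg)]] <- -1L
    }
  }
  # competitive pairs: the fungal partner carries the flipped sign
  if (length(comp) > 0)
    sgn[block %in% comp & seq_len(n_tot) > cfg$n_bacteria] <- -1L
  list(block = block, sign = sgn, mesic = mesic, comp = comp)
}

#' Generate paired bacterial and fungal OTU tables
#'
#' Simulates two-kingdom OTU count tables with the structure the
#' downstream pipeline assumes: latent log abundances are multivariate
#' normal with planted correlation blocks spanning both kingdoms (a
#' configurable fraction of mixed-block members carry sign-flipped
#' loadings, producing negative associations); obligate competitive
#' bacterium-fungus pairs are strongly anti-correlated and always
#' present; a drought-sensitive "mesic" all-positive block is
#' structurally absent under treatments with elevated negative-link
#' targets; per-treatment richness effects are structural zeros (a
#' seeded subset of OTUs absent from all samples of a treatment), so
#' richness targets hold exactly in expectation; counts are fixed-depth
#' multinomial draws from the exponentiated latents.
#'
#' @param design Data frame from [generate_design()].
#' @param cfg A [sim_config()].
#' @return List with elements `bacteria` and `fungi` ([otu_table]s),
#'   plus `blocks` (planted block id per OTU of the combined pool, 0 =
#'   none), `signs` (loading signs) and `latent` (samples x OTUs latent
#'   log-abundance matrix, for diagnostics).
#' @export
generate_otu_tables <- function(design, cfg = sim_config()) {
  stopifnot(is.data.frame(design), all(c("sample_id", "treatment") %in%
                                         names(design)))
  with_seed(cfg$seed, {
    n_s <- nrow(design)
    n_tot <- cfg$n_bacteria + cfg$n_fungi
    kingdom <- rep(c("bacteria", "fungi"), c(cfg$n_bacteria, cfg$n_fungi))
    otu_ids <- paste0(ifelse(kingdom == "bacteria", "B_OTU", "F_OTU"),
                      c(seq_len(cfg$n_bacteria), seq_len(cfg$n_fungi)))
    bl <- plant_blocks(cfg)

    # latent log abundance: baseline + block factor + idiosyncratic noise.
    # Mixed-block members get a +2 log-sd abundance bonus: planted
    # modules are the dominant taxa, and high abundance keeps
    # anti-correlated pairs clear of the detection floor (censoring
    # would otherwise attenuate their negative correlations). Mesic
    # members get only +0.5: they must be reliably detected where
    # present, but abundant enough taxa leaving the community would
    # inflate every remaining relative abundance (compositional
    # closure) and plant spurious negative associations.
    mixed_member <- bl$block > 0 & bl$block <= cfg$n_blocks
    mesic_member <- bl$mesic > 0 & bl$block == bl$mesic
    mu <- stats::rnorm(n_tot, 0, cfg$log_sd) +
      mixed_member * 2 * cfg$log_sd + mesic_member * 0.5 * cfg$log_sd
    n_fac <- max(cfg$n_blocks, bl$mesic)  # comp pairs drawn separately
    fac <- matrix(stats::rnorm(n_s * n_fac), n_s, n_fac)
    eps <- matrix(stats::rnorm(n_s * n_tot), n_s, n_tot)
    lat <- sweep(eps * sqrt(1 - cfg$block_rho) * cfg$log_sd, 2, mu, `+`)
    in_b <- which(bl$block > 0 & !(bl$block %in% bl$comp))
    lat[, in_b] <- lat[, in_b] +
      sweep(fac[, bl$block[in_b], drop = FALSE], 2,
            bl$sign[in_b] * sqrt(cfg$block_rho) * cfg$log_sd, `*`)
    # competitive pairs: near-perfect anti-correlation (rho 0.98), so
    # their negative edges survive any plausible threshold
    if (length(bl$comp) > 0) {
      rho_cp <- 0.995
      for (cid in bl$comp) {
        mem <- which(bl$block == cid)
        g <- stats::rnorm(n_s)
        mu_cp <- 2 * cfg$log_sd + stats::rnorm(length(mem), 0, 0.2)
        noise <- matrix(stats::rnorm(n_s * length(mem)), n_s) *
          sqrt(1 - rho_cp) * cfg$log_sd
        lat[, mem] <- sweep(noise, 2, mu_cp, `+`) +
          outer(g, bl$sign[mem] * sqrt(rho_cp) * cfg$log_sd)
      }
    }

    # Structural zeros: a global baseline absent set (the same OTUs are
    # missing from every treatment, so null effects plant no
    # treatment-aligned structure), plus treatment-specific deviations
    # from the richness effects. Negative effects zero extra OTUs in
    # that treatment; positive effects resurrect baseline-absent ones.
    present <- matrix(TRUE, n_s, n_tot)
    trts <- levels(design$treatment)
    neg_boost <- cfg$negative_edge_fraction -
      min(cfg$negative_edge_fraction)
    for (kd in c("bacteria", "fungi")) {
      idx <- which(kingdom == kd)
      n_pool <- length(idx)
      base_n <- round(cfg$base_presence * n_pool)
      # planted block members are the dominant taxa: never baseline-absent
      non_block <- idx[bl$block[idx] == 0]
      n_absent <- min(n_pool - base_n, length(non_block))
      base_absent <- if (n_absent > 0)
        non_block[sample.int(length(non_block), n_absent)] else integer(0)
      present[, base_absent] <- FALSE
      base_present <- setdiff(idx, base_absent)
      for (tr in trts) {
        eff <- cfg$richness_effects[[tr]]
        if (is.null(eff)) eff <- c(bacteria = 0, fungi = 0)
        target <- round(base_n * (1 + eff[[kd]]))
        if (target < 3)
          stop("degenerate simulation: richness effect leaves < 3 OTUs")
        rows <- which(design$treatment == tr)
        delta <- target - length(base_present)
        if (delta < 0) {
          n_zero <- -delta
          zero <- integer(0)
          if (neg_boost[[tr]] > 0 && bl$mesic > 0) {
            # the mesic block is this treatment's drought-sensitive
            # richness loss: its members go first
            mes <- base_present[bl$block[base_present] == bl$mesic]
            take <- min(n_zero, length(mes))
            zero <- mes[seq_len(take)]
            n_zero <- n_zero - take
          }
          if (n_zero > 0) {
            # the rest never touches planted blocks, so mixed-block
            # edges stay comparable across treatments
            free <- base_present[bl$block[base_present] == 0]
            free <- setdiff(free, zero)
            zero <- c(zero, free[sample.int(length(free),
                                            min(n_zero, length(free)))])
          }
          present[rows, zero] <- FALSE
        } else if (delta > 0) {
          add <- base_absent[sample.int(length(base_absent),
                                        min(delta, length(base_absent)))]
          present[rows, add] <- TRUE
        }
      }
    }

    counts <- matrix(0L, n_s, n_tot,
                     dimnames = list(design$sample_id, otu_ids))
    for (i in seq_len(n_s)) {
      for (kd in c("bacteria", "fungi")) {
        idx <- which(kingdom == kd & present[i, ])
        p <- exp(lat[i, idx])
        counts[i, idx] <- as.integer(
          stats::rmultinom(1, cfg$depth, p / sum(p)))
      }
    }

    tax <- ifelse(kingdom == "bacteria",
                  "k__Bacteria;p__synthetic", "k__Fungi;p__synthetic")
    names(bl$block) <- otu_ids
    names(bl$sign) <- otu_ids
    dimnames(lat) <- dimnames(counts)
    list(bacteria = otu_table(counts[, kingdom == "bacteria"], "bacteria",
                              tax[kingdom == "bacteria"]),
         fungi = otu_table(counts[, kingdom == "fungi"], "fungi",
                           tax[kingdom == "fungi"]),
         blocks = bl$block, signs = bl$sign, latent = lat)
  })
}

#' Generate the soil function matrix and covariate table
#'
#' Each of the 17 functions is simulated as a per-function baseline plus
#' the configured treatment-by-group standardized effect plus Gaussian
#' noise, then given an arbitrary function-specific affine scale so raw
#' values have heterogeneous units (min-max standardization downstream
#' removes the affine part). Soil covariates (SWC, ST, pH, SOC, TN, TP,
#' L-CS, R-CS, POXC, HCl-ROC) get treatment-linked means with the
#' moisture-driven directions of the emulated system: SWC, SOC, L-CS and
#' POXC track precipitation; ST, R-CS and HCl-ROC run opposite.
#'
#' @inheritParams generate_otu_tables
#' @return List with `functions` (samples x 17 matrix), `groups` (named
#'   vector from [function_groups()]) and `soil` (samples x 10 covariate
#'   data frame).
#' @export
generate_functions <- function(design, cfg = sim_config()) {
  grp <- function_groups()
  if (length(grp) != 17 || length(unique(grp)) != 4)
    stop("schema error: 17 functions in 4 groups are required")
  with_seed(cfg$seed + 1L, {
    n_s <- nrow(design)
    fn <- names(grp)
    vals <- matrix(0, n_s, 17, dimnames = list(design$sample_id, fn))
    for (j in seq_along(fn)) {
      eff <- vapply(as.character(design$treatment), function(tr)
        cfg$function_effects[[tr]][[grp[j]]], numeric(1))
      vals[, j] <- eff + stats::rnorm(n_s, 0, cfg$noise_sd)
    }
    # heterogeneous raw units: affine per function
    scales <- exp(stats::rnorm(17, 0, 1))
    offsets <- stats::rnorm(17, 10, 5)
    vals <- sweep(sweep(vals, 2, scales, `*`), 2, offsets, `+`)

    trt <- as.character(design$treatment)
    precip <- c(DP = -1, Control = 0, IP = 1)[trt]
    mk <- function(mu, slope, sd) mu + slope * precip +
      stats::rnorm(n_s, 0, sd)
    soil <- data.frame(
      SWC = mk(12, 4, 1), ST = mk(22, -0.8, 0.5), pH = mk(8.4, -0.05, 0.08),
      SOC = mk(6, 1, 0.4), TN = mk(0.6, 0.08, 0.05),
      TP = mk(0.55, 0.02, 0.04),
      L_CS = mk(1.2, 0.15, 0.08), R_CS = mk(0.8, -0.12, 0.06),
      POXC = mk(450, 60, 30), HCl_ROC = mk(2.5, -0.35, 0.2),
      row.names = design$sample_id)
    list(functions = vals, groups = grp, soil = soil)
  })
}

#' Sample communities under Sloan's neutral model
#'
#' For each taxon with metacommunity relative abundance `p`, each sample's
#' latent relative abundance is drawn from the stationary beta
#' distribution with shape parameters `(N m p, N m (1 - p))`; the draws
#' are renormalized and `N` reads are sampled multinomially. Occurrence
#' frequencies therefore follow the Sloan prediction
#' `1 - pbeta(1/N, N m p, N m (1 - p))` in expectation.
#'
#' @param meta_abundances Nonnegative metacommunity relative abundances,
#'   summing to 1 (tolerance 1e-9).
#' @param N Local community size (reads per sample), >= 1.
#' @param m Migration probability, in (0, 1].
#' @param n_samples Number of local communities to draw.
#' @param seed Integer seed.
#' @return An [otu_table] (all labelled bacteria) of `n_samples` x taxa
#'   counts.
#' @export
sample_neutral_community <- function(meta_abundances, N, m, n_samples,
                                     seed = 1) {
  if (!is.numeric(m) || m <= 0 || m > 1)
    stop("parameter error: m must lie in (0, 1]")
  if (N < 1) stop("parameter error: N must be >= 1")
  p <- meta_abundances
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("meta_abundances must be nonnegative and sum to 1")
  with_seed(seed, {
    n_t <- length(p)
    counts <- matrix(0L, n_samples, n_t,
                     dimnames = list(paste0("S", seq_len(n_samples)),
                                     if (is.null(names(p)))
                                       paste0("OTU", seq_len(n_t))
                                     else names(p)))
    pos <- which(p > 0)
    for (i in seq_len(n_samples)) {
      x <- numeric(n_t)
      x[pos] <- stats::rbeta(length(pos), N * m * p[pos],
                             N * m * (1 - p[pos]))
      if (sum(x) <= 0) x[pos] <- p[pos]  # pathological underflow guard
      counts[i, ] <- as.integer(stats::rmultinom(1, N, x / sum(x)))
    }
    otu_table(counts)
  })
}

#' Sample communities along an environmental-filtering gradient
#'
#' Emulates deterministic environmental selection of tunable strength for
#' null-model benchmarking. Each sample keeps richness `richness`; a
#' fraction `w` of its taxa are the same template set in every sample
#' (deterministic filtering), the rest are drawn at random from the
#' regional pool with probability proportional to the pool occupancy
#' weights. `w = 0` reproduces the proportional-occupancy null model
#' itself; `w = 1` makes all samples identical.
#'
#' @param w Filtering strength in `[0, 1]`.
#' @param n_taxa Regional pool size.
#' @param richness Per-sample richness.
#' @param n_samples Number of samples.
#' @param occupancy_weights Optional pool weights (default uniform).
#' @param seed Integer seed.
#' @return An [otu_table] of presence counts (0/1).
#' @export
sample_filtered_community <- function(w, n_taxa = 200, richness = 80,
                                      n_samples = 6,
                                      occupancy_weights = NULL, seed = 1) {
  stopifnot(w >= 0, w <= 1, richness <= n_taxa)
  if (is.null(occupancy_weights)) occupancy_weights <- rep(1, n_taxa)
  with_seed(seed, {
    n_det <- round(w * richness)
    template <- sample.int(n_taxa, richness, prob = occupancy_weights)
    counts <- matrix(0L, n_samples, n_taxa,
                     dimnames = list(paste0("S", seq_len(n_samples)),
                                     paste0("OTU", seq_len(n_taxa))))
    for (i in seq_len(n_samples)) {
      det <- template[seq_len(n_det)]
      pool <- setdiff(seq_len(n_taxa), det)
      rnd <- pool[sample.int(length(pool), richness - n_det,
                             prob = occupancy_weights[pool])]
      counts[i, c(det, rnd)] <- 1L
    }
    otu_table(counts)
  })
}
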