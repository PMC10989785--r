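#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (seeded, deterministic).
#'
#' @param table An [otu_table] or counts matrix (samples x OTUs).
#' @param depth Target reads per sample; must not exceed any sample's
#'   total.
#' @param seed Integer seed.
#' @return Object of the same type as `table`, rarefied.
#' @export
rarefy <- function(table, depth, seed = 1) {
  counts <- otu_counts(table)
  if (any(rowSums(counts) < depth))
    stop("depth error: rarefaction depth exceeds a sample's total reads")
  rar <- with_seed(seed, vegan::rrarefy(counts, depth))
  mode(rar) <- "integer"
  if (inherits(table, "otu_table")) {
    out <- table
    out$counts <- rar
    out
  } else rar
}

#' Per-sample OTU richness
#'
#' @param table An [otu_table] or counts matrix.
#' @return Named integer vector: number of OTUs with count > 0 per
#'   sample.
#' @export
richness <- function(table) {
  counts <- otu_counts(table)
  rowSums(counts > 0)
}

#' Combined two-kingdom biodiversity score
#'
#' Min-max standardizes bacterial and fungal richness separately to
#' `[0, 1]` and averages the two, giving a per-sample biodiversity index
#' that weighs both kingdoms equally.
#'
#' @param bact_richness,fung_richness Per-sample richness vectors over the
#'   same samples.
#' @return Numeric vector in `[0, 1]`.
#' @export
combined_biodiversity <- function(bact_richness, fung_richness) {
  if (length(bact_richness) != length(fung_richness))
    stop("richness vectors must cover the same samples")
  (minmax_standardize(bact_richness) +
     minmax_standardize(fung_richness)) / 2
}

#' Levins' niche breadth
#'
#' For OTU j with across-sample proportions `p_ij` (of the OTU's own
#' total), `B_j = 1 / sum_i p_ij^2`: the effective number of samples
#' (habitats) the OTU occupies, from 1 (specialist, single sample) to the
#' number of samples (perfect generalist). The community summary `Bcom`
#' is the unweighted mean of `B` over OTUs occurring in at least
#' `min_occurrence` samples.
#'
#' @param table An [otu_table] or counts matrix.
#' @param min_occurrence Minimum number of samples an OTU must occupy to
#'   enter the community mean (default 2).
#' @return List with `B` (named per-OTU vector, retained OTUs only),
#'   `Bcom` (scalar) and `min_occurrence`.
#' @export
levins_niche_breadth <- function(table, min_occurrence = 2) {
  counts <- otu_counts(table)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " OTU(s) with zero total excluded")
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(counts, 2, tot, `/`)
  B <- 1 / colSums(p^2)
  keep <- colSums(counts > 0) >= min_occurrence
  list(B = B[keep], Bcom = mean(B[keep]), min_occurrence = min_occurrence)
}

# incidence Jaccard dissimilarity matrix via cross products
jaccard_binary <- function(inc) {
  # inc: samples x taxa logical/0-1 matrix; returns samples x samples D
  inc <- inc * 1
  shared <- tcrossprod(inc)
  rich <- diag(shared)
  union <- outer(rich, rich, `+`) - shared
  d <- 1 - shared / union
  d[union == 0] <- 0
  d
}

#' Normalized stochasticity ratio (NST)
#'
#' Null-model-based estimate of the stochasticity of community assembly
#' within each treatment group, on incidence Jaccard dissimilarity. For
#' each within-group sample pair the observed dissimilarity `D` is
#' compared with the null expectation `E` under randomizations that keep
#' each sample's richness fixed and draw taxa with probability
#' proportional to their regional occupancy frequency. The pairwise
#' stochasticity is `D/E` when `D <= E` and `(1-D)/(1-E)` otherwise; the
#' group value is the mean over pairs, clamped to `[0, 1]`. 1 means
#' turnover indistinguishable from the null (purely stochastic); values
#' near 0 mean strong departures in either direction (deterministic
#' homogenization or divergence).
#'
#' @param table An [otu_table] or counts matrix.
#' @param groups Treatment labels over samples (>= 3 samples per group).
#' @param n_null Number of null randomizations (>= 100).
#' @param seed Integer seed.
#' @return List of class `nst_result`: `nst` (named per-group values),
#'   `pairwise` (per-group data frames of D, E and the ratio), and the
#'   null-model settings used.
#' @export
nst <- function(table, groups, n_null = 1000, seed = 1) {
  counts <- otu_counts(table)
  groups <- as.factor(groups)
  if (length(groups) != nrow(counts))
    stop("groups must label every sample")
  if (n_null < 100) stop("n_null must be at least 100")
  if (any(table(groups) < 3))
    stop("insufficient replication: every group needs >= 3 samples")
  inc <- counts > 0
  occ <- colSums(inc)
  pool <- which(occ > 0)
  w <- occ[pool]
  n_taxa <- ncol(counts)

  with_seed(seed, {
    res <- lapply(levels(groups), function(g) {
      rows <- which(groups == g)
      inc_g <- inc[rows, , drop = FALSE]
      rich <- rowSums(inc_g)
      D <- jaccard_binary(inc_g)
      Esum <- matrix(0, length(rows), length(rows))
      null_inc <- matrix(FALSE, length(rows), n_taxa)
      for (r in seq_len(n_null)) {
        null_inc[] <- FALSE
        for (i in seq_along(rows)) {
          null_inc[i, pool[sample.int(length(pool), rich[i],
                                      prob = w)]] <- TRUE
        }
        Esum <- Esum + jaccard_binary(null_inc)
      }
      E <- Esum / n_null
      ut <- upper.tri(D)
      d <- D[ut]; e <- E[ut]
      ratio <- ifelse(d <= e,
                      ifelse(e == 0, 1, d / e),
                      (1 - d) / (1 - e))
      ratio <- pmin(pmax(ratio, 0), 1)
      list(value = mean(ratio),
           pairwise = data.frame(D = d, E = e, stochasticity = ratio))
    })
    names(res) <- levels(groups)
    structure(list(nst = vapply(res, `[[`, numeric(1), "value"),
                   pairwise = lapply(res, `[[`, "pairwise"),
                   settings = list(metric = "incidence Jaccard",
                                   null = "fixed richness, proportional occupancy",
                                   n_null = n_null, seed = seed)),
              class = "nst_result")
  })
}

#' Fit Sloan's neutral community model
#'
#' Estimates the migration parameter `m` by nonlinear least squares of
#' observed OTU occurrence frequencies against the neutral prediction,
#' where `p` is an OTU's mean relative abundance and `N` the mean reads
#' per sample. Two detection models are available. `"sampling"` (the
#' default) accounts for the read-sampling layer on top of the neutral
#' beta distribution: an OTU is detected unless its beta-binomial read
#' count is zero, giving
#' `F(p) = 1 - B(N m p, N m (1-p) + N) / B(N m p, N m (1-p))`.
#' `"threshold"` is the classic hard detection limit `d = 1/N` (one
#' read), `F(p) = 1 - pbeta(d, N m p, N m (1-p))`; it ignores read
#' sampling and overestimates `m` by ~25% on data that include it, but
#' is provided for comparability with the conventional fit.
#' `R^2 = 1 - SSE/SST` is computed on untransformed frequencies and may
#' be negative for data far from neutrality; it is reported as-is.
#'
#' @param table An [otu_table] or counts matrix (>= 10 OTUs, >= 5
#'   samples).
#' @param detection `"sampling"` (default) or `"threshold"`.
#' @return List of class `ncm_fit`: `m`, `r_squared`, `N`,
#'   `detection_limit`, `detection`, `n_otus`, `saturated` (TRUE when
#'   essentially all OTUs are present in every sample, making the fit
#'   degenerate), and `data` (per-OTU p, observed and predicted
#'   frequency).
#' @export
sloan_ncm_fit <- function(table, detection = c("sampling", "threshold")) {
  detection <- match.arg(detection)
  counts <- otu_counts(table)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 10 || nrow(counts) < 5)
    stop("sloan_ncm_fit() needs >= 10 OTUs and >= 5 samples")
  N <- mean(rowSums(counts))
  d <- 1 / N
  rel <- counts / rowSums(counts)
  p <- colMeans(rel)
  freq <- colMeans(counts > 0)
  saturated <- mean(freq > 0.999) > 0.95

  pred_fun <- function(m) {
    a <- N * m * p
    b <- N * m * (1 - p)
    if (detection == "sampling")
      1 - exp(lbeta(a, b + N) - lbeta(a, b))
    else
      1 - stats::pbeta(d, a, b)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(freq ~ pred_fun(m),
                      start = list(m = 0.1),
                      lower = 1e-6, upper = 1,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to a 1-D profile search before declaring failure
    obj <- function(lm10) sum((freq - pred_fun(10^lm10))^2)
    opt <- stats::optimize(obj, c(-6, 0))
    if (!is.finite(opt$objective))
      stop("fit failure: NCM optimizer did not converge (",
           conditionMessage(fit), ")")
    m_hat <- 10^opt$minimum
  } else {
    m_hat <- stats::coef(fit)[["m"]]
  }
  m_hat <- min(max(m_hat, 1e-6), 1)
  pred <- pred_fun(m_hat)
  sse <- sum((freq - pred)^2)
  sst <- sum((freq - mean(freq))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sse / sst
  structure(list(m = m_hat, r_squared = r2, N = N, detection_limit = d,
                 detection = detection,
                 n_otus = ncol(counts), saturated = saturated,
                 data = data.frame(p = p, freq_obs = freq,
                                   freq_pred = pred)),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: m = %.4g, R^2 = %.3f (N = %.0f, %d OTUs%s)\n",
              x$m, x$r_squared, x$N, x$n_otus,
              if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

#' @export
print.nst_result <- function(x, ...) {
  cat("NST (", x$settings$metric, ", ", x$settings$null, "):\n", sep = "")
  print(round(x$nst, 3))
  invisible(x)
}
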