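#' Soil multifunctionality indices
#'
#' Computes per-sample soil multifunctionality from a samples-by-functions
#' measurement matrix by three indices: the averaging index (mean of the
#' 0-1 min-max standardized functions), the group-weighted index (mean of
#' the four function-group means, so each group contributes equally), and
#' the principal-coordinate index (first axis of a Euclidean PCoA of the
#' standardized matrix, sign-oriented so its Spearman correlation with the
#' averaging index is nonnegative). Per-sample group scores are returned
#' alongside.
#'
#' @param values Numeric matrix, samples x functions, no missing values.
#' @param groups Named character vector mapping each function (column) to
#'   its group; defaults to the 17-function scheme of
#'   [function_groups()].
#' @return A list of class `multifunctionality` with elements
#'   `standardized` (samples x functions in `[0,1]`), `mf_avg`,
#'   `mf_group_weighted`, `mf_pcoa` (per-sample numeric vectors),
#'   `group_scores` (samples x groups), and `pcoa_axes` (further PCoA
#'   axes, for inspection).
#' @examples
#' sim <- generate_functions(generate_design(6), sim_config(seed = 1))
#' mf <- multifunctionality(sim$functions, sim$groups)
#' head(mf$mf_avg)
#' @export
multifunctionality <- function(values, groups = function_groups()) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("function matrix must have no missing values")
  if (is.null(colnames(values))) colnames(values) <- names(groups)
  if (!all(colnames(values) %in% names(groups)))
    stop("schema error: every function must be assigned to a group")
  groups <- groups[colnames(values)]
  std <- apply(values, 2, minmax_standardize)
  rownames(std) <- rownames(values)

  mf_avg <- rowMeans(std)
  glev <- unique(groups)
  gsc <- sapply(glev, function(g)
    rowMeans(std[, groups == g, drop = FALSE]))
  if (any(table(factor(groups, glev)) == 0))
    stop("schema error: empty function group")
  mf_gw <- rowMeans(gsc)

  pc <- pcoa_scores(std)
  mf_pcoa <- orient_axis(pc[, 1], mf_avg)

  structure(list(standardized = std, mf_avg = mf_avg,
                 mf_group_weighted = mf_gw, mf_pcoa = mf_pcoa,
                 group_scores = gsc, pcoa_axes = pc),
            class = "multifunctionality")
}

# Euclidean PCoA of a samples-x-features matrix = principal component
# scores of the centered matrix; returned with as many axes as have
# positive eigenvalues (at most n-1).
pcoa_scores <- function(x) {
  if (nrow(x) < 3) stop("insufficient data: PCoA needs at least 3 samples")
  k <- min(nrow(x) - 1, ncol(x))
  sc <- suppressWarnings(stats::cmdscale(stats::dist(x), k = k))
  if (is.null(dim(sc))) sc <- matrix(sc, ncol = 1)
  rownames(sc) <- rownames(x)
  sc
}

# flip an axis so its Spearman correlation with a reference is >= 0
orient_axis <- function(axis, reference) {
  if (stats::sd(axis) == 0 || stats::sd(reference) == 0) return(axis)
  rho <- stats::cor(axis, reference, method = "spearman")
  if (!is.na(rho) && rho < 0) -axis else axis
}

#' @export
print.multifunctionality <- function(x, ...) {
  cat(sprintf(
    "multifunctionality: %d samples, %d functions, %d groups\n",
    nrow(x$standardized), ncol(x$standardized), ncol(x$group_scores)))
  cat(sprintf("  mf_avg range: [%.3f, %.3f]\n",
              min(x$mf_avg), max(x$mf_avg)))
  invisible(x)
}
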