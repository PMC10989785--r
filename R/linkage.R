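#' Spearman screen of predictors against a response
#'
#' Spearman rank correlation of each predictor with the response, with
#' two-sided p-values and Benjamini-Hochberg adjusted q-values. Constant
#' predictors are flagged with `NA` correlations.
#'
#' @param predictors Data frame or matrix, samples x predictors (n >= 5).
#' @param response Numeric vector over the same samples.
#' @return Data frame: predictor, rho, p, q.
#' @export
spearman_screen <- function(predictors, response) {
  x <- as.data.frame(predictors)
  if (nrow(x) < 5) stop("spearman_screen() needs n >= 5")
  if (length(response) != nrow(x))
    stop("response must match the predictor rows")
  res <- lapply(names(x), function(nm) {
    v <- x[[nm]]
    if (stats::sd(v) == 0) {
      warning("constant predictor '", nm, "': rho undefined")
      return(data.frame(predictor = nm, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(v, response, method = "spearman"))
    data.frame(predictor = nm, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Random-forest permutation importance
#'
#' Fits a regression random forest and reports each predictor's
#' importance as the percentage increase in out-of-bag mean-squared error
#' when that predictor is permuted (raw increase relative to the
#' baseline OOB MSE, as a percentage). Significance is assessed by
#' refitting the forest on `n_perms` response-permuted datasets and
#' comparing each observed importance with its null distribution.
#'
#' @param predictors Data frame or matrix, samples x predictors (n >=
#'   10).
#' @param response Numeric response.
#' @param n_trees Number of trees (default 500).
#' @param n_perms Response permutations for the null (default 100; 0
#'   skips the significance step).
#' @param seed Integer seed.
#' @return Data frame: predictor, inc_mse_pct, p (NA when `n_perms =
#'   0`), plus attribute `"baseline_mse"`.
#' @export
permutation_importance <- function(predictors, response, n_trees = 500,
                                   n_perms = 100, seed = 1) {
  x <- as.data.frame(predictors)
  if (nrow(x) < 10) stop("permutation_importance() needs n >= 10")
  if (stats::sd(response) == 0) stop("degenerate (constant) response")
  fit_once <- function(y) {
    rf <- randomForest::randomForest(x, y, ntree = n_trees,
                                     importance = TRUE)
    base <- rf$mse[n_trees]
    raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    list(imp = 100 * raw / base, base = base)
  }
  imp_once <- function(y) fit_once(y)$imp
  with_seed(seed, {
    obs_fit <- fit_once(response)
    obs <- obs_fit$imp
    p <- rep(NA_real_, length(obs))
    if (n_perms > 0) {
      null_mat <- vapply(seq_len(n_perms),
                         function(i) imp_once(sample(response)),
                         numeric(length(obs)))
      p <- vapply(seq_along(obs), function(j)
        (1 + sum(null_mat[j, ] >= obs[j])) / (n_perms + 1), numeric(1))
    }
    out <- data.frame(predictor = names(x), inc_mse_pct = unname(obs),
                      p = p)
    attr(out, "baseline_mse") <- obs_fit$base
    out[order(-out$inc_mse_pct), ]
  })
}

#' Partial correlation
#'
#' Pearson correlation between `x` and `y` after controlling for one or
#' more covariates, computed from the inverse of the joint correlation
#' matrix (`r = -P_xy / sqrt(P_xx P_yy)`). With a single control this
#' equals `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. A
#' rank-based variant replaces all variables by their ranks first.
#'
#' @param x,y Numeric vectors.
#' @param controls Numeric vector, matrix or data frame of controls (may
#'   be NULL for the zero-order correlation).
#' @param method `"pearson"` (default) or `"spearman"` (rank-based).
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(x, y, controls = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  z <- if (is.null(controls)) NULL else as.matrix(controls)
  n <- length(x)
  if (!is.null(z) && n <= ncol(z) + 2)
    stop("need n > number of controls + 2")
  dat <- cbind(x = x, y = y, z)
  if (method == "spearman") dat <- apply(dat, 2, rank)
  cm <- stats::cor(dat)
  if (is.null(z)) return(cm["x", "y"])
  cond <- tryCatch(kappa(cm, exact = TRUE), error = function(e) Inf)
  P <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(P) || !all(is.finite(P)))
    stop(sprintf(
      "singular correlation matrix (condition number %.3g): %s",
      cond, "controls are collinear with x or y"))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Zero-order and pairwise-controlled correlation report
#'
#' For each factor: its zero-order correlation with the response, its
#' correlation controlling each other factor in turn, and the percent
#' change `(|r0| - |rc|) / |r0| * 100` (a large drop when controlling Z
#' means the factor's apparent effect runs through Z).
#'
#' @param factors Data frame or matrix, samples x factors (>= 2
#'   factors).
#' @param response Numeric response vector.
#' @param method Passed to [partial_correlation()].
#' @return List of class `partial_report`: `zero_order` (named vector),
#'   `controlled` (factors x controls matrix, `NA` on the diagonal) and
#'   `pct_change` (same shape).
#' @export
partial_report <- function(factors, response,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  f <- as.data.frame(factors)
  if (ncol(f) < 2) stop("partial_report() needs at least 2 factors")
  nm <- names(f)
  r0 <- vapply(nm, function(a)
    partial_correlation(f[[a]], response, NULL, method), numeric(1))
  rc <- matrix(NA_real_, ncol(f), ncol(f), dimnames = list(nm, nm))
  for (a in nm) for (b in setdiff(nm, a))
    rc[a, b] <- partial_correlation(f[[a]], response, f[[b]], method)
  pct <- 100 * (abs(r0) - abs(rc)) / abs(r0)
  structure(list(zero_order = r0, controlled = rc, pct_change = pct),
            class = "partial_report")
}
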