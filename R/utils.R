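#' Evaluate an expression with a private RNG state
#'
#' All stochastic functions in mfnet take an explicit `seed` and route their
#' draws through this helper, so the caller's global RNG stream is never
#' consumed or disturbed and identical seeds give bit-identical output.
#'
#' @param seed Integer seed, or `NULL` to use (and advance) the current RNG.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # initialise so there is a state to restore
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Min-max standardization to the unit interval
#'
#' Linearly rescales a vector to `[0, 1]` as `(x - min) / (max - min)`. A
#' constant vector is mapped to 0.5 everywhere (a neutral contribution to any
#' averaged index) with a warning; dropping it instead would silently change
#' the denominator of every index built on the standardized values.
#'
#' @param x Numeric vector, length >= 2, no missing values.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' minmax_standardize(c(2, 4, 6))
#' @export
minmax_standardize <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("minmax_standardize() needs a numeric vector of length >= 2")
  if (anyNA(x)) stop("minmax_standardize() does not accept missing values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant vector: standardized to 0.5 everywhere")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Compact letter display from a matrix of pairwise p-values.
# Insert-absorb style: groups are processed in order of their location
# statistic; a group joins every letter whose members it does not differ
# from, and opens a new letter when none accepts it. Exact for the small
# numbers of groups (3 treatments) this package compares.
cld_letters <- function(pmat, order_stat, alpha = 0.05) {
  g <- rownames(pmat)
  ord <- order(order_stat, decreasing = TRUE)
  g <- g[ord]
  differs <- function(a, b) {
    p <- pmat[a, b]
    !is.na(p) && p < alpha
  }
  sets <- list()
  for (gi in g) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(vapply(sets[[k]], differs, logical(1), b = gi))) {
        sets[[k]] <- c(sets[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- gi
  }
  out <- vapply(rownames(pmat), function(gi) {
    paste0(letters[which(vapply(sets, function(s) gi %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  out
}
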