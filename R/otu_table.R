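#' OTU count table with kingdom annotation
#'
#' A lightweight container for a samples-by-OTUs count matrix plus the
#' per-OTU kingdom label (bacteria or fungi) and an optional taxonomy
#' lineage string. All mfnet community functions accept either an
#' `otu_table` or a bare counts matrix (kingdom-aware operations require
#' the full object).
#'
#' @param counts Numeric matrix, samples in rows, OTUs in columns,
#'   nonnegative integers. Row and column names are required.
#' @param kingdom Character vector over OTUs, values in
#'   `c("bacteria", "fungi")`; recycled if length 1.
#' @param taxonomy Optional character vector of lineage strings over OTUs.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, kingdom = "bacteria", taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, ncol(counts))
  if (length(kingdom) != ncol(counts))
    stop("kingdom must have one entry per OTU")
  if (!all(kingdom %in% c("bacteria", "fungi")))
    stop("kingdom values must be 'bacteria' or 'fungi'")
  names(kingdom) <- colnames(counts)
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy must have one entry per OTU")
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, kingdom = kingdom, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%d bacteria, %d fungi)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$kingdom == "bacteria"), sum(x$kingdom == "fungi")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

# coerce matrix-or-otu_table inputs to a counts matrix
otu_counts <- function(table) {
  if (inherits(table, "otu_table")) table$counts else as.matrix(table)
}

# subset OTUs (columns), keeping annotations in step
otu_subset <- function(table, keep) {
  stopifnot(inherits(table, "otu_table"))
  otu_table(table$counts[, keep, drop = FALSE],
            kingdom = table$kingdom[keep],
            taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[keep])
}

#' Write / read an OTU table as TSV
#'
#' Plain-text interchange format: rows are OTUs, columns are samples; the
#' first three columns hold the OTU id, kingdom, and taxonomy string.
#'
#' @param table An [otu_table].
#' @param path File path.
#' @return `write_otu_table` returns `path` invisibly; `read_otu_table`
#'   returns an [otu_table].
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  tax <- if (is.null(table$taxonomy)) rep(NA_character_, ncol(table$counts))
         else table$taxonomy
  df <- data.frame(otu_id = colnames(table$counts),
                   kingdom = unname(table$kingdom),
                   taxonomy = unname(tax),
                   t(table$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(otu_id = "character",
                                         kingdom = "character",
                                         taxonomy = "character"))
  counts <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(counts) <- df$otu_id
  tax <- df$taxonomy
  otu_table(counts, kingdom = df$kingdom,
            taxonomy = if (!all(is.na(tax))) tax)
}

#' Merge bacterial and fungal OTU tables over a shared sample set
#'
#' @param bacteria,fungi [otu_table] objects with identical sample sets.
#' @return A merged [otu_table] with kingdom labels preserved.
#' @export
merge_kingdoms <- function(bacteria, fungi) {
  stopifnot(inherits(bacteria, "otu_table"), inherits(fungi, "otu_table"))
  if (!identical(rownames(bacteria$counts), rownames(fungi$counts)))
    stop("tables must share the same samples in the same order")
  tax <- NULL
  if (!is.null(bacteria$taxonomy) && !is.null(fungi$taxonomy))
    tax <- c(bacteria$taxonomy, fungi$taxonomy)
  otu_table(cbind(bacteria$counts, fungi$counts),
            kingdom = c(bacteria$kingdom, fungi$kingdom),
            taxonomy = tax)
}
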