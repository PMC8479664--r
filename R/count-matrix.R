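#' Construct a count matrix
#'
#' A count matrix holds non-negative expression quantifications, genes in rows
#' and units (bulk samples, bulk replicates, or single cells) in columns.
#' Values need not be integers: transcript-abundance estimators commonly emit
#' real-valued "effective counts", and the whole likelihood machinery uses the
#' continuous (log-gamma) extension of the Poisson mass function.
#'
#' Negative, missing or non-finite values, and duplicated gene or unit
#' identifiers, are rejected at construction so that downstream code never has
#' to re-validate.
#'
#' @param values numeric matrix, genes x units, all entries finite and >= 0.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param unit_ids character vector of unique unit identifiers (defaults to
#'   `colnames(values)`).
#' @param kind `"bulk"` or `"single_cell"`; which role the columns play.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (the matrix, with dimnames), `gene_ids`, `unit_ids` and `kind`.
#' @examples
#' y <- matrix(c(5, 0, 0, 3), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' count_matrix(y, kind = "bulk")
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         unit_ids = colnames(values),
                         kind = c("bulk", "single_cell")) {
  kind <- match.arg(kind)
  if (!is.matrix(values))
    values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(unit_ids))
    stop_validation("gene_ids and unit_ids are required (set dimnames or pass explicitly)")
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  if (length(gene_ids) != nrow(values))
    stop_validation("length of gene_ids (%d) does not match row count (%d)",
                    length(gene_ids), nrow(values))
  if (length(unit_ids) != ncol(values))
    stop_validation("length of unit_ids (%d) does not match column count (%d)",
                    length(unit_ids), ncol(values))
  if (nrow(values) < 1L)
    stop_validation("no genes")
  if (anyDuplicated(gene_ids))
    stop_validation("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(unit_ids))
    stop_validation("duplicate unit id: %s", unit_ids[duplicated(unit_ids)][1L])
  if (anyNA(values) || !all(is.finite(values)))
    stop_validation("count values must be finite and non-missing")
  if (any(values < 0))
    stop_validation("count values must be non-negative")
  dimnames(values) <- list(gene_ids, unit_ids)
  structure(list(values = values, gene_ids = gene_ids, unit_ids = unit_ids,
                 kind = kind),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %d genes x %d %s units>\n",
              nrow(x$values), ncol(x$values),
              if (x$kind == "bulk") "bulk" else "single-cell"))
  invisible(x)
}

# coerce a count_matrix or bare matrix/vector to the internal dense matrix
as_count_values <- function(x, kind = "bulk") {
  if (inherits(x, "count_matrix"))
    return(x)
  if (is.vector(x) && is.numeric(x))
    x <- matrix(x, ncol = 1L, dimnames = list(names(x), "unit_1"))
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("gene_%d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("unit_%d", seq_len(ncol(x)))
  count_matrix(x, kind = kind)
}

#' Construct a cell-label table
#'
#' Assigns each reference unit (cell) to a named cell type. Type names are
#' ordered by first appearance so that downstream matrices have a stable,
#' input-determined column order.
#'
#' @param unit_ids character vector of unique unit identifiers.
#' @param labels character vector, one cell-type name per unit.
#' @return An object of class `cell_labels`: list with `unit_ids`, `labels`,
#'   `type_names` (unique labels in first-appearance order).
#' @examples
#' cell_labels(c("c1", "c2", "c3"), c("cancer", "cancer", "immune"))
#' @export
cell_labels <- function(unit_ids, labels) {
  unit_ids <- as.character(unit_ids)
  labels <- as.character(labels)
  if (length(unit_ids) != length(labels))
    stop_validation("unit_ids and labels differ in length")
  if (length(unit_ids) < 1L)
    stop_validation("empty label table")
  if (anyDuplicated(unit_ids))
    stop_validation("duplicated unit id in labels: %s",
                    unit_ids[duplicated(unit_ids)][1L])
  if (anyNA(labels) || any(!nzchar(labels)))
    stop_validation("labels must be non-empty strings")
  structure(list(unit_ids = unit_ids, labels = labels,
                 type_names = unique(labels)),
            class = "cell_labels")
}

#' @export
print.cell_labels <- function(x, ...) {
  cat(sprintf("<cell_labels: %d units, %d types (%s)>\n",
              length(x$unit_ids), length(x$type_names),
              paste(x$type_names, collapse = ", ")))
  invisible(x)
}

#' Align a count matrix with a label table
#'
#' Restricts both objects to the intersection of their unit identifiers, in
#' count-matrix column order, warning about units dropped from either side.
#' The operation is idempotent.
#'
#' @param counts a [count_matrix()].
#' @param labels a [cell_labels()].
#' @return list with elements `counts` and `labels`, aligned.
#' @export
align_labels <- function(counts, labels) {
  stopifnot(inherits(counts, "count_matrix"), inherits(labels, "cell_labels"))
  keep <- counts$unit_ids[counts$unit_ids %in% labels$unit_ids]
  if (length(keep) == 0L)
    stop_validation("no unit ids shared between counts and labels")
  dropped_counts <- setdiff(counts$unit_ids, keep)
  dropped_labels <- setdiff(labels$unit_ids, keep)
  if (length(dropped_counts) || length(dropped_labels))
    warning(sprintf("align_labels: dropped %d unlabelled unit(s) from counts [%s]; %d labelled unit(s) absent from counts [%s]",
                    length(dropped_counts),
                    paste(utils::head(dropped_counts, 5L), collapse = ", "),
                    length(dropped_labels),
                    paste(utils::head(dropped_labels, 5L), collapse = ", ")),
            call. = FALSE)
  cm <- count_matrix(counts$values[, keep, drop = FALSE],
                     gene_ids = counts$gene_ids, unit_ids = keep,
                     kind = counts$kind)
  lb <- labels$labels[match(keep, labels$unit_ids)]
  list(counts = cm, labels = cell_labels(keep, lb))
}
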