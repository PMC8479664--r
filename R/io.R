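# Readers and writers for the plain-text formats the tool touches:
# dense TSV count tables, CellRanger-style MatrixMarket triplets, two-column
# label tables, and the decomposition output directory. All numeric output is
# written with 12 significant digits so write/read round-trips preserve values
# to at least 9 significant digits and repeated runs are byte-identical.

fmt_num <- function(x) sprintf("%.12g", x)

write_tsv_matrix <- function(values, path, row_label = "gene_id") {
  con <- file(path, open = "wb")  # binary: fixed "\n" endings for determinism
  on.exit(close(con))
  writeLines(paste(c(row_label, colnames(values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(values)), function(i)
    paste(c(rownames(values)[i], fmt_num(values[i, ])), collapse = "\t"),
    character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read a dense TSV count table
#'
#' Expects a header row of unit identifiers, a first column of gene
#' identifiers, and a numeric body. Tab-separated, `.` decimal separator, no
#' thousands separators; `NA` values are rejected.
#'
#' @param path path to the TSV file.
#' @param kind `"bulk"` or `"single_cell"`.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, kind = c("bulk", "single_cell")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop_io("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(tab) == 0L)
    stop_validation("no genes in %s", path)
  if (ncol(tab) < 2L)
    stop_validation("no units in %s", path)
  gene_ids <- tab[[1L]]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | body == "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_format("non-numeric value '%s' at row %d, column %d of %s",
                body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L] + 1L,
                path)
  if (any(num < 0))
    stop_validation("negative count in %s", path)
  dimnames(num) <- list(gene_ids, colnames(body))
  count_matrix(num, kind = kind)
}

#' Write a dense TSV count table
#'
#' Inverse of [read_counts_tsv()]; values round-trip to at least 9 significant
#' digits and the output is byte-deterministic.
#'
#' @param counts a [count_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  write_tsv_matrix(counts$values, path)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1L), 1L)
}

#' Read a CellRanger-style MatrixMarket count triplet
#'
#' Reads a sparse MatrixMarket coordinate file together with plain-text
#' feature and barcode lists (first tab-separated field of each line is taken
#' as the identifier) and materializes the dense count matrix, genes x cells.
#'
#' @param matrix_path path to the MatrixMarket `.mtx` file (1-based indices).
#' @param features_path path to the feature (gene) list.
#' @param barcodes_path path to the barcode (cell) list.
#' @param transpose `"auto"` (default) transposes the matrix when only the
#'   transposed orientation matches the id-list lengths; `TRUE`/`FALSE` force.
#' @return a [count_matrix()] with `kind = "single_cell"`.
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path,
                            transpose = "auto") {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop_io("file not found: %s", p)
  mm <- tryCatch(Matrix::readMM(matrix_path),
                 error = function(e) stop_format("invalid MatrixMarket file %s: %s",
                                                 matrix_path, conditionMessage(e)))
  genes <- read_id_column(features_path)
  cells <- read_id_column(barcodes_path)
  fits_as_is <- nrow(mm) == length(genes) && ncol(mm) == length(cells)
  fits_flipped <- ncol(mm) == length(genes) && nrow(mm) == length(cells)
  do_t <- if (identical(transpose, "auto")) {
    if (fits_as_is) FALSE
    else if (fits_flipped) TRUE
    else NA
  } else isTRUE(transpose)
  if (is.na(do_t) || (!do_t && !fits_as_is) || (do_t && !fits_flipped)) {
    off <- if (nrow(mm) != length(genes) && ncol(mm) != length(genes))
      features_path else barcodes_path
    stop_format("matrix dimensions %d x %d in %s do not match id list lengths (%d features, %d barcodes); offending file: %s",
                nrow(mm), ncol(mm), matrix_path, length(genes), length(cells), off)
  }
  dense <- as.matrix(mm)
  if (do_t) dense <- t(dense)
  if (any(dense < 0))
    stop_validation("negative entry in %s", matrix_path)
  dimnames(dense) <- list(genes, cells)
  count_matrix(dense, kind = "single_cell")
}

#' Read a two-column cell-label table
#'
#' Tab-separated `unit_id<TAB>label` rows with an optional header (a first
#' line whose leading field looks like `unit_id`, `cell`, `barcode` or `id`).
#'
#' @param path path to the label TSV.
#' @return a [cell_labels()].
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path))
    stop_io("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop_validation("empty label file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop_format("expected two tab-separated columns in %s (line %d)",
                path, which(lengths(fields) < 2L)[1L])
  header_words <- c("unit_id", "cell_id", "barcode", "cell", "unit", "id")
  if (tolower(fields[[1L]][1L]) %in% header_words)
    fields <- fields[-1L]
  if (length(fields) == 0L)
    stop_validation("no labelled units in %s", path)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  labs <- vapply(fields, `[[`, character(1L), 2L)
  cell_labels(ids, labs)
}

write_cell_labels <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("unit_id\tlabel", con)
  writeLines(paste(labels$unit_ids, labels$labels, sep = "\t"), con)
  invisible(path)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write a decomposition result to a directory
#'
#' Emits `composition.tsv` (cell types x replicates), `scale.tsv`,
#' `X.tsv`/`T.tsv` (fitted profiles and precisions), one
#' `allocations_<type>.tsv` per cell type (genes x replicates), and
#' `run_metadata.txt` recording the resolved options. Output is
#' byte-deterministic for identical fits.
#'
#' @param fit a `poisdecon` fit as returned by [poisdecon()].
#' @param out_dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_decomposition <- function(fit, out_dir) {
  stopifnot(inherits(fit, "poisdecon"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io("cannot create output directory: %s", out_dir)
  write_tsv_matrix(fit$composition, file.path(out_dir, "composition.tsv"),
                   row_label = "cell_type")
  sc <- matrix(fit$scale, nrow = 1L,
               dimnames = list("scale", colnames(fit$composition)))
  write_tsv_matrix(sc, file.path(out_dir, "scale.tsv"), row_label = "field")
  write_tsv_matrix(fit$X, file.path(out_dir, "X.tsv"))
  write_tsv_matrix(fit$T, file.path(out_dir, "T.tsv"))
  for (l in seq_along(fit$type_names)) {
    al <- fit$allocations[, l, , drop = FALSE]
    dim(al) <- dim(fit$allocations)[c(1L, 3L)]
    dimnames(al) <- list(fit$gene_ids, colnames(fit$composition))
    write_tsv_matrix(al, file.path(out_dir,
                                   sprintf("allocations_%s.tsv",
                                           sanitize_name(fit$type_names[l]))))
  }
  meta <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("poisdecon"))),
    sprintf("n_genes\t%d", length(fit$gene_ids)),
    sprintf("n_types\t%d", length(fit$type_names)),
    sprintf("n_replicates\t%d", ncol(fit$composition)),
    sprintf("tol\t%s", fmt_num(fit$options$tol)),
    sprintf("max_iter\t%d", fit$options$max_iter),
    sprintf("t_min\t%s", fmt_num(fit$options$t_bounds[1L])),
    sprintf("t_max\t%s", fmt_num(fit$options$t_bounds[2L])),
    sprintf("free_reference\t%s", fit$options$free_reference),
    sprintf("seed\t%s", if (is.null(fit$options$seed)) "NA" else fit$options$seed),
    sprintf("n_iter\t%d", fit$n_iter),
    sprintf("converged\t%s", fit$converged),
    sprintf("n_fallback_genes\t%d", fit$n_fallback)
  )
  con <- file(file.path(out_dir, "run_metadata.txt"), open = "wb")
  writeLines(meta, con)
  close(con)
  invisible(out_dir)
}
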