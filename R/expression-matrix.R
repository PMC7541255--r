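#' @keywords internal
"_PACKAGE"

EXPRESSION_UNITS <- c("TPM", "CPM", "RPKM", "FPKM", "READS", "QN", "UNKNOWN")

#' Construct an expression matrix
#'
#' The central container of the package: a genes x cells matrix of
#' nonnegative, finite expression values together with unique gene and cell
#' identifiers and a units label. Units (TPM, CPM, RPKM, FPKM, raw READS,
#' quantile-normalized QN) are carried as metadata only; no conversion
#' between units is performed anywhere in the package.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids character vector of row identifiers (defaults to existing
#'   rownames, else `gene1..geneM`).
#' @param cell_ids character vector of column identifiers (defaults to
#'   existing colnames, else `cell1..cellN`).
#' @param units one of `r paste(EXPRESSION_UNITS, collapse = ", ")`.
#' @return an object of class `ExpressionMatrix` with fields `values`
#'   (dimnamed matrix) and `units`.
#' @export
ExpressionMatrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                             units = "UNKNOWN") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  units <- match.arg(units, EXPRESSION_UNITS)

  if (length(gene_ids) != nrow(values))
    stopf("gene_ids length (%d) != number of rows (%d)",
          length(gene_ids), nrow(values))
  if (length(cell_ids) != ncol(values))
    stopf("cell_ids length (%d) != number of columns (%d)",
          length(cell_ids), ncol(values))
  if (anyDuplicated(gene_ids))
    stopf("duplicate gene ids (first: '%s')", gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(cell_ids))
    stopf("duplicate cell ids (first: '%s')", cell_ids[duplicated(cell_ids)][1])
  if (any(!is.finite(values)))
    stopf("expression values must all be finite")
  if (any(values < 0))
    stopf("expression values must be nonnegative (found %g)", min(values))

  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, units = units), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and cell identifiers
#' @param M an `ExpressionMatrix` or `PreprocessedMatrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(M) rownames(M$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(M) colnames(M$values)

parse_dense <- function(path, sep) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stopf("parse error in '%s': need a header line and at least one gene row",
          path)
  header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  body <- strsplit(lines[-1L], sep, fixed = TRUE)
  ncol_expected <- length(header)
  gene <- character(length(body))
  vals <- matrix(NA_real_, length(body), ncol_expected - 1L)
  for (r in seq_along(body)) {
    fields <- body[[r]]
    if (length(fields) != ncol_expected)
      stopf("parse error in '%s' at line %d: %d fields, expected %d",
            path, r + 1L, length(fields), ncol_expected)
    gene[r] <- fields[1L]
    v <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(v))
      stopf("parse error in '%s' at line %d: non-numeric value '%s'",
            path, r + 1L, fields[-1L][which(is.na(v))[1]])
    vals[r, ] <- v
  }
  # header convention: first field is a corner label (often empty), the rest
  # are cell ids
  list(values = vals, gene_ids = gene, cell_ids = header[-1L])
}

read_mtx <- function(path) {
  dir <- dirname(path)
  genes_path <- file.path(dir, "genes.txt")
  cells_path <- file.path(dir, "barcodes.txt")
  for (p in c(genes_path, cells_path))
    if (!file.exists(p))
      stopf("MTX input requires sibling file '%s'", p)
  mm <- as.matrix(Matrix::readMM(path))
  list(values = mm,
       gene_ids = readLines(genes_path),
       cell_ids = readLines(cells_path))
}

#' Read an expression matrix from TSV, CSV or Matrix Market files
#'
#' Dense TSV/CSV files use the common scRNA-seq flat-file convention: the
#' first row holds cell ids (after a corner label), the first column holds
#' gene ids. MTX files follow the Matrix Market coordinate standard
#' (genes x cells, 1-based) and require sibling `genes.txt` and
#' `barcodes.txt` files in the same directory.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`; in
#'   the latter case the matrix is transposed on read so the result is always
#'   genes x cells.
#' @param units units label to attach (metadata only).
#' @return an [ExpressionMatrix].
#' @export
read_expression <- function(path,
                            format = c("tsv", "csv", "mtx"),
                            orientation = c("genes_by_cells", "cells_by_genes"),
                            units = "UNKNOWN") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: '%s'", path)

  parsed <- switch(format,
    tsv = parse_dense(path, "\t"),
    csv = parse_dense(path, ","),
    mtx = read_mtx(path))

  values <- parsed$values
  g <- parsed$gene_ids
  c_ <- parsed$cell_ids
  if (orientation == "cells_by_genes") {
    values <- t(values)
    tmp <- g; g <- c_; c_ <- tmp
  }
  ExpressionMatrix(values, gene_ids = g, cell_ids = c_, units = units)
}

fmt_full <- function(v) {
  # %.17g round-trips doubles exactly through as.numeric()
  out <- sprintf("%.17g", v)
  ifelse(v == floor(v) & abs(v) < 2^53, sprintf("%.0f", v), out)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: values are written with full double
#' precision so that a read/write round trip reproduces the matrix
#' bit-for-bit. For `format = "mtx"` the path names the coordinate file and
#' `genes.txt` / `barcodes.txt` are written alongside it.
#'
#' @param M an [ExpressionMatrix].
#' @param path output path.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(M, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(M, "ExpressionMatrix"))
  v <- M$values
  if (format == "mtx") {
    nz <- which(v != 0, arr.ind = TRUE)
    lines <- c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(v), ncol(v), nrow(nz)),
               sprintf("%d %d %s", nz[, 1], nz[, 2], fmt_full(v[nz])))
    writeLines(lines, path)
    writeLines(rownames(v), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(v), file.path(dirname(path), "barcodes.txt"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    chr <- matrix(fmt_full(v), nrow(v), ncol(v))
    lines <- c(paste(c("gene_id", colnames(v)), collapse = sep),
               paste(rownames(v),
                     apply(chr, 1L, paste, collapse = sep), sep = sep))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Randomly subsample cells above a size cap
#'
#' If the matrix has more than `max_cells` cells, a uniform random subset of
#' `max_cells` columns is kept (original column order preserved); otherwise
#' the matrix is returned unchanged. This mirrors the 5000-cell cap the SC3
#' workflow applies to large data sets. The subset is a pure function of
#' `seed`.
#'
#' @param M an [ExpressionMatrix].
#' @param max_cells maximum number of cells to keep (>= 2).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return an [ExpressionMatrix] with at most `max_cells` columns.
#' @export
subsample_cells <- function(M, max_cells = 5000L, seed = 1L) {
  stopifnot(inherits(M, "ExpressionMatrix"))
  max_cells <- check_count(max_cells, "max_cells", min = 2L)
  n <- ncol(M$values)
  if (n <= max_cells) return(M)
  keep <- withr::with_seed(seed, sort(sample.int(n, max_cells)))
  ExpressionMatrix(M$values[, keep, drop = FALSE], units = M$units)
}

#' Read or write per-cell labels as one-column TSV
#'
#' One label per line, aligned with the cell ids of the matrix the labels
#' belong to; no header.
#'
#' @param path file path.
#' @return for `read_labels`, a character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  readLines(path)
}

#' @rdname read_labels
#' @param labels vector of labels (coerced to character).
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
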